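# Evaluation: reconstruction correlation, classification metrics with
# macro averaging, fold summaries, and the paired one-tailed t-test used
# to compare initialisations across cross-validation folds.

#' Pearson correlation between a map and its reconstruction
#'
#' Computed over in-mask voxels only. Zero variance in either map is an
#' error rather than a silent 0.
#'
#' @param original,reconstructed [stat_map]s (or 3D arrays) on the same
#'   grid.
#' @param mask a [brain_mask].
#' @return correlation in \[-1, 1\].
#' @export
reconstruction_correlation <- function(original, reconstructed, mask) {
  a <- if (inherits(original, "stat_map")) original$data else original
  b <- if (inherits(reconstructed, "stat_map")) reconstructed$data else reconstructed
  if (!identical(dim(a), dim(b)) || !identical(dim(a), dim(mask$data)))
    stopf("maps and mask must share one grid")
  va <- a[mask$data]; vb <- b[mask$data]
  if (length(va) < 2) stopf("need at least 2 in-mask voxels")
  if (sd(va) == 0 || sd(vb) == 0)
    stopf("correlation undefined: zero variance over in-mask voxels")
  cor(va, vb)
}

#' Multiclass classification metrics
#'
#' Accuracy, macro-averaged precision and recall, macro F1 (unweighted
#' mean over classes of `2PR/(P+R)`, zero when `P+R = 0`), and per-class
#' accuracy (the per-class recall). Classes absent from `y_true`
#' contribute 0 to the macro averages, with a warning.
#'
#' @param y_true,y_pred equal-length integer label vectors coded
#'   `0..n_classes-1`.
#' @param n_classes total number of classes.
#' @return a list with elements `accuracy`, `precision`, `recall`,
#'   `f1_macro`, `per_class_accuracy` (named numeric of length
#'   `n_classes`) and `n`.
#' @export
classification_metrics <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred))
    stopf("'y_true' and 'y_pred' must have equal length")
  lv <- seq_len(n_classes) - 1L
  if (any(!c(y_true, y_pred) %in% lv)) stopf("labels must lie in 0..%d", n_classes - 1)
  cm <- table(factor(y_true, levels = lv), factor(y_pred, levels = lv))
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  if (any(support == 0))
    warnf("%d class(es) absent from y_true contribute 0 to macro averages",
          sum(support == 0))
  prec <- ifelse(predicted > 0, tp / predicted, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = mean(y_true == y_pred),
       precision = mean(prec),
       recall = mean(rec),
       f1_macro = mean(f1),
       per_class_accuracy = setNames(as.numeric(rec), lv),
       n = length(y_true))
}

#' Mean and standard error over cross-validation folds
#'
#' @param values per-fold metric values (at least 2).
#' @return `list(mean, sem)` with `sem = sd / sqrt(n)` (sample sd, n-1
#'   denominator).
#' @export
summarize_folds <- function(values) {
  if (length(values) < 2) stopf("need at least 2 fold values")
  list(mean = mean(values), sem = sd(values) / sqrt(length(values)))
}

#' Paired one-tailed t-test over fold-matched values
#'
#' The paired (dependent-samples) t statistic on the differences
#' `d = a - b`: `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of
#' freedom and a one-tailed p-value for the stated alternative. With 5
#' folds this gives 4 degrees of freedom. Zero-variance differences with
#' nonzero mean yield a signed infinite t (p -> 0 when the alternative
#' matches the sign); identical vectors yield `t = 0, p = 0.5`.
#'
#' @param a,b equal-length per-fold values, paired by fold.
#' @param alternative `"greater"` tests mean(a) > mean(b), `"less"` the
#'   reverse.
#' @return an object of class `ttest_result`: list with `t`, `p`, `dof`,
#'   `alternative`, and the 0.05 significance flag `significant`.
#' @export
paired_onetailed_ttest <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) stopf("'a' and 'b' must have equal length")
  n <- length(a)
  if (n < 2) stopf("need at least 2 paired values")
  d <- a - b
  dof <- n - 1L
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0) {
      t <- 0; p <- 0.5
    } else {
      t <- sign(mean(d)) * Inf
      p <- if ((alternative == "greater") == (t > 0)) 0 else 1
    }
  } else {
    t <- mean(d) / (s / sqrt(n))
    p <- if (alternative == "greater") pt(t, dof, lower.tail = FALSE)
         else pt(t, dof)
  }
  structure(list(t = t, p = p, dof = dof, alternative = alternative,
                 significant = is.finite(p) && p < 0.05),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("paired one-tailed t-test (%d dof, alternative '%s'): t = %.4g, p = %.4g%s\n",
              x$dof, x$alternative, x$t, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}

# "mean (sem)" strings for report tables, values given in percent
format_mean_sem <- function(mean, sem, scale = 100, digits = 1) {
  sprintf("%.*f (%.2f)", digits, scale * mean, scale * sem)
}
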