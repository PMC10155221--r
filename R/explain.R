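# Explainability: per-layer feature maps and their between-subject
# correlation, the quantitative handle on representation generalizability.
# A high mean correlation between subjects' feature maps for the same
# class indicates features that are less sensitive to individual
# differences.

#' Extract one layer's feature maps for a statistic map
#'
#' Runs the classifier (or autoencoder) encoder up to the requested block
#' in inference mode and returns the post-activation tensor
#' (conv -> batch-norm -> leaky-ReLU output). Model parameters are left
#' untouched.
#'
#' @param model an `stl_cnn` or `stl_cae`.
#' @param map a preprocessed [stat_map].
#' @param layer block index in `1..n_layers`.
#' @return an object of class `feature_tensor`: list with `layer`, `data`
#'   (4-d array D x H x W x C), `subject_id`, `class_id`.
#' @export
extract_layer_features <- function(model, map, layer) {
  if (layer < 1 || layer > model$spec$n_layers)
    stopf("'layer' must lie in 1..%d", model$spec$n_layers)
  x <- as_batch_array(list(map))
  spec <- model$spec
  out <- cpp_encoder_infer(x, model$params$encoder, layer,
                           spec$negative_slope, spec$stride, spec$pad)
  d <- dim(out)
  structure(list(layer = as.integer(layer),
                 data = array(out, d[1:4]),
                 subject_id = map$meta$subject_id %||% NA_character_,
                 class_id = map$meta$class_id %||% NA_character_),
            class = "feature_tensor")
}

#' Mean feature map of one class across subjects
#'
#' @param model an `stl_cnn` or `stl_cae`.
#' @param maps list of preprocessed [stat_map]s, all of the same class
#'   (one per subject).
#' @param layer block index.
#' @return a `feature_tensor` holding the elementwise mean.
#' @export
mean_class_feature_map <- function(model, maps, layer) {
  if (!length(maps)) stopf("need at least 1 map")
  classes <- unique(vapply(maps, function(m) m$meta$class_id %||% NA_character_, ""))
  if (length(classes) > 1) stopf("maps mix classes: %s", paste(classes, collapse = ", "))
  feats <- lapply(maps, function(m) extract_layer_features(model, m, layer))
  acc <- feats[[1]]$data
  if (length(feats) > 1) {
    for (i in 2:length(feats)) acc <- acc + feats[[i]]$data
  }
  structure(list(layer = as.integer(layer), data = acc / length(feats),
                 subject_id = NA_character_, class_id = classes),
            class = "feature_tensor")
}

#' Between-subject correlation of feature maps for one class
#'
#' Each subject's feature tensor is flattened to one vector (all channels
#' concatenated) and the Pearson correlation is computed for every
#' unordered pair of subjects; `n (n - 1) / 2` pairs for `n` subjects.
#' Pairs involving a zero-variance feature vector are skipped with a
#' warning and counted in `n_skipped`.
#'
#' @param model an `stl_cnn` or `stl_cae`.
#' @param maps_by_subject named list: subject id -> one preprocessed
#'   [stat_map] of the class under study.
#' @param layer block index.
#' @return a list with `layer`, `class_id`, `n_pairs`, `correlations`,
#'   `mean_r`, `sd_r`, `n_skipped`.
#' @export
between_subject_feature_correlation <- function(model, maps_by_subject, layer) {
  if (length(maps_by_subject) < 2) stopf("need at least 2 subjects")
  vecs <- lapply(maps_by_subject, function(m) {
    as.numeric(extract_layer_features(model, m, layer)$data)
  })
  ok <- vapply(vecs, function(v) sd(v) > 0, logical(1))
  cls <- unique(vapply(maps_by_subject,
                       function(m) m$meta$class_id %||% NA_character_, ""))
  n <- length(vecs)
  cors <- numeric(0)
  n_skipped <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!ok[i] || !ok[j]) { n_skipped <- n_skipped + 1L; next }
    cors <- c(cors, cor(vecs[[i]], vecs[[j]]))
  }
  if (n_skipped > 0)
    warnf("%d pair(s) skipped due to zero-variance feature vectors", n_skipped)
  list(layer = as.integer(layer), class_id = cls[1],
       n_pairs = length(cors), correlations = cors,
       mean_r = if (length(cors)) mean(cors) else NA_real_,
       sd_r = if (length(cors) > 1) sd(cors) else NA_real_,
       n_skipped = n_skipped)
}

#' Export a feature tensor as one NIfTI volume per channel
#'
#' @param feat a `feature_tensor`.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return paths written, invisibly.
#' @export
write_feature_maps <- function(feat, dir, prefix = "feature") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(feat$data)
  paths <- character(d[4])
  for (ch in seq_len(d[4])) {
    p <- file.path(dir, sprintf("%s_layer%d_ch%03d.nii.gz", prefix, feat$layer, ch))
    write_stat_map(stat_map(feat$data[, , , ch],
                            default_affine(d[1:3], spacing = 4)), p)
    paths[ch] <- p
  }
  invisible(paths)
}
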