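# Subject-wise split machinery: validation/test holdout, k-fold plans,
# nested subsamples, and multi-study fold combination. All folds are
# indexed 0..k-1, matching their serialized form.

#' Construct a fold plan
#'
#' A fold plan assigns every subject of a subdataset to exactly one
#' cross-validation fold.
#'
#' @param assignment named integer vector: subject id -> fold index in
#'   `0..k-1`.
#' @param k number of folds.
#' @param subdataset `"validation"` or `"test"`.
#' @param study_scoped whether the plan was built per study
#'   ([combine_study_folds]).
#' @return an object of class `fold_plan`.
#' @export
fold_plan <- function(assignment, k = 5L, subdataset = c("test", "validation"),
                      study_scoped = FALSE) {
  subdataset <- match.arg(subdataset)
  if (is.null(names(assignment)) || any(!nzchar(names(assignment))))
    stopf("'assignment' must be named by subject id")
  if (anyDuplicated(names(assignment)))
    stopf("each subject must appear in exactly one fold")
  if (any(assignment < 0 | assignment >= k))
    stopf("fold indices must lie in 0..%d", k - 1)
  structure(list(assignment = vapply(assignment, as.integer, integer(1)),
                 k = as.integer(k), subdataset = subdataset,
                 study_scoped = isTRUE(study_scoped)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %s, %d subjects in %d folds%s\n", x$subdataset,
              length(x$assignment), x$k,
              if (x$study_scoped) " (study-scoped)" else ""))
  print(table(fold = x$assignment))
  invisible(x)
}

plan_subjects <- function(plan) names(plan$assignment)

#' Subject-level holdout split
#'
#' Partitions the subjects of a manifest into validation and test sets at
#' the given fraction, so that no subject contributes maps to both.
#'
#' @param manifest a manifest with a complete `subject_id` column.
#' @param fraction fraction of subjects assigned to the validation side.
#' @param seed integer seed.
#' @return `list(validation_subjects, test_subjects)`.
#' @export
split_holdout_by_subject <- function(manifest, fraction = 0.5, seed = 1L) {
  if (!"subject_id" %in% names(manifest) || anyNA(manifest$subject_id))
    stopf("manifest must have a complete 'subject_id' column")
  subjects <- sort(unique(manifest$subject_id))
  n_val <- round(fraction * length(subjects))
  val <- with_seed(seed, sample(subjects, n_val))
  list(validation_subjects = sort(val),
       test_subjects = sort(setdiff(subjects, val)))
}

#' Assign subjects to k cross-validation folds
#'
#' Fold sizes differ by at most one; when the subject count is not
#' divisible by `k`, earlier folds receive the extra subjects.
#'
#' @param subjects character vector of subject ids.
#' @param k number of folds.
#' @param seed integer seed.
#' @param subdataset which subdataset the plan belongs to.
#' @return a [fold_plan].
#' @export
assign_subject_folds <- function(subjects, k = 5L, seed = 1L,
                                 subdataset = "test") {
  n <- length(subjects)
  if (n < k) stopf("cannot split %d subjects into %d folds", n, k)
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  shuffled <- with_seed(seed, sample(subjects))
  assignment <- setNames(rep(seq_len(k) - 1L, times = sizes), shuffled)
  fold_plan(assignment, k = k, subdataset = subdataset)
}

#' Draw nested subject subsamples of a fold plan
#'
#' For each requested size `N`, draws `N/k` subjects per fold of the parent
#' plan, keeping each subject's fold index. The plans are nested: every
#' subject of a smaller plan belongs to the next larger plan (and so on up
#' to the parent), so models trained on any subsample can be tested on the
#' parent's held-out fold without subject leakage.
#'
#' @param parent a [fold_plan].
#' @param sizes strictly decreasing subject counts, each divisible by `k`
#'   and at most the parent's subject count.
#' @param seed integer seed.
#' @return a named list of [fold_plan]s, one per size (names are the
#'   sizes).
#' @export
nested_subsample_folds <- function(parent, sizes, seed = 1L) {
  k <- parent$k
  if (any(diff(sizes) >= 0)) stopf("'sizes' must be strictly decreasing")
  if (any(sizes %% k != 0)) stopf("each size must be divisible by k = %d", k)
  if (sizes[1] > length(parent$assignment))
    stopf("largest size exceeds the parent plan's %d subjects",
          length(parent$assignment))
  plans <- list()
  current <- parent
  for (N in sizes) {
    per_fold <- N %/% k
    keep <- unlist(lapply(seq_len(k) - 1L, function(f) {
      members <- names(current$assignment)[current$assignment == f]
      with_seed(derive_seed(seed, "subsample", N, f), sample(members, per_fold))
    }))
    current <- fold_plan(current$assignment[keep], k = k,
                         subdataset = parent$subdataset,
                         study_scoped = parent$study_scoped)
    plans[[as.character(N)]] <- current
  }
  plans
}

check_nested <- function(plan, global_plan) {
  subs <- plan_subjects(plan)
  if (!all(subs %in% plan_subjects(global_plan)))
    stopf("leakage: plan contains subjects missing from the global plan")
  if (!all(plan$assignment == global_plan$assignment[subs]))
    stopf("leakage: plan fold indices differ from the global plan")
  invisible(TRUE)
}

#' Train/test map split for one cross-validation fold
#'
#' Training maps come from the plan's subjects in folds other than
#' `fold_i`; test maps come from the *global* plan's subjects in fold
#' `fold_i`. Because the plan is nested in the global plan with preserved
#' fold indices, the two sets are guaranteed subject-disjoint. Passing the
#' plan itself as `global_plan` gives the ordinary subset-only split.
#'
#' @param plan a [fold_plan] (possibly a nested subsample).
#' @param global_plan the superset [fold_plan] providing the test fold.
#' @param fold_i fold index in `0..k-1`.
#' @param manifest manifest of all maps.
#' @return `list(train, test)` manifests.
#' @export
cv_split <- function(plan, global_plan, fold_i, manifest) {
  if (fold_i < 0 || fold_i >= plan$k)
    stopf("'fold_i' must lie in 0..%d", plan$k - 1)
  check_nested(plan, global_plan)
  train_subj <- names(plan$assignment)[plan$assignment != fold_i]
  test_subj <- names(global_plan$assignment)[global_plan$assignment == fold_i]
  list(train = manifest[manifest$subject_id %in% train_subj, , drop = FALSE],
       test = manifest[manifest$subject_id %in% test_subj, , drop = FALSE])
}

#' Build combined validation/test fold plans for a multi-study manifest
#'
#' Per study, subjects are first held out 50/50 (or `holdout_fraction`)
#' into validation and test sides, then split into `k` folds; the n-th
#' fold of the dataset is the union of the n-th folds of all studies, so
#' every combined fold keeps the study heterogeneity. A study with fewer
#' than 2 subjects is assigned wholly to the validation side with a
#' warning.
#'
#' @param manifest a manifest with complete `subject_id` and `study_id`.
#' @param k number of folds.
#' @param holdout_fraction fraction of each study's subjects on the
#'   validation side.
#' @param seed integer seed.
#' @return `list(validation, test)` of study-scoped [fold_plan]s.
#' @export
combine_study_folds <- function(manifest, k = 5L, holdout_fraction = 0.5,
                                seed = 1L) {
  if (!"study_id" %in% names(manifest) || anyNA(manifest$study_id))
    stopf("manifest must have a complete 'study_id' column")
  val_assign <- integer(0); test_assign <- integer(0)
  for (st in sort(unique(manifest$study_id))) {
    subjects <- sort(unique(manifest$subject_id[manifest$study_id == st]))
    if (length(subjects) < 2) {
      warnf("study '%s' has fewer than 2 subjects; assigned wholly to the validation side", st)
      val <- subjects; test <- character(0)
    } else {
      h <- split_holdout_by_subject(
        manifest[manifest$study_id == st, , drop = FALSE],
        fraction = holdout_fraction, seed = derive_seed(seed, "holdout", st))
      val <- h$validation_subjects; test <- h$test_subjects
    }
    assign_side <- function(subjects, side) {
      if (!length(subjects)) return(integer(0))
      if (length(subjects) >= k) {
        assign_subject_folds(subjects, k = k,
                             seed = derive_seed(seed, side, st))$assignment
      } else {
        # tiny study side: spread subjects over the first folds
        shuffled <- with_seed(derive_seed(seed, side, st), sample(subjects))
        setNames(seq_along(shuffled) - 1L, shuffled)
      }
    }
    val_assign <- c(val_assign, assign_side(val, "validation"))
    test_assign <- c(test_assign, assign_side(test, "test"))
  }
  list(validation = fold_plan(val_assign, k = k, subdataset = "validation",
                              study_scoped = TRUE),
       test = fold_plan(test_assign, k = k, subdataset = "test",
                        study_scoped = TRUE))
}

#' Extract a small multi-study dataset from combined fold plans
#'
#' Keeps only studies with strictly more than `min_subjects` subjects
#' overall, then draws `per_fold` subjects per fold per study per
#' subdataset, preserving fold indices, so the small plans are nested in
#' the input plans.
#'
#' @param validation,test study-scoped [fold_plan]s from
#'   [combine_study_folds].
#' @param manifest the multi-study manifest.
#' @param min_subjects keep studies with more than this many subjects.
#' @param per_fold subjects drawn per fold per study per subdataset.
#' @param seed integer seed.
#' @return `list(validation, test)` of small [fold_plan]s.
#' @export
extract_small_multistudy <- function(validation, test, manifest,
                                     min_subjects = 20L, per_fold = 2L,
                                     seed = 1L) {
  study_of <- function(subjects) {
    manifest$study_id[match(subjects, manifest$subject_id)]
  }
  counts <- table(study_of(unique(manifest$subject_id)))
  kept_studies <- names(counts)[counts > min_subjects]
  if (!length(kept_studies)) stopf("no study has more than %d subjects", min_subjects)
  shrink <- function(plan, side) {
    subs <- plan_subjects(plan)
    studies <- study_of(subs)
    keep <- unlist(lapply(kept_studies, function(st) {
      unlist(lapply(seq_len(plan$k) - 1L, function(f) {
        members <- subs[studies == st & plan$assignment == f]
        if (length(members) < per_fold)
          stopf("study '%s' fold %d (%s) has %d subjects, fewer than per_fold = %d",
                st, f, side, length(members), per_fold)
        with_seed(derive_seed(seed, "small", side, st, f),
                  sample(members, per_fold))
      }))
    }))
    fold_plan(plan$assignment[keep], k = plan$k, subdataset = plan$subdataset,
              study_scoped = TRUE)
  }
  list(validation = shrink(validation, "validation"),
       test = shrink(test, "test"))
}

#' Serialize a fold plan to JSON
#'
#' The file stores the subject-to-fold assignment keyed by subject id, for
#' reproducibility of every split.
#'
#' @param plan a [fold_plan].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(list(
    subdataset = plan$subdataset, k = plan$k,
    study_scoped = plan$study_scoped,
    assignment = as.list(plan$assignment)
  ), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a fold plan written by [write_fold_plan]
#'
#' @param path JSON path.
#' @return a [fold_plan].
#' @export
read_fold_plan <- function(path) {
  x <- jsonlite::read_json(path)
  fold_plan(setNames(vapply(x$assignment, as.integer, integer(1)),
                     names(x$assignment)),
            k = x$k, subdataset = x$subdataset, study_scoped = x$study_scoped)
}
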