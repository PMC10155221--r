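# Metadata curation: repository-style inclusion criteria and the map-level
# pretraining split.

FILENAME_TOKENS <- c("SetA_mean", "SetB_mean", "con", "cope")

# TRUE where the filename flags a raw contrast file. In token mode the
# basename is split on non-alphanumeric characters and a record is rejected
# when a token is "con"/"cope" optionally followed by digits (this catches
# SPM "con_0001" and FSL "cope3" while keeping legitimate names such as
# "contrast_of_interest"); "SetA_mean"/"SetB_mean" are matched as literal
# substrings since they span an underscore. Substring mode rejects any
# filename containing one of the four tokens anywhere.
filename_flagged <- function(filenames, mode = c("token", "substring")) {
  mode <- match.arg(mode)
  base <- basename(filenames)
  if (mode == "substring") {
    Reduce(`|`, lapply(FILENAME_TOKENS, function(tok) grepl(tok, base, fixed = TRUE)))
  } else {
    setab <- grepl("SetA_mean", base, fixed = TRUE) |
      grepl("SetB_mean", base, fixed = TRUE)
    conish <- vapply(strsplit(base, "[^A-Za-z0-9]+"), function(tokens) {
      any(grepl("^(con|cope)[0-9]*$", tokens, ignore.case = TRUE))
    }, logical(1))
    setab | conish
  }
}

#' Filter a manifest with the statistic-map inclusion criteria
#'
#' Keeps exactly the rows satisfying all of: modality `"fMRI-BOLD"`,
#' `is_valid` true, `not_mni` false, map type `"T map"` or `"Z map"`, not
#' thresholded, and a filename that does not look like a raw contrast file
#' (`con*`/`cope*` SPM/FSL names, `SetA_mean`/`SetB_mean` AFNI names,
#' matched under the token rule described above). The input manifest is
#' never modified.
#'
#' @param manifest a manifest `data.frame`.
#' @param filename_mode `"token"` (default) or `"substring"`; see above.
#' @return `list(manifest, report)`: the kept rows, and a `data.frame` with
#'   one row per rule giving the number of input rows rejected by that rule
#'   (rules are counted independently, so a row can appear in several
#'   counts).
#' @export
filter_metadata <- function(manifest, filename_mode = c("token", "substring")) {
  filename_mode <- match.arg(filename_mode)
  required <- c("modality", "map_type", "is_valid", "not_mni", "thresholded",
                "filename")
  for (col in required) {
    if (!col %in% names(manifest)) stopf("manifest is missing required column '%s'", col)
  }
  pass <- list(
    modality = manifest$modality == "fMRI-BOLD",
    is_valid = as.logical(manifest$is_valid),
    not_mni = !as.logical(manifest$not_mni),
    map_type = manifest$map_type %in% c("T map", "Z map"),
    thresholded = !as.logical(manifest$thresholded),
    filename = !filename_flagged(manifest$filename, filename_mode)
  )
  keep <- Reduce(`&`, pass)
  report <- data.frame(
    rule = names(pass),
    rejected = vapply(pass, function(p) sum(!p), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(manifest = manifest[keep, , drop = FALSE], report = report)
}

#' Split a pretraining manifest into train and test sets
#'
#' A map-level (not subject-level) uniform random split, as appropriate for
#' the unsupervised pretraining stage where no labels are used. The train
#' set receives `round(train_fraction * N)` maps.
#'
#' @param manifest a manifest `data.frame` with at least 2 rows.
#' @param train_fraction fraction of maps assigned to training, in (0, 1).
#' @param seed integer seed.
#' @return `list(train, test)`: two disjoint manifests whose union is the
#'   input.
#' @export
split_pretraining <- function(manifest, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("'train_fraction' must lie strictly between 0 and 1")
  n <- nrow(manifest)
  if (n < 2) stopf("cannot split a manifest with fewer than 2 maps")
  n_train <- round(train_fraction * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = manifest[sort(idx), , drop = FALSE],
       test = manifest[setdiff(seq_len(n), idx), , drop = FALSE])
}
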