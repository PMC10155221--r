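# Synthetic statistic-map corpora.
#
# The generator emulates the structure of repository-hosted task-fMRI
# statistic maps: smooth brain-masked activation blobs on a z scale, with
# subject-level nuisance (rigid integer-voxel shift + multiplicative gain),
# study-level nuisance (multiplicative gain + smoothness jitter), and
# additive smoothed Gaussian noise. Three regimes are supported:
#   single_study       - one study, contrasts nested in tasks, one map per
#                        (subject, contrast); emulates a large single-site
#                        task battery (23 contrasts in 7 tasks).
#   multi_study        - subjects nested in studies, each study covering an
#                        imbalanced subset of concept classes.
#   pretraining_corpus - unlabelled heterogeneous maps from throwaway
#                        templates, plus contaminant records that the
#                        metadata curation filters must reject.

MANIFEST_COLS <- c("path", "image_id", "subject_id", "study_id", "contrast",
                   "task", "concept", "modality", "map_type", "is_valid",
                   "not_mni", "thresholded", "filename")

#' Configuration of the synthetic statistic-map generator
#'
#' Collects every data-generating assumption in one validated object. The
#' defaults are the reference study conditions used throughout the package's
#' tests and benchmarks.
#'
#' @param regime one of `"single_study"`, `"multi_study"`,
#'   `"pretraining_corpus"`.
#' @param grid_shape voxel grid, each dimension at least 16.
#' @param n_classes number of classes (contrasts, concepts, or throwaway
#'   pretraining templates). At least 2.
#' @param n_tasks single-study only: number of parent tasks the contrasts
#'   are nested in.
#' @param n_subjects single-study only: number of subjects.
#' @param n_studies,subjects_per_study multi-study only.
#' @param n_maps pretraining corpus only: number of records emitted.
#' @param contaminant_fraction pretraining corpus only: fraction of records
#'   violating at least one inclusion criterion.
#' @param subject_shift_sd sd of the subject's rigid integer-voxel shift.
#' @param subject_gain_sd sd of the subject log-gain.
#' @param study_gain_sd sd of the study log-gain.
#' @param study_smoothness_jitter sd (mm) of the study-specific extra
#'   smoothing applied on top of `smoothing_fwhm`.
#' @param noise_sd sd of the additive smoothed noise, in z units.
#' @param smoothing_fwhm FWHM (mm) of the noise smoothing kernel.
#' @param class_imbalance optional per-class sampling weights
#'   (multi-study); `NULL` uses a mildly decaying default.
#' @param mask_path optional NIfTI brain mask; by default an ellipsoid
#'   inscribed in the grid is used.
#' @param seed integer master seed for the whole corpus.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(regime = c("single_study", "multi_study",
                                        "pretraining_corpus"),
                             grid_shape = default_grid(),
                             n_classes = NULL, n_tasks = NULL,
                             n_subjects = NULL,
                             n_studies = NULL, subjects_per_study = NULL,
                             n_maps = NULL, contaminant_fraction = 0.25,
                             subject_shift_sd = 1, subject_gain_sd = 0.15,
                             study_gain_sd = 0.2, study_smoothness_jitter = 2,
                             noise_sd = 1, smoothing_fwhm = 8,
                             class_imbalance = NULL, mask_path = NULL,
                             seed = 1L) {
  regime <- match.arg(regime)
  if (regime == "single_study") {
    n_classes <- n_classes %||% 23L
    n_tasks <- n_tasks %||% 7L
    n_subjects <- n_subjects %||% 25L
  } else if (regime == "multi_study") {
    n_classes <- n_classes %||% 30L
    n_studies <- n_studies %||% 11L
    subjects_per_study <- subjects_per_study %||% 20L
    if (is.null(subjects_per_study)) stopf("'subjects_per_study' is required in multi_study regime")
  } else {
    n_classes <- n_classes %||% 30L
    n_maps <- n_maps %||% 100L
  }
  if (length(grid_shape) != 3L || any(grid_shape < 16))
    stopf("'grid_shape' must have 3 dimensions, each >= 16")
  if (n_classes < 2) stopf("'n_classes' must be at least 2")
  sds <- c(subject_shift_sd, subject_gain_sd, study_gain_sd,
           study_smoothness_jitter, noise_sd, smoothing_fwhm)
  if (any(sds < 0)) stopf("all sd/smoothness parameters must be >= 0")
  if (regime == "pretraining_corpus" &&
      (contaminant_fraction < 0 || contaminant_fraction > 1))
    stopf("'contaminant_fraction' must lie in [0, 1]")
  if (!is.null(class_imbalance) && length(class_imbalance) != n_classes)
    stopf("'class_imbalance' must have one weight per class")
  structure(list(
    regime = regime, grid_shape = as.integer(grid_shape),
    n_classes = as.integer(n_classes), n_tasks = n_tasks,
    n_subjects = n_subjects, n_studies = n_studies,
    subjects_per_study = subjects_per_study, n_maps = n_maps,
    contaminant_fraction = contaminant_fraction,
    subject_shift_sd = subject_shift_sd, subject_gain_sd = subject_gain_sd,
    study_gain_sd = study_gain_sd,
    study_smoothness_jitter = study_smoothness_jitter,
    noise_sd = noise_sd, smoothing_fwhm = smoothing_fwhm,
    class_imbalance = class_imbalance, mask_path = mask_path,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Brain mask implied by a synthetic configuration
#'
#' @param config a [synthetic_config].
#' @return a [brain_mask]: the mask file named in the config, or the
#'   inscribed ellipsoid.
#' @export
config_mask <- function(config) {
  if (!is.null(config$mask_path)) return(read_brain_mask(config$mask_path))
  ellipsoid_mask(config$grid_shape, default_affine(config$grid_shape))
}

#' Draw the class activation templates for a configuration
#'
#' Each class is a set of isotropic Gaussian blobs (centre, width in mm,
#' z-scale peak amplitude) with all centres inside the brain mask. In the
#' single-study regime the classes are grouped under `n_tasks` parent tasks
#' and classes of the same task share that task's blobs, so classifying the
#' task is easier than classifying the class itself.
#'
#' @param config a [synthetic_config].
#' @param mask a [brain_mask] on the config's grid.
#' @return a list of `class_template` objects.
#' @export
make_class_templates <- function(config, mask = config_mask(config)) {
  if (!inherits(mask, "brain_mask") || !any(mask$data)) stopf("invalid or empty brain mask")
  if (config$n_classes < 2) stopf("'n_classes' must be at least 2")
  in_vox <- which(mask$data)
  dims <- dim(mask$data)
  draw_blobs <- function(n) {
    lapply(seq_len(n), function(i) {
      ctr <- arrayInd(sample(in_vox, 1L), dims)[1, ]
      amp <- runif(1, 4, 8) * sample(c(1, -1), 1, prob = c(0.85, 0.15))
      list(center = as.integer(ctr), width = runif(1, 8, 14), amplitude = amp)
    })
  }
  with_seed(derive_seed(config$seed, "templates"), {
    if (config$regime == "single_study") {
      tasks <- vapply(seq_len(config$n_tasks), function(t) pad_id("task", t, 2), "")
      task_blobs <- lapply(tasks, function(t) draw_blobs(2L))
      lapply(seq_len(config$n_classes), function(i) {
        ti <- (i - 1L) %% config$n_tasks + 1L
        structure(list(
          class_id = pad_id("contrast", i, 2),
          blobs = c(task_blobs[[ti]], draw_blobs(2L)),
          parent_task = tasks[ti]
        ), class = "class_template")
      })
    } else {
      prefix <- if (config$regime == "multi_study") "concept" else "nv_class"
      lapply(seq_len(config$n_classes), function(i) {
        structure(list(
          class_id = pad_id(prefix, i, 2),
          blobs = draw_blobs(3L),
          parent_task = NULL
        ), class = "class_template")
      })
    }
  })
}

# Evaluate the (separable) Gaussian blob sum of a template on the grid.
# `shift` translates all blob centres by integer voxels; blobs whose
# shifted centre leaves the grid are dropped.
render_template <- function(template, grid_shape, mask, shift = c(0L, 0L, 0L),
                            spacing = 4, extra_fwhm = 0) {
  vol <- array(0, grid_shape)
  n_in <- 0L
  for (b in template$blobs) {
    ctr <- b$center + shift
    if (any(ctr < 1L) || any(ctr > grid_shape)) next
    n_in <- n_in + 1L
    sigma <- sqrt((b$width / spacing)^2 + (extra_fwhm / (2 * sqrt(2 * log(2))) / spacing)^2)
    g1 <- exp(-(seq_len(grid_shape[1]) - ctr[1])^2 / (2 * sigma^2))
    g2 <- exp(-(seq_len(grid_shape[2]) - ctr[2])^2 / (2 * sigma^2))
    g3 <- exp(-(seq_len(grid_shape[3]) - ctr[3])^2 / (2 * sigma^2))
    vol <- vol + b$amplitude * outer(outer(g1, g2), g3)
  }
  attr(vol, "n_blobs_in_grid") <- n_in
  vol
}

#' Sample one statistic map from a class template
#'
#' Renders the template, applies the subject's rigid shift and gain and the
#' study's gain and smoothness jitter, and adds smoothed Gaussian noise
#' rescaled to `noise_sd`. Subject and study effects are derived
#' deterministically from the configuration seed and the respective IDs, so
#' they are redrawn per subject/study but fixed across all of that
#' subject's maps. Values are clipped to the z-plausible range \[-12, 12\]
#' and are exactly zero outside the mask.
#'
#' @param template a `class_template`.
#' @param subject_id,study_id identifier strings.
#' @param config a [synthetic_config].
#' @param mask a [brain_mask].
#' @param seed map-level seed (drives the noise draw).
#' @return a [stat_map].
#' @export
sample_stat_map <- function(template, subject_id, study_id, config,
                            mask = config_mask(config), seed = config$seed) {
  subj <- with_seed(derive_seed(config$seed, "subject", subject_id), list(
    shift = as.integer(round(rnorm(3, 0, config$subject_shift_sd))),
    gain = exp(rnorm(1, 0, config$subject_gain_sd))
  ))
  stdy <- with_seed(derive_seed(config$seed, "study", study_id), list(
    gain = exp(rnorm(1, 0, config$study_gain_sd)),
    extra_fwhm = abs(rnorm(1, 0, config$study_smoothness_jitter))
  ))
  spacing <- abs(mask$affine[1, 1])
  signal <- render_template(template, config$grid_shape, mask,
                            shift = subj$shift, spacing = spacing,
                            extra_fwhm = stdy$extra_fwhm)
  if (attr(signal, "n_blobs_in_grid") == 0L)
    stopf("degenerate sample: subject shift pushed all blobs of '%s' outside the grid",
          template$class_id)
  attr(signal, "n_blobs_in_grid") <- NULL
  vol <- stdy$gain * subj$gain * signal
  if (config$noise_sd > 0) {
    eps <- with_seed(seed, array(rnorm(prod(config$grid_shape)), config$grid_shape))
    eps <- gaussian_smooth3(eps, config$smoothing_fwhm + stdy$extra_fwhm, spacing)
    eps <- eps * (config$noise_sd / sd(eps))
    vol <- vol + eps
  }
  vol <- pmin(pmax(vol, -12), 12)
  vol[!mask$data] <- 0
  stat_map(vol, mask$affine, meta = list(
    subject_id = subject_id, study_id = study_id,
    class_id = template$class_id, parent_task = template$parent_task
  ))
}

empty_manifest_row <- function() {
  data.frame(path = "", image_id = "", subject_id = NA_character_,
             study_id = NA_character_, contrast = NA_character_,
             task = NA_character_, concept = NA_character_,
             modality = "fMRI-BOLD", map_type = "Z map", is_valid = TRUE,
             not_mni = FALSE, thresholded = FALSE, filename = "",
             stringsAsFactors = FALSE)
}

#' Generate a labelled synthetic collection
#'
#' In the `single_study` regime one map is produced per (subject, contrast)
#' pair, with contrast and parent-task labels in the manifest. In the
#' `multi_study` regime subjects are nested in studies, each study covers a
#' subset of the concept classes drawn with the (imbalanced) class weights,
#' and one map is produced per (subject, covered class).
#'
#' @param config a [synthetic_config] with a labelled regime.
#' @return `list(maps, manifest)`: a named list of [stat_map]s keyed by
#'   image id, and the matching manifest `data.frame` (one row per map).
#' @export
generate_labeled_collection <- function(config) {
  if (!config$regime %in% c("single_study", "multi_study"))
    stopf("regime must be single_study or multi_study")
  if (config$regime == "multi_study" && is.null(config$subjects_per_study))
    stopf("'subjects_per_study' is required in multi_study regime")
  mask <- config_mask(config)
  templates <- make_class_templates(config, mask)
  rows <- list(); maps <- list()
  add_map <- function(i, template, subject_id, study_id) {
    image_id <- pad_id("map", i, 6)
    m <- sample_stat_map(template, subject_id, study_id, config, mask,
                         seed = derive_seed(config$seed, "map", image_id))
    m$meta$image_id <- image_id
    row <- empty_manifest_row()
    row$image_id <- image_id
    row$subject_id <- subject_id
    row$study_id <- study_id
    row$filename <- paste0(image_id, "_zstat.nii.gz")
    if (config$regime == "single_study") {
      row$contrast <- template$class_id
      row$task <- template$parent_task
    } else {
      row$concept <- template$class_id
    }
    maps[[image_id]] <<- m
    rows[[length(rows) + 1L]] <<- row
  }
  if (config$regime == "single_study") {
    subjects <- vapply(seq_len(config$n_subjects), function(s) pad_id("sub", s), "")
    i <- 0L
    for (s in subjects) for (tp in templates) {
      i <- i + 1L
      add_map(i, tp, s, "study_01")
    }
  } else {
    w <- config$class_imbalance %||% (1 / sqrt(seq_len(config$n_classes)))
    coverage <- with_seed(derive_seed(config$seed, "coverage"), {
      cov <- lapply(seq_len(config$n_studies), function(s) {
        n_cover <- sample(6:10, 1)
        sort(sample.int(config$n_classes, min(n_cover, config$n_classes), prob = w))
      })
      missing <- setdiff(seq_len(config$n_classes), unique(unlist(cov)))
      for (cl in missing) {
        s <- sample.int(config$n_studies, 1)
        cov[[s]] <- sort(union(cov[[s]], cl))
      }
      cov
    })
    i <- 0L
    for (s in seq_len(config$n_studies)) {
      study_id <- pad_id("study", s, 2)
      for (j in seq_len(config$subjects_per_study)) {
        subject_id <- paste0(study_id, "_", pad_id("sub", j))
        for (cl in coverage[[s]]) {
          i <- i + 1L
          add_map(i, templates[[cl]], subject_id, study_id)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  list(maps = maps, manifest = manifest)
}

#' Generate an unlabelled pretraining corpus with contaminants
#'
#' Emits maps drawn from throwaway templates (classes disjoint from any
#' labelled collection) and, for a `contaminant_fraction` of records,
#' injects exactly the defects the metadata curation rules must reject:
#' wrong modality, `is_valid = FALSE`, `not_mni = TRUE`, a non-T/Z map
#' type, thresholded values (zeroed below a cutoff), or a contrast-file
#' name (`con*`, `cope*`, `SetA_mean*`, `SetB_mean*`). The hidden column
#' `.contaminant` records the ground truth for filter testing.
#'
#' @param config a [synthetic_config] with regime `pretraining_corpus`.
#' @return `list(maps, manifest)` as in [generate_labeled_collection].
#' @export
generate_pretraining_corpus <- function(config) {
  if (config$regime != "pretraining_corpus")
    stopf("regime must be pretraining_corpus")
  if (config$contaminant_fraction < 0 || config$contaminant_fraction > 1)
    stopf("'contaminant_fraction' must lie in [0, 1]")
  mask <- config_mask(config)
  templates <- make_class_templates(config, mask)
  n <- config$n_maps
  n_cont <- round(config$contaminant_fraction * n)
  plan <- with_seed(derive_seed(config$seed, "corpus_plan"), {
    idx <- sample.int(n, n_cont)
    list(cont = idx,
         type = setNames(rep_len(c("modality", "invalid", "not_mni",
                                   "map_type", "thresholded", "filename"),
                                 n_cont), idx),
         tmpl = sample.int(config$n_classes, n, replace = TRUE))
  })
  bad_names <- c("con_%04d.nii.gz", "cope%d.nii.gz",
                 "SetA_mean_%d.nii.gz", "SetB_mean_%d.nii.gz")
  rows <- list(); maps <- list()
  for (i in seq_len(n)) {
    image_id <- pad_id("nvmap", i, 6)
    subject_id <- pad_id("nv_sub", i, 5)
    study_id <- pad_id("nv_study", (i - 1L) %/% 8L + 1L, 4)
    m <- sample_stat_map(templates[[plan$tmpl[i]]], subject_id, study_id,
                         config, mask,
                         seed = derive_seed(config$seed, "map", image_id))
    m$meta$image_id <- image_id
    row <- empty_manifest_row()
    row$image_id <- image_id
    row$subject_id <- subject_id
    row$study_id <- study_id
    row$map_type <- if (i %% 2L == 0L) "T map" else "Z map"
    row$filename <- sprintf("%s_%04d.nii.gz",
                            if (i %% 2L == 0L) "tstat" else "zstat", i)
    row$.contaminant <- FALSE
    if (i %in% plan$cont) {
      row$.contaminant <- TRUE
      switch(plan$type[[as.character(i)]],
        modality = { row$modality <- "dMRI" },
        invalid = { row$is_valid <- FALSE },
        not_mni = { row$not_mni <- TRUE },
        map_type = { row$map_type <- "P map" },
        thresholded = {
          row$thresholded <- TRUE
          cut <- quantile(abs(m$data[mask$data]), 0.7)
          m$data[abs(m$data) < cut] <- 0
        },
        filename = {
          row$filename <- sprintf(bad_names[(i %% 4L) + 1L], i)
        })
    }
    maps[[image_id]] <- m
    rows[[length(rows) + 1L]] <- row
  }
  list(maps = maps, manifest = do.call(rbind, rows))
}

#' Write a collection to disk as NIfTI-1 plus a manifest CSV
#'
#' @param maps named list of [stat_map]s keyed by image id.
#' @param manifest the matching manifest.
#' @param dir output directory (created if needed).
#' @return the manifest with its `path` column filled in, invisibly; also
#'   written to `dir/manifest.csv`.
#' @export
write_collection <- function(maps, manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$image_id[i]
    p <- file.path(dir, paste0(id, ".nii.gz"))
    write_stat_map(maps[[id]], p)
    manifest$path[i] <- p
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a manifest CSV
#'
#' @param path CSV file with the standard manifest columns.
#' @return a manifest `data.frame`.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(MANIFEST_COLS, c("contrast", "task", "concept")),
                     names(m))
  if (length(missing)) stopf("manifest is missing column(s): %s",
                             paste(missing, collapse = ", "))
  m
}
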