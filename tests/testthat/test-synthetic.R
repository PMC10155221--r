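# Synthetic statistic-map generator: determinism, label structure, mask
# closure, nuisance structure, and the contaminant bookkeeping the
# curation filters rely on.

test_that("templates are deterministic and follow the contrast-in-task structure", {
  cfg <- synthetic_config("single_study", n_classes = 23, n_tasks = 7,
                          n_subjects = 2, seed = 9)
  mask <- config_mask(cfg)
  t1 <- make_class_templates(cfg, mask)
  t2 <- make_class_templates(cfg, mask)
  expect_identical(t1, t2)
  expect_length(t1, 23L)
  tasks <- vapply(t1, function(t) t$parent_task, "")
  expect_length(unique(tasks), 7L)
  # classes of one task share that task's blobs
  same_task <- which(tasks == tasks[1])
  expect_identical(t1[[same_task[1]]]$blobs[[1]], t1[[same_task[2]]]$blobs[[1]])
})

test_that("every blob centre lies inside the brain mask", {
  cfg <- tiny_config("single_study", n_classes = 8, n_tasks = 4)
  mask <- config_mask(cfg)
  templates <- make_class_templates(cfg, mask)
  for (tp in templates) for (b in tp$blobs) {
    expect_true(mask$data[b$center[1], b$center[2], b$center[3]])
  }
})

test_that("template generation rejects bad inputs", {
  cfg <- tiny_config("single_study")
  expect_error(synthetic_config("single_study", n_classes = 1), "n_classes")
  expect_error(make_class_templates(cfg, mask = list()), "mask")
})

test_that("no nuisance parameters means identical maps across subjects", {
  cfg <- tiny_config("single_study", subject_shift_sd = 0, subject_gain_sd = 0,
                     study_gain_sd = 0, study_smoothness_jitter = 0,
                     noise_sd = 0)
  mask <- config_mask(cfg)
  tp <- make_class_templates(cfg, mask)[[1]]
  m1 <- sample_stat_map(tp, "sub_a", "study_01", cfg, mask, seed = 1)
  m2 <- sample_stat_map(tp, "sub_b", "study_01", cfg, mask, seed = 2)
  expect_identical(m1$data, m2$data)
})

test_that("noiseless maps correlate perfectly with their re-render", {
  cfg <- tiny_config("single_study", noise_sd = 0)
  mask <- config_mask(cfg)
  tp <- make_class_templates(cfg, mask)[[2]]
  m1 <- sample_stat_map(tp, "sub_x", "study_01", cfg, mask, seed = 5)
  m2 <- sample_stat_map(tp, "sub_x", "study_01", cfg, mask, seed = 99)
  expect_equal(reconstruction_correlation(m1, m2, mask), 1.0, tolerance = 1e-12)
})

test_that("within-class correlation sits between 1 and the cross-class level", {
  cfg <- tiny_config("single_study")
  mask <- config_mask(cfg)
  # two classes with blobs in opposite corners of the mask
  ctr <- dim(mask$data) %/% 2
  ta <- manual_template("a", list(ctr - 4L, ctr - 3L))
  tb <- manual_template("b", list(ctr + 4L, ctr + 3L))
  subjects <- paste0("s", 1:6)
  maps_a <- lapply(subjects, function(s)
    sample_stat_map(ta, s, "study_01", cfg, mask,
                    seed = derive_seed(1, "a", s)))
  maps_b <- lapply(subjects, function(s)
    sample_stat_map(tb, s, "study_01", cfg, mask,
                    seed = derive_seed(1, "b", s)))
  within <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    within <- c(within, reconstruction_correlation(maps_a[[i]], maps_a[[j]], mask))
  }
  cross <- mapply(function(x, y) reconstruction_correlation(x, y, mask),
                  maps_a, maps_b)
  expect_lt(mean(within), 1)
  expect_gt(mean(within), mean(cross))
})

test_that("shifting all blobs outside the grid is a degenerate sample", {
  cfg <- tiny_config("single_study", subject_shift_sd = 0)
  mask <- config_mask(cfg)
  edge <- manual_template("edge", list(c(2L, 2L, 2L)))
  # a subject whose derived shift is forced: rebuild config with a huge
  # shift sd until some subject pushes the single blob out
  cfg2 <- tiny_config("single_study", subject_shift_sd = 40)
  shifted_out <- FALSE
  for (s in paste0("sub_", 1:50)) {
    res <- try(sample_stat_map(edge, s, "study_01", cfg2, mask, seed = 1),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      shifted_out <- TRUE
      expect_match(attr(res, "condition")$message, "degenerate")
      break
    }
  }
  expect_true(shifted_out)
})

test_that("single-study collections contain one map per subject and class", {
  cfg <- tiny_config("single_study", n_subjects = 10, n_classes = 4)
  coll <- generate_labeled_collection(cfg)
  expect_equal(nrow(coll$manifest), 40L)
  expect_length(coll$maps, 40L)
  expect_equal(nrow(unique(coll$manifest[c("subject_id", "contrast")])), 40L)
  expect_false(anyNA(coll$manifest$task))
  # regenerating with the same config gives identical manifests and maps
  coll2 <- generate_labeled_collection(cfg)
  expect_identical(coll$manifest, coll2$manifest)
  expect_identical(coll$maps[[1]]$data, coll2$maps[[1]]$data)
})

test_that("multi-study collections have the expected study structure", {
  cfg <- tiny_config("multi_study", n_studies = 11, subjects_per_study = 4,
                     n_classes = 30)
  coll <- generate_labeled_collection(cfg)
  expect_length(unique(coll$manifest$study_id), 11L)
  expect_false(anyNA(coll$manifest$concept))
  expect_true(all(table(coll$manifest$study_id) > 0))
  # every class covered somewhere, counts imbalanced
  counts <- table(coll$manifest$concept)
  expect_length(counts, 30L)
  expect_gt(max(counts) / min(counts), 1)
  # subjects nested in studies
  sub_study <- unique(coll$manifest[c("subject_id", "study_id")])
  expect_equal(anyDuplicated(sub_study$subject_id), 0L)
})

test_that("multi-study regime requires subjects_per_study", {
  cfg <- tiny_config("multi_study")
  cfg$subjects_per_study <- NULL
  expect_error(generate_labeled_collection(cfg), "subjects_per_study")
})

test_that("every generated map is exactly zero outside the brain mask", {
  coll <- tiny_collection(n_subjects = 3)
  mask <- coll$mask
  for (m in coll$maps) expect_identical(sum(abs(m$data[!mask$data])), 0)
  cfg <- tiny_config("pretraining_corpus", n_maps = 6)
  corp <- generate_pretraining_corpus(cfg)
  for (m in corp$maps) expect_identical(sum(abs(m$data[!config_mask(cfg)$data])), 0)
})

test_that("pretraining corpus marks contaminants that the filter rules catch", {
  cfg <- tiny_config("pretraining_corpus", n_maps = 100,
                     contaminant_fraction = 0.3)
  corp <- generate_pretraining_corpus(cfg)
  mf <- corp$manifest
  expect_equal(sum(mf$.contaminant), 30L)
  # independent row-by-row application of the six inclusion rules
  token_bad <- vapply(mf$filename, function(f) {
    tokens <- strsplit(basename(f), "[^A-Za-z0-9]+")[[1]]
    any(grepl("^(con|cope)[0-9]*$", tokens, ignore.case = TRUE)) ||
      grepl("SetA_mean", f, fixed = TRUE) || grepl("SetB_mean", f, fixed = TRUE)
  }, logical(1))
  clean <- mf$modality == "fMRI-BOLD" & mf$is_valid & !mf$not_mni &
    mf$map_type %in% c("T map", "Z map") & !mf$thresholded & !token_bad
  expect_identical(unname(clean), !mf$.contaminant)
  kept <- filter_metadata(mf)$manifest
  expect_setequal(kept$image_id, mf$image_id[!mf$.contaminant])
})

test_that("contaminant fraction zero keeps the whole corpus", {
  cfg <- tiny_config("pretraining_corpus", n_maps = 20,
                     contaminant_fraction = 0)
  corp <- generate_pretraining_corpus(cfg)
  expect_equal(nrow(filter_metadata(corp$manifest)$manifest), 20L)
  expect_error(tiny_config("pretraining_corpus", contaminant_fraction = 1.5),
               "contaminant_fraction")
})

test_that("thresholded contaminants have mostly exact zeros in-mask", {
  cfg <- tiny_config("pretraining_corpus", n_maps = 60,
                     contaminant_fraction = 0.5, seed = 7)
  corp <- generate_pretraining_corpus(cfg)
  mask <- config_mask(cfg)
  thr <- corp$manifest$image_id[corp$manifest$thresholded]
  expect_gt(length(thr), 0)
  for (id in thr) {
    v <- corp$maps[[id]]$data[mask$data]
    expect_gte(mean(v == 0), 0.5)
  }
})

test_that("corpus and labelled in-mask value distributions overlap", {
  cfg_l <- tiny_config("single_study", n_subjects = 4)
  cfg_c <- tiny_config("pretraining_corpus", n_maps = 20, seed = 3)
  mask <- config_mask(cfg_l)
  coll <- generate_labeled_collection(cfg_l)
  corp <- generate_pretraining_corpus(cfg_c)
  keep <- !corp$manifest$.contaminant
  vals_l <- unlist(lapply(coll$maps, function(m) m$data[mask$data]))
  vals_c <- unlist(lapply(corp$maps[keep], function(m) m$data[mask$data]))
  ks <- suppressWarnings(stats::ks.test(sample(vals_l, 4000), sample(vals_c, 4000)))
  expect_lt(unname(ks$statistic), 0.2)
})

test_that("a nearest-template assignment recovers labels on default settings", {
  cfg <- synthetic_config("single_study", n_subjects = 5, seed = 21)
  mask <- config_mask(cfg)
  templates <- make_class_templates(cfg, mask)
  coll <- generate_labeled_collection(cfg)
  renders <- lapply(templates, function(tp)
    stldecode:::render_template(tp, cfg$grid_shape, mask)[mask$data])
  correct <- 0L
  for (i in seq_len(nrow(coll$manifest))) {
    v <- coll$maps[[coll$manifest$image_id[i]]]$data[mask$data]
    rs <- vapply(renders, function(r) cor(v, r), numeric(1))
    pred <- templates[[which.max(rs)]]$class_id
    if (pred == coll$manifest$contrast[i]) correct <- correct + 1L
  }
  expect_gte(correct / nrow(coll$manifest), 0.9)
})

test_that("collections round-trip through NIfTI and manifest CSV", {
  coll <- tiny_collection(n_subjects = 2, n_classes = 3, n_tasks = 3)
  dir <- withr::local_tempdir()
  mf <- write_collection(coll$maps, coll$manifest, dir)
  expect_true(all(file.exists(mf$path)))
  back <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(back), nrow(mf))
  m <- read_stat_map(back$path[1])
  expect_equal(m$data, coll$maps[[back$image_id[1]]]$data, tolerance = 1e-6)
  expect_equal(m$affine, coll$maps[[back$image_id[1]]]$affine, tolerance = 1e-5)
})
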