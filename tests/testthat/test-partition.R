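# Subject-wise splits: holdout, k-fold assignment, nested subsamples,
# multi-study fold combination, and the global no-leakage guarantee.

subjects_n <- function(n) sprintf("sub_%03d", seq_len(n))

fake_manifest <- function(subjects, maps_per_subject = 3,
                          study = "study_01") {
  do.call(rbind, lapply(subjects, function(s) data.frame(
    image_id = paste0(s, "_m", seq_len(maps_per_subject)),
    subject_id = s, study_id = study, stringsAsFactors = FALSE)))
}

test_that("the subject holdout is a disjoint partition with no map overlap", {
  mf <- fake_manifest(subjects_n(100))
  h <- split_holdout_by_subject(mf, 0.5, seed = 2)
  expect_length(h$validation_subjects, 50L)
  expect_length(h$test_subjects, 50L)
  expect_length(intersect(h$validation_subjects, h$test_subjects), 0L)
  val_maps <- mf$image_id[mf$subject_id %in% h$validation_subjects]
  test_maps <- mf$image_id[mf$subject_id %in% h$test_subjects]
  expect_length(intersect(val_maps, test_maps), 0L)
  expect_identical(h, split_holdout_by_subject(mf, 0.5, seed = 2))
  mf$subject_id[3] <- NA
  expect_error(split_holdout_by_subject(mf, 0.5, 1), "subject_id")
})

test_that("fold assignment balances fold sizes to within one subject", {
  p <- assign_subject_folds(subjects_n(10), k = 5, seed = 1)
  expect_equal(as.integer(table(p$assignment)), rep(2L, 5))
  p <- assign_subject_folds(subjects_n(393), k = 5, seed = 1)
  sizes <- as.integer(table(p$assignment))
  expect_true(all(sizes %in% c(78L, 79L)))
  expect_equal(sum(sizes), 393L)
  expect_setequal(names(p$assignment), subjects_n(393))
  expect_error(assign_subject_folds(subjects_n(3), k = 5), "folds")
})

test_that("nested subsamples preserve fold indices and form a chain", {
  parent <- assign_subject_folds(subjects_n(250), k = 5, seed = 8)
  plans <- nested_subsample_folds(parent, c(200, 100, 50), seed = 8)
  expect_named(plans, c("200", "100", "50"))
  for (nm in names(plans)) {
    pl <- plans[[nm]]
    expect_length(pl$assignment, as.integer(nm))
    expect_equal(as.integer(table(pl$assignment)), rep(as.integer(nm) / 5L, 5))
  }
  # chain: 50 within 100 within 200 within parent, same fold index
  s50 <- names(plans[["50"]]$assignment)
  expect_true(all(s50 %in% names(plans[["100"]]$assignment)))
  expect_identical(plans[["50"]]$assignment,
                   plans[["100"]]$assignment[s50])
  s100 <- names(plans[["100"]]$assignment)
  expect_true(all(s100 %in% names(plans[["200"]]$assignment)))
  expect_identical(plans[["200"]]$assignment[s100],
                   plans[["100"]]$assignment)
  expect_identical(parent$assignment[s50], plans[["50"]]$assignment)
  expect_error(nested_subsample_folds(parent, c(100, 200), 1), "decreasing")
  expect_error(nested_subsample_folds(parent, c(100, 47)), "divisible")
})

test_that("the nesting chain and leakage audit hold across many seeds", {
  mf <- fake_manifest(subjects_n(60), maps_per_subject = 2)
  for (seed in 1:20) {
    parent <- assign_subject_folds(unique(mf$subject_id), k = 5, seed = seed)
    plans <- nested_subsample_folds(parent, c(40, 20), seed = seed)
    for (pl in plans) {
      expect_identical(parent$assignment[names(pl$assignment)], pl$assignment)
      for (f in 0:4) {
        sp <- cv_split(pl, parent, f, mf)
        expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0L)
      }
    }
  }
})

test_that("cv_split trains on the subsample and tests on the global fold", {
  mf <- fake_manifest(subjects_n(50), maps_per_subject = 1)
  parent <- assign_subject_folds(subjects_n(50), k = 5, seed = 4)
  sp <- cv_split(parent, parent, 0, mf)
  expect_equal(nrow(sp$train), 40L)   # ~80% of maps
  expect_equal(nrow(sp$test), 10L)
  small <- nested_subsample_folds(parent, 25, seed = 4)[["25"]]
  sp <- cv_split(small, parent, 2, mf)
  expect_equal(nrow(sp$train), 20L)   # 4 folds x 5 subjects
  expect_equal(nrow(sp$test), 10L)    # the full global fold
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0L)
  expect_error(cv_split(parent, parent, 5, mf), "fold_i")
  # a plan that is not nested in the global plan is a leakage error
  other <- assign_subject_folds(subjects_n(50), k = 5, seed = 99)
  if (!identical(other$assignment, parent$assignment)) {
    expect_error(cv_split(other, parent, 0, mf), "leakage")
  }
})

test_that("study-scoped folds combine every study into every fold", {
  mf <- do.call(rbind, lapply(1:4, function(s)
    fake_manifest(sprintf("st%d_sub%02d", s, 1:10), 2, paste0("study_", s))))
  plans <- combine_study_folds(mf, k = 5, seed = 6)
  for (side in plans) {
    expect_length(side$assignment, 20L)          # 5 subjects/study/side
    expect_equal(as.integer(table(side$assignment)), rep(4L, 5))
    studies <- mf$study_id[match(names(side$assignment), mf$subject_id)]
    # every fold contains one subject of every study
    tab <- table(studies, side$assignment)
    expect_true(all(tab == 1L))
  }
  expect_length(intersect(names(plans$validation$assignment),
                          names(plans$test$assignment)), 0L)
  expect_identical(combine_study_folds(mf, k = 5, seed = 6)$test$assignment,
                   plans$test$assignment)
})

test_that("a single study reduces to holdout plus fold assignment", {
  mf <- fake_manifest(subjects_n(20))
  plans <- combine_study_folds(mf, k = 5, seed = 3)
  expect_length(plans$validation$assignment, 10L)
  expect_length(plans$test$assignment, 10L)
  expect_setequal(c(names(plans$validation$assignment),
                    names(plans$test$assignment)), subjects_n(20))
})

test_that("tiny studies trigger a warning and fall into one subdataset", {
  mf <- rbind(fake_manifest(subjects_n(10), 1, "study_big"),
              fake_manifest("lonely_sub", 1, "study_tiny"))
  expect_warning(plans <- combine_study_folds(mf, k = 5, seed = 1),
                 "fewer than 2")
  expect_true("lonely_sub" %in% names(plans$validation$assignment))
})

test_that("the small multi-study extraction keeps large studies at fixed depth", {
  mf <- do.call(rbind, lapply(1:3, function(s)
    fake_manifest(sprintf("st%d_sub%02d", s, 1:30), 1, paste0("study_", s))))
  # plus one small study that must be dropped
  mf <- rbind(mf, fake_manifest(sprintf("st9_sub%02d", 1:10), 1, "study_9"))
  plans <- combine_study_folds(mf, k = 5, seed = 5)
  small <- extract_small_multistudy(plans$validation, plans$test, mf,
                                    min_subjects = 20, per_fold = 2, seed = 5)
  for (side in c("validation", "test")) {
    pl <- small[[side]]
    studies <- mf$study_id[match(names(pl$assignment), mf$subject_id)]
    expect_setequal(unique(studies), paste0("study_", 1:3))
    expect_equal(as.integer(table(studies)), rep(10L, 3))  # 2 x 5 folds
    # fold indices preserved from the input plan
    expect_identical(plans[[side]]$assignment[names(pl$assignment)],
                     pl$assignment)
  }
  # per_fold equal to the input fold size reproduces the kept studies
  full <- extract_small_multistudy(plans$validation, plans$test, mf,
                                   min_subjects = 20, per_fold = 3, seed = 5)
  expect_length(full$test$assignment, 45L)
})

test_that("fold plans survive a JSON round trip", {
  plan <- assign_subject_folds(subjects_n(17), k = 5, seed = 12,
                               subdataset = "validation")
  path <- withr::local_tempfile(fileext = ".json")
  write_fold_plan(plan, path)
  back <- read_fold_plan(path)
  expect_identical(back$assignment, plan$assignment)
  expect_identical(back$k, plan$k)
  expect_identical(back$subdataset, plan$subdataset)
})
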