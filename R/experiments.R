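# Experiment orchestration: pretraining with reconstruction reporting,
# default-vs-pretrained comparisons across sample sizes and targets,
# transfer-depth and freezing sweeps, and the reference small-sample
# benefit benchmark. All stage seeds derive from one master seed.

#' Preprocess every map of a collection onto the analysis grid
#'
#' @param maps named list of [stat_map]s.
#' @param mask a [brain_mask] on the target grid.
#' @return named list of preprocessed maps.
#' @export
preprocess_collection <- function(maps, mask) {
  lapply(maps, preprocess_map, mask = mask)
}

#' Curate, preprocess and pretrain autoencoders on an unlabelled corpus
#'
#' Applies the metadata inclusion filters, preprocesses the surviving
#' maps, splits them 80/20 at the map level, trains one CAE per requested
#' architecture and reports the mean in-mask reconstruction correlation
#' (with SEM across test maps) on the held-out 20%.
#'
#' @param corpus `list(maps, manifest)` as returned by
#'   [generate_pretraining_corpus], or a curated manifest plus maps.
#' @param mask a [brain_mask] on the analysis grid.
#' @param architectures encoder depths to pretrain.
#' @param width_multiplier channel scale.
#' @param epochs,batch_size,learning_rate training controls.
#' @param train_fraction map-level pretraining split.
#' @param seed master seed for the stage.
#' @return list with `cae_models` (named by depth), `report` (one row per
#'   architecture: `model`, `latent`, `mean_r`, `sem_r`, `n_test`),
#'   `filter_report`, `histories`, and the train/test manifests.
#' @export
run_pretraining <- function(corpus, mask, architectures = c(4L, 5L),
                            width_multiplier = 1, epochs = 200L,
                            batch_size = 32L, learning_rate = 1e-4,
                            train_fraction = 0.8, seed = 1L) {
  flt <- filter_metadata(corpus$manifest)
  if (nrow(flt$manifest) == 0) stopf("corpus is empty after metadata filtering")
  kept <- preprocess_collection(corpus$maps[flt$manifest$image_id], mask)
  sp <- split_pretraining(flt$manifest, train_fraction,
                          seed = derive_seed(seed, "pretrain_split"))
  input_grid <- dim(mask$data)
  cae_models <- list(); histories <- list(); rows <- NULL
  for (arch in architectures) {
    spec <- architecture_spec(arch, width_multiplier, input_grid)
    cae <- default_init(build_cae(spec), derive_seed(seed, "cae_init", arch))
    cfg <- train_config(learning_rate, batch_size, epochs, "mse",
                        seed = derive_seed(seed, "cae_train", arch))
    fit <- train_cae(cae, kept[sp$train$image_id], cfg)
    recon <- reconstruct_cae(fit$model, kept[sp$test$image_id])
    rs <- vapply(seq_len(nrow(sp$test)), function(i) {
      reconstruction_correlation(kept[[sp$test$image_id[i]]]$data,
                                 recon[, , , 1, i], mask)
    }, numeric(1))
    s <- summarize_folds(rs)
    cae_models[[as.character(arch)]] <- fit$model
    histories[[as.character(arch)]] <- fit$history
    rows <- rbind(rows, data.frame(
      model = sprintf("%d layers", arch), latent = spec$latent_dim,
      mean_r = s$mean, sem_r = s$sem, n_test = length(rs)))
  }
  list(cae_models = cae_models, report = rows, filter_report = flt$report,
       histories = histories, train = sp$train, test = sp$test)
}

# Train one classifier and evaluate it on one cross-validation fold.
comparison_fold <- function(manifest, maps, label_col, levels, plan,
                            global_plan, fold_i, init, cae, spec,
                            epochs, batch_size, learning_rate, seed,
                            transfer_cfg = NULL) {
  sp <- cv_split(plan, global_plan, fold_i, manifest)
  cnn <- default_init(build_cnn(spec, length(levels)),
                      derive_seed(seed, "init", init, fold_i))
  if (init == "pretrained") {
    cfg <- transfer_cfg %||% transfer_config(spec$n_layers)
    cnn <- transfer_weights(cae, cnn, cfg)
  }
  tc <- train_config(learning_rate, batch_size, epochs, "cross_entropy",
                     seed = derive_seed(seed, "train", init, fold_i))
  fit <- train_classifier(cnn, maps[sp$train$image_id],
                          encode_labels(sp$train[[label_col]], levels), tc)
  probs <- predict_cnn(fit$model, maps[sp$test$image_id])
  pred <- max.col(t(probs)) - 1L
  list(metrics = classification_metrics(
         encode_labels(sp$test[[label_col]], levels), pred, length(levels)),
       model = fit$model, test = sp$test)
}

# Representative contrast per task: the first contrast (by sort order)
# observed for each task, unless an explicit mapping is supplied.
one_contrast_subset <- function(manifest, representative = NULL) {
  if (is.null(representative)) {
    agg <- manifest[order(manifest$task, manifest$contrast), ]
    representative <- tapply(agg$contrast, agg$task, function(x) sort(x)[1])
  }
  keep <- manifest$contrast == unname(representative[manifest$task])
  manifest[keep, , drop = FALSE]
}

#' Compare default and pretrained initialisations across conditions
#'
#' Runs the subject-wise 5-fold comparison: training folds
#' come from the (possibly subsampled) plan, the test fold always from the
#' global plan, so train and test subjects never overlap. For each
#' (target, size) cell both initialisations are trained per fold and a
#' paired one-tailed t-test (pretrained > default) is computed on the
#' per-fold accuracies.
#'
#' @param manifest labelled manifest (one subdataset, e.g. the test side
#'   of a holdout).
#' @param maps named list of preprocessed maps.
#' @param targets classification targets: any of `"contrast"`, `"task"`,
#'   `"one_contrast_task"`, `"concept"`.
#' @param plans named list of [fold_plan]s to train on (e.g. sizes
#'   `"50"`, `"100"`); names label the `size` column.
#' @param global_plan the superset plan providing test folds.
#' @param cae trained `stl_cae` for the pretrained mode.
#' @param init_modes subset of `c("default", "pretrained")`.
#' @param width_multiplier,epochs,batch_size,learning_rate training
#'   controls.
#' @param representative_contrasts optional named vector task ->
#'   contrast for the one-contrast target.
#' @param seed master seed.
#' @return list with `table` (per-cell mean/SEM metrics), `tests`
#'   (per-cell paired t-test), and `per_fold` accuracies.
#' @export
run_comparison <- function(manifest, maps, targets, plans, global_plan,
                           cae = NULL, init_modes = c("default", "pretrained"),
                           width_multiplier = 1, epochs = 30L,
                           batch_size = 32L, learning_rate = 1e-4,
                           representative_contrasts = NULL, seed = 1L) {
  if ("pretrained" %in% init_modes && is.null(cae))
    stopf("pretrained mode requires a trained CAE")
  input_grid <- dim(maps[[1]]$data)
  rows <- NULL; tests <- NULL; per_fold <- list()
  for (target in targets) {
    mf <- manifest
    label_col <- switch(target,
      contrast = "contrast", task = "task", concept = "concept",
      one_contrast_task = {
        mf <- one_contrast_subset(manifest, representative_contrasts)
        "task"
      },
      stopf("unknown target '%s'", target))
    levels <- sort(unique(mf[[label_col]]))
    spec <- architecture_spec(if (!is.null(cae)) cae$spec$n_layers else 4L,
                              width_multiplier, input_grid)
    for (size in names(plans)) {
      plan <- plans[[size]]
      acc <- list()
      for (init in init_modes) {
        k <- plan$k
        accs <- f1s <- numeric(k)
        for (f in seq_len(k) - 1L) {
          res <- comparison_fold(mf, maps, label_col, levels, plan,
                                 global_plan, f, init, cae, spec, epochs,
                                 batch_size, learning_rate,
                                 derive_seed(seed, target, size))
          accs[f + 1L] <- res$metrics$accuracy
          f1s[f + 1L] <- res$metrics$f1_macro
        }
        acc[[init]] <- accs
        sa <- summarize_folds(accs); sf <- summarize_folds(f1s)
        rows <- rbind(rows, data.frame(
          target = target, size = size, init = init,
          mean_acc = sa$mean, sem_acc = sa$sem,
          mean_f1 = sf$mean, sem_f1 = sf$sem))
        per_fold[[paste(target, size, init, sep = "/")]] <- accs
      }
      if (all(c("default", "pretrained") %in% names(acc))) {
        tt <- paired_onetailed_ttest(acc$pretrained, acc$default, "greater")
        tests <- rbind(tests, data.frame(
          target = target, size = size, t = tt$t, p = tt$p, dof = tt$dof))
      }
    }
  }
  list(table = rows, tests = tests, per_fold = per_fold)
}

#' Transfer-depth sweep
#'
#' Trains classifiers whose first `n` conv blocks are initialised from the
#' pretrained encoder, for `n` from 0 (pure default initialisation) up to
#' the full encoder, and reports mean accuracy with SEM over folds.
#'
#' @inheritParams run_comparison
#' @param label_col manifest column with the class labels.
#' @param plan,global_plan fold plans.
#' @return a `data.frame` with one row per transfer depth
#'   (`n_transferred`, `label`, `mean_acc`, `sem_acc`).
#' @export
run_transfer_sweep <- function(manifest, maps, label_col, plan, global_plan,
                               cae, width_multiplier = 1, epochs = 30L,
                               batch_size = 32L, learning_rate = 1e-4,
                               seed = 1L) {
  n_layers <- cae$spec$n_layers
  levels <- sort(unique(manifest[[label_col]]))
  spec <- architecture_spec(n_layers, width_multiplier, dim(maps[[1]]$data))
  rows <- NULL
  for (n_tr in 0:n_layers) {
    accs <- numeric(plan$k)
    for (f in seq_len(plan$k) - 1L) {
      init <- if (n_tr == 0) "default" else "pretrained"
      res <- comparison_fold(manifest, maps, label_col, levels, plan,
                             global_plan, f, init, cae, spec, epochs,
                             batch_size, learning_rate,
                             derive_seed(seed, "transfer", n_tr),
                             transfer_cfg = transfer_config(n_tr))
      accs[f + 1L] <- res$metrics$accuracy
    }
    s <- summarize_folds(accs)
    rows <- rbind(rows, data.frame(
      n_transferred = n_tr,
      label = if (n_tr == 0) "0 (default initialization)"
              else if (n_tr == n_layers) "full pretrained model"
              else as.character(n_tr),
      mean_acc = s$mean, sem_acc = s$sem))
  }
  rows
}

#' Layer-freezing sweep
#'
#' Fine-tunes fully pretrained classifiers with the first 2 up to all
#' encoder blocks frozen, asserting after each fold that frozen parameters
#' did not drift.
#'
#' @inheritParams run_transfer_sweep
#' @return a `data.frame` with one row per freeze depth (`n_frozen`,
#'   `mean_acc`, `sem_acc`, `max_drift`).
#' @export
run_freeze_sweep <- function(manifest, maps, label_col, plan, global_plan,
                             cae, width_multiplier = 1, epochs = 30L,
                             batch_size = 32L, learning_rate = 1e-4,
                             seed = 1L) {
  n_layers <- cae$spec$n_layers
  levels <- sort(unique(manifest[[label_col]]))
  spec <- architecture_spec(n_layers, width_multiplier, dim(maps[[1]]$data))
  rows <- NULL
  for (n_fr in 2:n_layers) {
    accs <- numeric(plan$k)
    drift <- 0
    for (f in seq_len(plan$k) - 1L) {
      res <- comparison_fold(manifest, maps, label_col, levels, plan,
                             global_plan, f, "pretrained", cae, spec, epochs,
                             batch_size, learning_rate,
                             derive_seed(seed, "freeze", n_fr),
                             transfer_cfg = transfer_config(n_layers, n_fr))
      for (i in seq_len(n_fr)) {
        drift <- max(drift,
                     max(abs(res$model$params$encoder[[i]]$W -
                             cae$params$encoder[[i]]$W)),
                     max(abs(res$model$params$encoder[[i]]$b -
                             cae$params$encoder[[i]]$b)))
      }
      accs[f + 1L] <- res$metrics$accuracy
    }
    if (drift > 0) stopf("frozen parameters drifted by %g during training", drift)
    s <- summarize_folds(accs)
    rows <- rbind(rows, data.frame(n_frozen = n_fr, mean_acc = s$mean,
                                   sem_acc = s$sem, max_drift = drift))
  }
  rows
}

#' Reference small-sample benefit benchmark
#'
#' The package's desk-scale analogue of the published small-sample
#' experiment: a single-study synthetic collection with 23 contrasts in 7
#' tasks, 20 training subjects and 5 held-out test subjects per
#' repetition, quarter-width 5-layer models (the depth that benefits most
#' from self-taught learning) trained for 30 epochs. One CAE is pretrained
#' on a curated synthetic corpus and its encoder transferred into the
#' classifier; for each repetition both initialisations are trained on
#' identical data and compared on (a) test accuracy and (b) mean layer-3
#' between-subject feature correlation per class.
#'
#' @param seeds repetition indices (default 3 repetitions).
#' @param master_seed master seed; all stage seeds derive from it.
#' @param n_classes,n_tasks,n_subjects,train_fraction collection shape.
#' @param n_layers encoder depth used for both initialisations.
#' @param width_multiplier,epochs,batch_size,learning_rate training
#'   controls.
#' @param corpus_maps,contaminant_fraction pretraining corpus shape.
#' @param cae_epochs,cae_batch_size,cae_learning_rate CAE pretraining
#'   controls, calibrated at desk scale for a held-out reconstruction
#'   plateau on the small corpus.
#' @param feature_layer encoder block used for the correlation analysis.
#' @param cae optionally a pre-trained `stl_cae` to reuse.
#' @param verbose print progress lines.
#' @return list with `per_seed` (one row per repetition and init),
#'   `mean_acc` (named: default, pretrained), `feature_fraction_higher`
#'   (fraction of (repetition, class) cells where the pretrained model has
#'   the higher mean feature correlation), `feature_per_seed`, and the
#'   `cae` used.
#' @export
benefit_benchmark <- function(seeds = 1:3, master_seed = 7L,
                              n_classes = 23L, n_tasks = 7L,
                              n_subjects = 25L, train_fraction = 0.8,
                              n_layers = 5L,
                              width_multiplier = 0.25, epochs = 30L,
                              batch_size = 32L, learning_rate = 1e-4,
                              corpus_maps = 100L, contaminant_fraction = 0.25,
                              cae_epochs = 150L, cae_batch_size = 8L,
                              cae_learning_rate = 1e-3, feature_layer = 3L,
                              cae = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  grid <- default_grid()
  mask <- ellipsoid_mask(grid)
  if (is.null(cae)) {
    say("pretraining CAE on synthetic corpus (%d maps)", corpus_maps)
    corpus <- generate_pretraining_corpus(synthetic_config(
      "pretraining_corpus", n_maps = corpus_maps,
      contaminant_fraction = contaminant_fraction,
      seed = derive_seed(master_seed, "corpus")))
    pre <- run_pretraining(corpus, mask, architectures = n_layers,
                           width_multiplier = width_multiplier,
                           epochs = cae_epochs, batch_size = cae_batch_size,
                           learning_rate = cae_learning_rate,
                           seed = derive_seed(master_seed, "pretrain"))
    cae <- pre$cae_models[[as.character(n_layers)]]
  }
  spec <- architecture_spec(n_layers, width_multiplier, grid)
  per_seed <- NULL; feat_rows <- NULL
  for (s in seeds) {
    say("repetition %d: generating collection", s)
    coll <- generate_labeled_collection(synthetic_config(
      "single_study", n_classes = n_classes, n_tasks = n_tasks,
      n_subjects = n_subjects,
      seed = derive_seed(master_seed, "collection", s)))
    maps <- preprocess_collection(coll$maps, mask)
    hold <- split_holdout_by_subject(coll$manifest, train_fraction,
                                     seed = derive_seed(master_seed, "holdout", s))
    train_mf <- coll$manifest[coll$manifest$subject_id %in%
                                hold$validation_subjects, ]
    test_mf <- coll$manifest[coll$manifest$subject_id %in%
                               hold$test_subjects, ]
    levels <- sort(unique(coll$manifest$contrast))
    models <- list()
    for (init in c("default", "pretrained")) {
      say("repetition %d: training %s classifier", s, init)
      cnn <- default_init(build_cnn(spec, length(levels)),
                          derive_seed(master_seed, "init", init, s))
      if (init == "pretrained")
        cnn <- transfer_weights(cae, cnn, transfer_config(spec$n_layers))
      cfg <- train_config(learning_rate, batch_size, epochs, "cross_entropy",
                          seed = derive_seed(master_seed, "train", init, s))
      fit <- train_classifier(cnn, maps[train_mf$image_id],
                              encode_labels(train_mf$contrast, levels), cfg)
      probs <- predict_cnn(fit$model, maps[test_mf$image_id])
      pred <- max.col(t(probs)) - 1L
      m <- classification_metrics(encode_labels(test_mf$contrast, levels),
                                  pred, length(levels))
      models[[init]] <- fit$model
      per_seed <- rbind(per_seed, data.frame(
        seed = s, init = init, accuracy = m$accuracy, f1_macro = m$f1_macro))
    }
    for (cl in levels) {
      sub <- test_mf[test_mf$contrast == cl, ]
      by_subj <- setNames(maps[sub$image_id], sub$subject_id)
      rs <- vapply(models, function(mdl) {
        between_subject_feature_correlation(mdl, by_subj, feature_layer)$mean_r
      }, numeric(1))
      feat_rows <- rbind(feat_rows, data.frame(
        seed = s, class = cl, default_r = rs[["default"]],
        pretrained_r = rs[["pretrained"]]))
    }
  }
  mean_acc <- tapply(per_seed$accuracy, per_seed$init, mean)
  list(per_seed = per_seed,
       mean_acc = c(default = unname(mean_acc[["default"]]),
                    pretrained = unname(mean_acc[["pretrained"]])),
       feature_fraction_higher = mean(feat_rows$pretrained_r >
                                        feat_rows$default_r),
       feature_per_seed = feat_rows,
       cae = cae)
}
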