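# Training: Adam optimisation of CAEs (mean squared reconstruction error)
# and classifiers (cross-entropy), plus the hyperparameter grid search.
#
# No learning-rate schedule, weight decay, early stopping or augmentation
# is used; final-epoch parameters are the trained model. Batches are
# reshuffled each epoch with a per-epoch derived seed, so (seed, config,
# data) fully determine the run on a fixed device.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-4, all other Adam
#'   parameters at their conventional defaults).
#' @param batch_size minibatch size (the reference grid uses 32 or 64).
#' @param epochs number of passes over the training set.
#' @param loss `"mse"` for autoencoders, `"cross_entropy"` for
#'   classifiers.
#' @param seed integer seed controlling initial shuffling and batch order.
#' @param shuffle reshuffle map order each epoch.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 32L,
                         epochs = 200L, loss = c("mse", "cross_entropy"),
                         seed = 1L, shuffle = TRUE) {
  loss <- match.arg(loss)
  if (learning_rate <= 0) stopf("'learning_rate' must be positive")
  if (batch_size < 1) stopf("'batch_size' must be at least 1")
  if (epochs < 1) stopf("'epochs' must be at least 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss = loss,
                 seed = as.integer(seed), shuffle = isTRUE(shuffle)),
            class = "train_config")
}

# Per-epoch batch orders; the shuffle stream derives from the config seed
# so (seed, config, data) fully determine a run.
epoch_orders <- function(n, epochs, shuffle, seed) {
  lapply(seq_len(epochs), function(e) {
    if (shuffle) with_seed(derive_seed(seed, "epoch", e), sample.int(n))
    else seq_len(n)
  })
}

#' Train a convolutional autoencoder
#'
#' Minimises the mean squared reconstruction error with Adam. The
#' per-epoch mean loss is recorded; a non-finite loss aborts with the
#' epoch index.
#'
#' @param model an initialised `stl_cae`.
#' @param maps training maps: list of preprocessed [stat_map]s or a 5-d
#'   array.
#' @param cfg a [train_config] with `loss = "mse"`.
#' @return `list(model, history)` where `history` is a `data.frame` with
#'   columns `epoch` and `loss`.
#' @export
train_cae <- function(model, maps, cfg) {
  if (cfg$loss != "mse") stopf("autoencoder training requires loss = 'mse'")
  x <- as_batch_array(maps)
  n <- dim(x)[5]
  spec <- model$spec
  orders <- epoch_orders(n, cfg$epochs, cfg$shuffle, cfg$seed)
  res <- cpp_cae_train(x, model$params$encoder, model$params$decoder,
                       spec$negative_slope, spec$stride, spec$pad,
                       if (spec$output_activation == "tanh") 0L else 1L,
                       cfg$learning_rate, cfg$batch_size, orders)
  model$params$encoder <- res$encoder
  model$params$decoder <- res$decoder
  list(model = model, history = data.frame(epoch = seq_len(cfg$epochs),
                                           loss = res$history))
}

#' Train a convolutional classifier
#'
#' Minimises cross-entropy with Adam. Labels are integer-coded in
#' `0..n_classes-1`. Blocks frozen with [freeze_prefix()] receive no
#' updates and their batch-norm layers run in inference mode.
#'
#' @param model an initialised (possibly weight-transferred) `stl_cnn`.
#' @param maps training maps: list of preprocessed [stat_map]s or 5-d
#'   array.
#' @param labels integer vector, one label per map.
#' @param cfg a [train_config] with `loss = "cross_entropy"`.
#' @return `list(model, history)`.
#' @export
train_classifier <- function(model, maps, labels, cfg) {
  if (cfg$loss != "cross_entropy")
    stopf("classifier training requires loss = 'cross_entropy'")
  x <- as_batch_array(maps)
  n <- dim(x)[5]
  labels <- as.integer(labels)
  if (length(labels) != n) stopf("need one label per map")
  if (any(labels < 0 | labels >= model$n_classes))
    stopf("labels must lie in 0..%d", model$n_classes - 1)
  spec <- model$spec
  orders <- epoch_orders(n, cfg$epochs, cfg$shuffle, cfg$seed)
  res <- cpp_cnn_train(x, labels, model$params$encoder, model$params$dense,
                       model$frozen, spec$negative_slope, spec$stride,
                       spec$pad, cfg$learning_rate, cfg$batch_size, orders)
  model$params$encoder <- res$encoder
  model$params$dense <- res$dense
  list(model = model, history = data.frame(epoch = seq_len(cfg$epochs),
                                           loss = res$history))
}

#' Hyperparameter grid
#'
#' @param architectures encoder depths to compare.
#' @param batch_sizes,epoch_options candidate batch sizes and epoch
#'   counts.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(architectures = c(4L, 5L), batch_sizes = c(32L, 64L),
                      epoch_options = c(200L, 500L)) {
  if (!length(architectures) || !length(batch_sizes) || !length(epoch_options))
    stopf("grid sets must be nonempty")
  structure(list(architectures = as.integer(architectures),
                 batch_sizes = as.integer(batch_sizes),
                 epoch_options = as.integer(epoch_options)),
            class = "grid_spec")
}

#' Grid search over architecture, batch size and epochs
#'
#' Trains one classifier per grid cell per validation fold (k-fold on the
#' validation plan), reports per-cell mean accuracy and macro F1 with
#' standard errors, and returns the best cell (highest mean accuracy, ties
#' broken by mean F1).
#'
#' @param manifest labelled manifest of the validation dataset.
#' @param maps named list of preprocessed [stat_map]s keyed by image id.
#' @param label_col manifest column holding the class labels.
#' @param init_mode `"default"` or `"pretrained"`.
#' @param grid a [grid_spec].
#' @param validation_plan a [fold_plan] on the validation subjects.
#' @param cae_models named list of trained `stl_cae`s keyed by
#'   architecture depth (`"4"`, `"5"`); required in pretrained mode.
#' @param width_multiplier channel scale for the trained models.
#' @param learning_rate,seed training controls.
#' @return `list(best, report)`: the best cell as a one-row `data.frame`,
#'   and the full report with columns `init`, `model`, `epochs`, `batch`,
#'   `mean_acc`, `sem_acc`, `mean_f1`, `sem_f1`.
#' @export
hyperparameter_search <- function(manifest, maps, label_col, init_mode,
                                  grid = grid_spec(), validation_plan,
                                  cae_models = NULL, width_multiplier = 1,
                                  learning_rate = 1e-4, seed = 1L) {
  init_mode <- match.arg(init_mode, c("default", "pretrained"))
  levels <- sort(unique(manifest[[label_col]]))
  grid_rows <- expand.grid(model = grid$architectures,
                           epochs = grid$epoch_options,
                           batch = grid$batch_sizes)
  input_grid <- dim(maps[[1]]$data)
  report <- NULL
  for (r in seq_len(nrow(grid_rows))) {
    arch <- grid_rows$model[r]
    if (init_mode == "pretrained" && is.null(cae_models[[as.character(arch)]]))
      stopf("pretrained mode requires a CAE checkpoint for the %d-layer architecture", arch)
    accs <- f1s <- numeric(validation_plan$k)
    for (f in seq_len(validation_plan$k) - 1L) {
      sp <- cv_split(validation_plan, validation_plan, f, manifest)
      spec <- architecture_spec(arch, width_multiplier, input_grid)
      cnn <- default_init(build_cnn(spec, length(levels)),
                          derive_seed(seed, "init", r, f))
      if (init_mode == "pretrained") {
        cnn <- transfer_weights(cae_models[[as.character(arch)]], cnn,
                                transfer_config(spec$n_layers))
      }
      cfg <- train_config(learning_rate, grid_rows$batch[r],
                          grid_rows$epochs[r], "cross_entropy",
                          seed = derive_seed(seed, "train", r, f))
      fit <- train_classifier(cnn, maps[sp$train$image_id],
                              encode_labels(sp$train[[label_col]], levels),
                              cfg)
      probs <- predict_cnn(fit$model, maps[sp$test$image_id])
      pred <- max.col(t(probs)) - 1L
      m <- classification_metrics(encode_labels(sp$test[[label_col]], levels),
                                  pred, length(levels))
      accs[f + 1L] <- m$accuracy
      f1s[f + 1L] <- m$f1_macro
    }
    report <- rbind(report, data.frame(
      init = init_mode, model = arch, epochs = grid_rows$epochs[r],
      batch = grid_rows$batch[r],
      mean_acc = mean(accs), sem_acc = summarize_folds(accs)$sem,
      mean_f1 = mean(f1s), sem_f1 = summarize_folds(f1s)$sem
    ))
  }
  ord <- order(-report$mean_acc, -report$mean_f1)
  list(best = report[ord[1], , drop = FALSE], report = report)
}

#' Integer-code labels against a fixed level set
#'
#' @param values label values.
#' @param levels the complete, ordered level set.
#' @return integer codes in `0..length(levels)-1`.
#' @export
encode_labels <- function(values, levels) {
  codes <- match(values, levels) - 1L
  if (anyNA(codes)) stopf("label value not in the provided level set")
  codes
}
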