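# Training behaviour: loss definitions, convergence on easy problems,
# determinism, freezing, and the hyperparameter grid.

test_that("the recorded autoencoder loss is the mean squared error", {
  spec <- architecture_spec(4, 0.05, tiny_grid())
  cae <- default_init(build_cae(spec), 2)
  x <- array(rnorm(prod(tiny_grid()) * 4, sd = 0.3), c(tiny_grid(), 1, 4))
  # single batch, one epoch: the recorded loss is the pre-update loss of
  # the initial parameters
  fit <- train_cae(cae, x, train_config(1e-4, 4, 1, "mse", seed = 1,
                                        shuffle = FALSE))
  recon <- stldecode:::cae_forward(cae, x, training = TRUE)$out
  expect_equal(fit$history$loss[1], mean((recon - x)^2), tolerance = 1e-5)
})

test_that("an overfit run shrinks the reconstruction loss by 10x", {
  cfg <- tiny_config("single_study", n_subjects = 2)
  mask <- config_mask(cfg)
  coll <- generate_labeled_collection(cfg)
  maps <- preprocess_collection(coll$maps, mask)[1:8]
  spec <- architecture_spec(4, 0.1, tiny_grid())
  cae <- default_init(build_cae(spec), 4)
  fit <- train_cae(cae, maps, train_config(1e-3, 8, 300, "mse", seed = 2))
  expect_lt(tail(fit$history$loss, 1), 0.1 * fit$history$loss[1])
  # divergence is reported with the epoch index, not silently
  expect_true(all(is.finite(fit$history$loss)))
})

test_that("a separable two-class problem is learned to perfect accuracy", {
  mask <- tiny_mask()
  cfg <- tiny_config("single_study", noise_sd = 0.3, subject_shift_sd = 0)
  ctr <- dim(mask$data) %/% 2
  templates <- list(manual_template("a", list(ctr - 3L)),
                    manual_template("b", list(ctr + 3L)))
  maps <- list(); labels <- integer(0)
  for (s in paste0("s", 1:10)) for (ci in 1:2) {
    maps <- c(maps, list(preprocess_map(
      sample_stat_map(templates[[ci]], s, "study_01", cfg, mask,
                      seed = derive_seed(3, s, ci)), mask)))
    labels <- c(labels, ci - 1L)
  }
  spec <- architecture_spec(4, 0.1, tiny_grid())
  cnn <- default_init(build_cnn(spec, 2), 7)
  fit <- train_classifier(cnn, maps, labels,
                          train_config(1e-3, 10, 60, "cross_entropy", seed = 3))
  probs <- predict_cnn(fit$model, maps)
  pred <- max.col(t(probs)) - 1L
  expect_equal(mean(pred == labels), 1.0)
})

test_that("initial cross-entropy sits at the chance level log(K)", {
  spec <- architecture_spec(4, 0.1, tiny_grid())
  for (K in c(4L, 9L)) {
    cnn <- default_init(build_cnn(spec, K), 5)
    n <- 12
    x <- array(rnorm(prod(tiny_grid()) * n, sd = 0.3), c(tiny_grid(), 1, n))
    labels <- with_seed <- sample(0:(K - 1), n, replace = TRUE)
    fit <- train_classifier(cnn, x, labels,
                            train_config(1e-4, n, 1, "cross_entropy", seed = 1))
    expect_equal(fit$history$loss[1], log(K), tolerance = 0.1 * log(K))
  }
})

test_that("training is deterministic for a fixed seed and rejects bad labels", {
  spec <- architecture_spec(4, 0.1, tiny_grid())
  x <- array(rnorm(prod(tiny_grid()) * 6, sd = 0.3), c(tiny_grid(), 1, 6))
  labels <- c(0L, 1L, 2L, 0L, 1L, 2L)
  run <- function() {
    cnn <- default_init(build_cnn(spec, 3), 9)
    train_classifier(cnn, x, labels,
                     train_config(1e-4, 2, 3, "cross_entropy", seed = 13))
  }
  f1 <- run(); f2 <- run()
  expect_identical(param_vector(f1$model$params), param_vector(f2$model$params))
  expect_identical(f1$history, f2$history)
  cnn <- default_init(build_cnn(spec, 3), 9)
  expect_error(train_classifier(cnn, x, c(labels[-1], 3L),
                                train_config(1e-4, 2, 1, "cross_entropy")),
               "labels")
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_error(train_config(epochs = 0), "epochs")
})

test_that("frozen blocks stay bitwise fixed while trainable ones move", {
  spec <- architecture_spec(5, 0.1, tiny_grid())
  cae <- default_init(build_cae(spec), 21)
  cnn <- default_init(build_cnn(spec, 3), 22)
  cnn <- transfer_weights(cae, cnn, transfer_config(5, n_frozen = 2))
  before <- cnn$params
  x <- array(rnorm(prod(tiny_grid()) * 10, sd = 0.3), c(tiny_grid(), 1, 10))
  labels <- rep(0:1, 5)
  fit <- train_classifier(cnn, x, labels,
                          train_config(1e-3, 5, 5, "cross_entropy", seed = 2))
  after <- fit$model$params
  for (i in 1:2) {
    expect_identical(after$encoder[[i]]$W, before$encoder[[i]]$W)
    expect_identical(after$encoder[[i]]$b, before$encoder[[i]]$b)
    expect_identical(after$encoder[[i]]$gamma, before$encoder[[i]]$gamma)
    expect_identical(after$encoder[[i]]$rmean, before$encoder[[i]]$rmean)
  }
  for (i in 3:5) {
    expect_false(identical(after$encoder[[i]]$W, before$encoder[[i]]$W))
  }
  expect_false(identical(after$dense$W, before$dense$W))

  # freezing everything leaves only the dense layer trainable
  cnn_all <- transfer_weights(cae, default_init(build_cnn(spec, 3), 23),
                              transfer_config(5, n_frozen = 5))
  fit2 <- train_classifier(cnn_all, x, labels,
                           train_config(1e-3, 5, 3, "cross_entropy", seed = 2))
  for (i in 1:5) {
    expect_identical(fit2$model$params$encoder[[i]]$W,
                     cnn_all$params$encoder[[i]]$W)
  }
  expect_false(identical(fit2$model$params$dense$W, cnn_all$params$dense$W))
})

test_that("the grid search trains one model per cell per fold and ranks cells", {
  coll <- tiny_collection(n_subjects = 10, n_classes = 3, n_tasks = 3)
  plan <- assign_subject_folds(unique(coll$manifest$subject_id), k = 5,
                               seed = 1, subdataset = "validation")
  grid <- grid_spec(architectures = 4L, batch_sizes = c(4L, 8L),
                    epoch_options = 2L)
  res <- hyperparameter_search(coll$manifest, coll$maps, "contrast",
                               "default", grid, plan,
                               width_multiplier = 0.1, seed = 4)
  expect_equal(nrow(res$report), 2L)
  expect_named(res$report, c("init", "model", "epochs", "batch",
                             "mean_acc", "sem_acc", "mean_f1", "sem_f1"))
  expect_equal(nrow(res$best), 1L)
  expect_gte(res$best$mean_acc, max(res$report$mean_acc) - 1e-12)
  expect_error(grid_spec(architectures = integer(0)), "nonempty")
  expect_error(
    hyperparameter_search(coll$manifest, coll$maps, "contrast", "pretrained",
                          grid, plan, cae_models = NULL,
                          width_multiplier = 0.1),
    "CAE checkpoint")
})
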