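# Architectures, initialisation, weight transfer, and freezing.

test_that("latent sizes match the published 4- and 5-layer architectures", {
  s4 <- architecture_spec(4)
  expect_equal(s4$latent_dim, 18432L)             # 512 x 3 x 4 x 3
  expect_equal(s4$latent_shape, c(512L, 3L, 4L, 3L))
  s5 <- architecture_spec(5)
  expect_equal(s5$latent_dim, 4096L)              # 512 x 2 x 2 x 2
  expect_equal(s5$latent_shape, c(512L, 2L, 2L, 2L))
})

test_that("decoder kernels reproduce the published shape-preserving choices", {
  s4 <- architecture_spec(4)
  expect_equal(s4$decoder_kernels,
               list(c(4L, 3L, 4L), c(4L, 4L, 4L), c(4L, 4L, 4L), c(4L, 4L, 4L)))
  s5 <- architecture_spec(5)
  expect_equal(s5$decoder_kernels[[1]], c(3L, 4L, 3L))
  expect_equal(s5$decoder_kernels[[2]], c(4L, 3L, 4L))
  expect_true(all(vapply(s5$decoder_kernels[3:5],
                         function(k) all(k == 4L), logical(1))))
})

test_that("the stride-2 shape chain follows the closed-form conv formulas", {
  s4 <- architecture_spec(4)
  chain <- lapply(s4$shapes, identity)
  expect_equal(chain[[1]], c(48L, 56L, 48L))
  expect_equal(chain[[2]], c(24L, 28L, 24L))
  expect_equal(chain[[4]], c(6L, 7L, 6L))
  expect_equal(chain[[5]], c(3L, 4L, 3L))
  # a dimension that saturates at one voxel still yields an invertible
  # decoder chain
  s <- architecture_spec(5, width_multiplier = 0.05, input_grid = c(16, 16, 8))
  expect_equal(s$shapes[[6]], c(1L, 1L, 1L))
  for (i in 1:5) {
    k <- s$decoder_kernels[[i]]
    n_in <- s$shapes[[7 - i]]
    expect_equal((n_in - 1L) * 2L - 2L + k, s$shapes[[6 - i]])
  }
})

test_that("encoder and decoder shapes match the conv formulas on random grids", {
  set.seed(6)
  fwd <- function(n, k = 3, s = 2, p = 1) (n + 2 * p - k) %/% s + 1
  for (rep in 1:50) {
    grid <- sample(seq(16, 40, by = 2), 3, replace = TRUE)
    n_layers <- sample(4:5, 1)
    spec <- architecture_spec(n_layers, width_multiplier = 0.05,
                              input_grid = grid)
    expected <- grid
    for (i in seq_len(n_layers)) {
      expected <- fwd(expected)
      expect_equal(spec$shapes[[i + 1]], as.integer(expected))
    }
    # transposed-conv formula inverts the chain exactly
    for (i in seq_len(n_layers)) {
      k <- spec$decoder_kernels[[i]]
      n_in <- spec$shapes[[n_layers + 2 - i]]
      expect_equal((n_in - 1L) * 2L - 2L + k, spec$shapes[[n_layers + 1 - i]])
    }
  }
})

test_that("a built autoencoder reconstructs the input shape end to end", {
  spec <- architecture_spec(4, width_multiplier = 0.05,
                            input_grid = c(20, 24, 16))
  cae <- default_init(build_cae(spec), 3)
  x <- array(rnorm(20 * 24 * 16 * 2), c(20, 24, 16, 1, 2))
  out <- reconstruct_cae(cae, x)
  expect_equal(dim(out), dim(x))
  expect_true(all(out >= -1 & out <= 1))   # bounded output activation
})

test_that("classifier probabilities are normalised for any class count", {
  for (k in c(7L, 23L, 30L, 36L)) {
    spec <- architecture_spec(4, 0.05, tiny_grid())
    cnn <- default_init(build_cnn(spec, k), k)
    x <- array(rnorm(prod(tiny_grid()) * 3), c(tiny_grid(), 1, 3))
    p <- predict_cnn(cnn, x)
    expect_equal(dim(p), c(k, 3L))
    expect_equal(colSums(p), rep(1, 3), tolerance = 1e-6)
  }
  expect_error(build_cnn(architecture_spec(4, 0.05, tiny_grid()), 1), "n_classes")
})

test_that("Kaiming-uniform draws respect the 1/sqrt(fan_in) bound exactly", {
  spec <- architecture_spec(4, 0.25)
  cnn <- default_init(build_cnn(spec, 23), 11)
  for (i in seq_along(cnn$params$encoder)) {
    blk <- cnn$params$encoder[[i]]
    fan_in <- prod(dim(blk$W)[1:4])
    bound <- 1 / sqrt(fan_in)
    expect_true(all(abs(blk$W) <= bound))
    expect_true(all(abs(blk$b) <= bound))
    expect_true(all(blk$gamma == 1) && all(blk$beta == 0))
  }
  dense <- cnn$params$dense
  expect_true(all(abs(dense$W) <= 1 / sqrt(nrow(dense$W))))
  # determinism
  cnn2 <- default_init(build_cnn(spec, 23), 11)
  expect_identical(param_vector(cnn$params), param_vector(cnn2$params))
})

test_that("empirical weight variance matches the uniform-bound prediction", {
  spec <- architecture_spec(4, 0.5)
  cae <- default_init(build_cae(spec), 5)
  blk <- cae$params$encoder[[4]]          # > 1e5 weights
  fan_in <- prod(dim(blk$W)[1:4])
  expect_gt(length(blk$W), 1e5)
  expect_equal(stats::var(as.numeric(blk$W)), 1 / (3 * fan_in),
               tolerance = 0.1)
})

test_that("weight transfer copies exactly the requested prefix", {
  spec <- architecture_spec(5, 0.05, tiny_grid())
  cae <- default_init(build_cae(spec), 1)
  cnn0 <- default_init(build_cnn(spec, 4), 2)

  full <- transfer_weights(cae, cnn0, transfer_config(5))
  for (i in 1:5) {
    expect_identical(full$params$encoder[[i]]$W, cae$params$encoder[[i]]$W)
    expect_identical(full$params$encoder[[i]]$b, cae$params$encoder[[i]]$b)
  }
  none <- transfer_weights(cae, cnn0, transfer_config(0))
  expect_identical(param_vector(none$params), param_vector(cnn0$params))

  two <- transfer_weights(cae, cnn0, transfer_config(2))
  for (i in 1:2) expect_identical(two$params$encoder[[i]]$W,
                                  cae$params$encoder[[i]]$W)
  for (i in 3:5) expect_false(isTRUE(all.equal(two$params$encoder[[i]]$W,
                                               cae$params$encoder[[i]]$W)))
  expect_identical(two$params$dense$W, cnn0$params$dense$W)
  # batch-norm parameters stay untouched unless requested
  expect_identical(two$params$encoder[[1]]$rmean, cnn0$params$encoder[[1]]$rmean)
  bn <- transfer_weights(cae, cnn0, transfer_config(2, transfer_batchnorm = TRUE))
  expect_identical(bn$params$encoder[[1]]$gamma, cae$params$encoder[[1]]$gamma)
})

test_that("architecture mismatches and bad freeze counts are rejected", {
  s5 <- architecture_spec(5, 0.05, tiny_grid())
  s4 <- architecture_spec(4, 0.05, tiny_grid())
  cae <- default_init(build_cae(s5), 1)
  cnn4 <- default_init(build_cnn(s4, 3), 1)
  expect_error(transfer_weights(cae, cnn4, transfer_config(4)), "mismatch")
  cnn5 <- default_init(build_cnn(s5, 3), 1)
  expect_error(transfer_weights(cae, cnn5, transfer_config(2, n_frozen = 3)),
               "freeze")
  expect_error(freeze_prefix(cnn5, 6), "n_frozen")
  expect_equal(freeze_prefix(cnn5, 2)$frozen, 2L)
})

test_that("width_multiplier scales conv parameter counts quadratically", {
  n_conv_params <- function(wm) {
    spec <- architecture_spec(4, wm, tiny_grid())
    cin <- c(1L, spec$channels[-4])
    sum(27 * cin * spec$channels)
  }
  # analytic: weights of layer i are 27 * c_{i-1} * c_i; doubling the width
  # quadruples every term except the input layer, which doubles
  p1 <- n_conv_params(0.25); p2 <- n_conv_params(0.5)
  spec1 <- architecture_spec(4, 0.25, tiny_grid())
  first1 <- 27 * 1 * spec1$channels[1]
  expect_equal(p2, 4 * (p1 - first1) + 2 * first1)
  # and the formula matches the allocated arrays
  cae <- build_cae(spec1)
  alloc <- sum(vapply(cae$params$encoder, function(b) length(b$W), numeric(1)))
  expect_equal(alloc, p1)
})

test_that("analytic gradients match finite differences on the granular ops", {
  set.seed(2)
  D <- 6; H <- 5; W <- 7; Cin <- 2; Cout <- 3; N <- 2
  x <- array(rnorm(D * H * W * Cin * N), c(D, H, W, Cin, N))
  w <- array(rnorm(27 * Cin * Cout), c(3, 3, 3, Cin, Cout))
  b <- rnorm(Cout)
  y <- stldecode:::cpp_conv3d_fwd(x, w, b, 2L, 1L)
  R <- array(rnorm(length(y)), dim(y))
  bw <- stldecode:::cpp_conv3d_bwd(x, w, R, 2L, 1L, TRUE)
  numgrad <- function(f, arr, eps = 1e-3, n_probe = 20) {
    idx <- sample(length(arr), n_probe)
    g <- numeric(n_probe)
    for (q in seq_along(idx)) {
      a1 <- arr; a1[idx[q]] <- a1[idx[q]] + eps
      a2 <- arr; a2[idx[q]] <- a2[idx[q]] - eps
      g[q] <- (f(a1) - f(a2)) / (2 * eps)
    }
    list(g = g, idx = idx)
  }
  nw <- numgrad(function(v) sum(stldecode:::cpp_conv3d_fwd(x, v, b, 2L, 1L) * R), w)
  expect_equal(bw$dw[nw$idx], nw$g, tolerance = 5e-3)
  nx <- numgrad(function(v) sum(stldecode:::cpp_conv3d_fwd(v, w, b, 2L, 1L) * R), x)
  expect_equal(bw$dx[nx$idx], nx$g, tolerance = 5e-3)

  kt <- c(4L, 3L, 4L)
  wt <- array(rnorm(prod(kt) * Cout * Cin), c(kt, Cout, Cin))
  xt <- array(rnorm(3 * 4 * 3 * Cin * N), c(3, 4, 3, Cin, N))
  bt <- rnorm(Cout)
  yt <- stldecode:::cpp_convt3d_fwd(xt, wt, bt, 2L, 1L)
  expect_equal(dim(yt), c(6L, 7L, 6L, Cout, N))
  Rt <- array(rnorm(length(yt)), dim(yt))
  bwt <- stldecode:::cpp_convt3d_bwd(xt, wt, Rt, 2L, 1L)
  nwt <- numgrad(function(v) sum(stldecode:::cpp_convt3d_fwd(xt, v, bt, 2L, 1L) * Rt), wt)
  expect_equal(bwt$dw[nwt$idx], nwt$g, tolerance = 5e-3)
  nxt <- numgrad(function(v) sum(stldecode:::cpp_convt3d_fwd(v, wt, bt, 2L, 1L) * Rt), xt)
  expect_equal(bwt$dx[nxt$idx], nxt$g, tolerance = 5e-3)
})

test_that("the fused training step reproduces the reference forward/backward", {
  set.seed(3)
  grid <- tiny_grid()
  spec <- architecture_spec(4, 0.1, grid)
  cnn <- default_init(build_cnn(spec, 3), 5)
  B <- 4
  x <- array(rnorm(prod(grid) * B), c(grid, 1, B))
  y <- c(0L, 1L, 2L, 1L)
  fwd <- stldecode:::cnn_forward(cnn, x, training = TRUE, want_cache = TRUE)
  ref_loss <- -mean(log(fwd$probs[cbind(y + 1L, 1:B)]))
  dlog <- fwd$probs
  dlog[cbind(y + 1L, 1:B)] <- dlog[cbind(y + 1L, 1:B)] - 1
  ref <- stldecode:::cnn_backward(cnn, fwd, dlog / B)
  st <- stldecode:::cpp_cnn_train_step(x, seq_len(B), y, cnn$params$encoder,
                                       cnn$params$dense, 0L, 0.01, 2L, 1L)
  expect_equal(st$loss, ref_loss, tolerance = 1e-5)
  for (i in 1:4) {
    expect_equal(st$encoder[[i]]$W, ref$encoder[[i]]$W, tolerance = 1e-4)
    expect_equal(st$encoder[[i]]$gamma, ref$encoder[[i]]$gamma, tolerance = 1e-4)
    expect_equal(st$encoder[[i]]$beta, ref$encoder[[i]]$beta, tolerance = 1e-4)
    # conv biases feed straight into batch norm, so their true gradient is
    # zero; both paths agree on that to absolute tolerance
    expect_equal(st$encoder[[i]]$b, ref$encoder[[i]]$b, tolerance = 1e-5)
  }
  expect_equal(st$dense$W, unclass(ref$dense$W), tolerance = 1e-4,
               ignore_attr = TRUE)

  cae <- default_init(build_cae(spec), 6)
  fwd <- stldecode:::cae_forward(cae, x, training = TRUE, want_cache = TRUE)
  ref_loss <- mean((fwd$out - x)^2)
  ref <- stldecode:::cae_backward(cae, fwd, 2 * (fwd$out - x) / length(fwd$out))
  st <- stldecode:::cpp_cae_train_step(x, seq_len(B), cae$params$encoder,
                                       cae$params$decoder, 0.01, 2L, 1L, 0L)
  expect_equal(st$loss, ref_loss, tolerance = 1e-6)
  for (i in 1:4) {
    expect_equal(st$encoder[[i]]$W, ref$encoder[[i]]$W, tolerance = 1e-4)
    expect_equal(st$decoder[[i]]$W, ref$decoder[[i]]$W, tolerance = 1e-4)
  }
})
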