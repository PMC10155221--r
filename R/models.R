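# Model architectures: 4- and 5-layer 3D convolutional autoencoders (CAE)
# and the matching convolutional classifiers (CNN) sharing the encoder.
#
# Every encoder layer is a conv block: 3x3x3 convolution with stride 2 and
# padding 1, 3D batch normalisation, leaky ReLU. The decoder mirrors the
# encoder with transposed convolutions whose kernel sizes are chosen per
# dimension so that each decoder layer exactly inverts the corresponding
# encoder shape; on the default 48x56x48 grid this yields kernels
# (4,3,4),(4,4,4),(4,4,4),(4,4,4) for the 4-layer model and
# (3,4,3),(4,3,4),(4,4,4),(4,4,4),(4,4,4) for the 5-layer model. The final
# decoder layer applies a bounded output activation (tanh by default) so
# reconstructions live in [-1, 1] like the normalised inputs.

conv_out_shape <- function(shape, k = 3L, s = 2L, p = 1L) {
  (shape + 2L * p - k) %/% s + 1L
}

convt_out_shape <- function(shape, k, s = 2L, p = 1L) {
  (shape - 1L) * s - 2L * p + k
}

#' Define a CAE/CNN architecture
#'
#' @param n_layers 4 or 5 convolutional layers per part.
#' @param width_multiplier positive scale applied to the base channel
#'   counts (64,128,256,512) or (32,64,128,256,512); fractional values give
#'   desk-scale models with identical shape structure.
#' @param input_grid voxel grid the model ingests.
#' @param negative_slope leaky-ReLU slope for negative inputs.
#' @param output_activation bounded decoder output map: `"tanh"` (default,
#'   range \[-1,1\] matching the normalised inputs) or `"sigmoid"`.
#' @return an object of class `arch_spec` with the per-layer shape chain,
#'   channel counts, decoder kernels and latent dimension.
#' @export
architecture_spec <- function(n_layers = 4L, width_multiplier = 1,
                              input_grid = default_grid(),
                              negative_slope = 0.01,
                              output_activation = c("tanh", "sigmoid")) {
  output_activation <- match.arg(output_activation)
  if (!n_layers %in% c(4L, 5L)) stopf("'n_layers' must be 4 or 5")
  if (width_multiplier <= 0) stopf("'width_multiplier' must be positive")
  base <- if (n_layers == 4L) c(64L, 128L, 256L, 512L) else c(32L, 64L, 128L, 256L, 512L)
  channels <- pmax(1L, as.integer(round(base * width_multiplier)))
  shapes <- vector("list", n_layers + 1L)
  shapes[[1]] <- as.integer(input_grid)
  for (i in seq_len(n_layers)) {
    nxt <- conv_out_shape(shapes[[i]])
    if (any(nxt < 1L))
      stopf("input grid dimension %d collapses below 1 voxel at layer %d",
            which(nxt < 1L)[1], i)
    shapes[[i + 1L]] <- nxt
  }
  # per-dimension transposed-conv kernels that exactly invert the chain
  decoder_kernels <- lapply(seq_len(n_layers), function(i) {
    n_in <- shapes[[n_layers + 2L - i]]
    n_out <- shapes[[n_layers + 1L - i]]
    k <- n_out - 2L * (n_in - 1L) + 2L
    if (any(k < 2L)) stopf("no valid transposed-conv kernel for decoder layer %d", i)
    k
  })
  structure(list(
    n_layers = as.integer(n_layers), channels = channels,
    kernel = c(3L, 3L, 3L), stride = 2L, pad = 1L,
    decoder_kernels = decoder_kernels,
    negative_slope = negative_slope, output_activation = output_activation,
    width_multiplier = width_multiplier,
    input_grid = as.integer(input_grid), shapes = shapes,
    latent_shape = c(channels[n_layers], shapes[[n_layers + 1L]]),
    latent_dim = as.integer(channels[n_layers] * prod(shapes[[n_layers + 1L]]))
  ), class = "arch_spec")
}

#' @export
print.arch_spec <- function(x, ...) {
  cat(sprintf("<arch_spec> %d-layer 3D conv model, width x%.3g, input %s\n",
              x$n_layers, x$width_multiplier,
              paste(x$input_grid, collapse = "x")))
  cin <- c(1L, x$channels[-x$n_layers])
  for (i in seq_len(x$n_layers)) {
    cat(sprintf("  enc %d: conv 3x3x3 /2  %4d -> %4d ch, out %s\n", i,
                cin[i], x$channels[i],
                paste(x$shapes[[i + 1]], collapse = "x")))
  }
  cat(sprintf("  latent: %d x %s = %d elements\n", x$channels[x$n_layers],
              paste(x$shapes[[x$n_layers + 1]], collapse = "x"), x$latent_dim))
  dec_in <- rev(x$channels)
  dec_out <- c(rev(x$channels)[-1], 1L)
  for (i in seq_len(x$n_layers)) {
    cat(sprintf("  dec %d: convT %s /2 %4d -> %4d ch, out %s\n", i,
                paste(x$decoder_kernels[[i]], collapse = "x"),
                dec_in[i], dec_out[i],
                paste(x$shapes[[x$n_layers + 1 - i]], collapse = "x")))
  }
  invisible(x)
}

alloc_block <- function(k, cin, cout, transposed = FALSE, bn = TRUE) {
  wdim <- if (transposed) c(k, cout, cin) else c(k, cin, cout)
  blk <- list(W = array(0, wdim), b = numeric(cout), transposed = transposed)
  if (bn) {
    blk$gamma <- rep(1, cout); blk$beta <- numeric(cout)
    blk$rmean <- numeric(cout); blk$rvar <- rep(1, cout)
  }
  blk
}

encoder_blocks <- function(spec) {
  cin <- c(1L, spec$channels[-spec$n_layers])
  lapply(seq_len(spec$n_layers), function(i) {
    alloc_block(spec$kernel, cin[i], spec$channels[i])
  })
}

#' Build a convolutional autoencoder
#'
#' Allocates an encoder of `n_layers` conv blocks (conv, batch norm, leaky
#' ReLU) and a symmetric decoder of transposed-conv blocks, with the
#' bounded output activation on the final block (which carries no batch
#' norm). Parameters are allocated but not initialised; see
#' [default_init()].
#'
#' @param spec an [architecture_spec].
#' @return an object of class `stl_cae`.
#' @export
build_cae <- function(spec) {
  dec_in <- rev(spec$channels)
  dec_out <- c(rev(spec$channels)[-1], 1L)
  decoder <- lapply(seq_len(spec$n_layers), function(i) {
    alloc_block(spec$decoder_kernels[[i]], dec_in[i], dec_out[i],
                transposed = TRUE, bn = i < spec$n_layers)
  })
  structure(list(spec = spec,
                 params = list(encoder = encoder_blocks(spec),
                               decoder = decoder),
                 frozen = 0L),
            class = "stl_cae")
}

#' Build a convolutional classifier
#'
#' The encoder architecture of the CAE followed by a flatten and one dense
#' layer with `n_classes` outputs and a softmax.
#'
#' @param spec an [architecture_spec].
#' @param n_classes number of output classes (at least 2).
#' @return an object of class `stl_cnn`.
#' @export
build_cnn <- function(spec, n_classes) {
  if (n_classes < 2) stopf("'n_classes' must be at least 2")
  structure(list(spec = spec,
                 params = list(encoder = encoder_blocks(spec),
                               dense = list(W = matrix(0, spec$latent_dim, n_classes),
                                            b = numeric(n_classes))),
                 n_classes = as.integer(n_classes),
                 frozen = 0L),
            class = "stl_cnn")
}

#' @export
print.stl_cae <- function(x, ...) {
  cat("<stl_cae>\n"); print(x$spec); invisible(x)
}

#' @export
print.stl_cnn <- function(x, ...) {
  cat(sprintf("<stl_cnn> %d classes, %d frozen block(s)\n", x$n_classes, x$frozen))
  print(x$spec); invisible(x)
}

#' Kaiming-uniform default initialisation
#'
#' Convolution and dense weights are drawn from the Kaiming-uniform
#' distribution with negative-slope parameter `a = sqrt(5)`, i.e. from
#' `U(-b, b)` with `b = sqrt(6 / ((1 + a^2) fan_in)) = 1 / sqrt(fan_in)`;
#' biases use the same bound. `fan_in` is the receptive-field input count
#' (`Cin * prod(kernel)` for convolutions, `Cout * prod(kernel)` for
#' transposed convolutions, the input feature count for the dense layer).
#' Batch-norm scales are set to 1, shifts to 0, running mean/variance to
#' 0/1. Deterministic for a fixed seed.
#'
#' @param model an `stl_cae` or `stl_cnn`.
#' @param seed integer seed.
#' @return the model with initialised parameters.
#' @export
default_init <- function(model, seed = 1L) {
  init_block <- function(blk) {
    wd <- dim(blk$W)
    k3 <- prod(wd[1:3])
    # conv weight dims (k,k,k,Cin,Cout); convT dims (k,k,k,Cout,Cin):
    # position 4 holds Cin for conv and Cout for convT, which is exactly
    # the fan-in channel convention needed here.
    fan_in <- k3 * wd[4]
    bound <- 1 / sqrt(fan_in)
    blk$W[] <- runif(length(blk$W), -bound, bound)
    blk$b[] <- runif(length(blk$b), -bound, bound)
    if (!is.null(blk$gamma)) {
      blk$gamma[] <- 1; blk$beta[] <- 0; blk$rmean[] <- 0; blk$rvar[] <- 1
    }
    blk
  }
  with_seed(seed, {
    model$params$encoder <- lapply(model$params$encoder, init_block)
    if (!is.null(model$params$decoder))
      model$params$decoder <- lapply(model$params$decoder, init_block)
    if (!is.null(model$params$dense)) {
      fan_in <- nrow(model$params$dense$W)
      bound <- 1 / sqrt(fan_in)
      model$params$dense$W[] <- runif(length(model$params$dense$W), -bound, bound)
      model$params$dense$b[] <- runif(length(model$params$dense$b), -bound, bound)
    }
  })
  model
}

#' Transfer configuration for encoder-to-classifier weight copy
#'
#' @param n_transferred number of conv blocks (counted from the input)
#'   whose weights and biases are copied from the pretrained encoder.
#' @param n_frozen number of conv blocks excluded from gradient updates
#'   during fine-tuning; must not exceed `n_transferred` unless the whole
#'   encoder is transferred.
#' @param transfer_batchnorm copy batch-norm parameters too (default
#'   `FALSE`: only convolution weights and biases are transferred).
#' @return an object of class `transfer_config`.
#' @export
transfer_config <- function(n_transferred, n_frozen = 0L,
                            transfer_batchnorm = FALSE) {
  if (n_transferred < 0 || n_frozen < 0) stopf("counts must be non-negative")
  structure(list(n_transferred = as.integer(n_transferred),
                 n_frozen = as.integer(n_frozen),
                 transfer_batchnorm = isTRUE(transfer_batchnorm)),
            class = "transfer_config")
}

#' Transfer pretrained encoder weights into a classifier
#'
#' Copies the convolution weights and biases of the first `n_transferred`
#' encoder blocks of the CAE into the classifier; the remaining blocks and
#' the dense layer keep their current (default) initialisation. Batch-norm
#' parameters are copied only when `transfer_batchnorm` is set.
#'
#' @param cae a trained `stl_cae`.
#' @param cnn an `stl_cnn` with a matching encoder architecture.
#' @param cfg a [transfer_config].
#' @return the classifier with transferred parameters and the freeze count
#'   applied.
#' @export
transfer_weights <- function(cae, cnn, cfg = transfer_config(cnn$spec$n_layers)) {
  a <- cae$spec; b <- cnn$spec
  if (a$n_layers != b$n_layers)
    stopf("architecture mismatch: CAE has %d encoder layers, CNN has %d",
          a$n_layers, b$n_layers)
  diff <- which(a$channels != b$channels)
  if (length(diff))
    stopf("architecture mismatch at encoder layer %d: %d vs %d channels",
          diff[1], a$channels[diff[1]], b$channels[diff[1]])
  if (cfg$n_transferred > b$n_layers)
    stopf("cannot transfer %d of %d layers", cfg$n_transferred, b$n_layers)
  if (cfg$n_frozen > cfg$n_transferred && cfg$n_transferred < b$n_layers)
    stopf("cannot freeze %d layers when only %d are transferred",
          cfg$n_frozen, cfg$n_transferred)
  for (i in seq_len(cfg$n_transferred)) {
    src <- cae$params$encoder[[i]]
    cnn$params$encoder[[i]]$W <- src$W
    cnn$params$encoder[[i]]$b <- src$b
    if (cfg$transfer_batchnorm) {
      cnn$params$encoder[[i]]$gamma <- src$gamma
      cnn$params$encoder[[i]]$beta <- src$beta
      cnn$params$encoder[[i]]$rmean <- src$rmean
      cnn$params$encoder[[i]]$rvar <- src$rvar
    }
  }
  cnn$transfer <- cfg
  freeze_prefix(cnn, cfg$n_frozen)
}

#' Freeze the first conv blocks of a model
#'
#' Frozen blocks (convolution weights and biases, batch-norm scale and
#' shift) are excluded from gradient updates; their batch-norm layers run
#' in inference mode during training so running statistics are frozen too.
#'
#' @param model an `stl_cnn` (or `stl_cae`).
#' @param n_frozen number of blocks to freeze, at most the encoder depth.
#' @return the model with the freeze count set.
#' @export
freeze_prefix <- function(model, n_frozen) {
  if (n_frozen < 0 || n_frozen > model$spec$n_layers)
    stopf("'n_frozen' must lie in 0..%d", model$spec$n_layers)
  model$frozen <- as.integer(n_frozen)
  model
}
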