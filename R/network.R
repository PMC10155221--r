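# Forward and backward passes. Internal: user-facing entry points are the
# training functions, predict_cnn() and the feature extractors.
#
# Activations are 5-d arrays (D, H, W, C, N). Batch-norm layers of frozen
# blocks always run in inference mode and never update running statistics.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

conv_block_forward <- function(blk, x, spec, bn_train, want_cache = FALSE) {
  conv <- cpp_conv3d_fwd(x, blk$W, blk$b, spec$stride, spec$pad)
  bn <- cpp_bn3d_fwd(conv, blk$gamma, blk$beta, blk$rmean, blk$rvar,
                     BN_EPS, BN_MOMENTUM, bn_train)
  act <- cpp_lrelu_fwd(bn$y, spec$negative_slope)
  cache <- NULL
  if (want_cache) {
    cache <- list(x = x, conv = conv, bn_y = bn$y,
                  bn_mean = bn$mean, bn_var = bn$var, bn_train = bn_train)
  }
  list(out = act, rmean = bn$running_mean, rvar = bn$running_var,
       cache = cache)
}

conv_block_backward <- function(blk, cache, dout, spec, need_dx) {
  dbn_y <- cpp_lrelu_bwd(cache$bn_y, dout, spec$negative_slope)
  mean <- if (cache$bn_train) cache$bn_mean else blk$rmean
  var <- if (cache$bn_train) cache$bn_var else blk$rvar
  bn <- cpp_bn3d_bwd(cache$conv, dbn_y, blk$gamma, mean, var, BN_EPS,
                     cache$bn_train)
  cv <- cpp_conv3d_bwd(cache$x, blk$W, bn$dx, spec$stride, spec$pad, need_dx)
  list(dx = if (need_dx) cv$dx else NULL,
       grads = list(W = cv$dw, b = cv$db, gamma = bn$dgamma, beta = bn$dbeta))
}

# Run the encoder, optionally only the first `upto` blocks. Returns the
# activation, per-block caches, and (in training mode) updated running
# statistics folded back into the parameter list.
encoder_forward <- function(model, x, training = FALSE,
                            upto = model$spec$n_layers, want_cache = FALSE) {
  spec <- model$spec
  caches <- vector("list", upto)
  enc <- model$params$encoder
  h <- x
  for (i in seq_len(upto)) {
    bn_train <- training && i > model$frozen
    step <- conv_block_forward(enc[[i]], h, spec, bn_train, want_cache)
    if (bn_train) {
      enc[[i]]$rmean <- step$rmean
      enc[[i]]$rvar <- step$rvar
    }
    caches[[i]] <- step$cache
    h <- step$out
  }
  list(out = h, caches = caches, encoder = enc)
}

# Backpropagate through encoder blocks upto..1. Gradients for frozen
# blocks are NULL and the pass stops once only frozen blocks remain.
encoder_backward <- function(model, caches, dout, upto = model$spec$n_layers) {
  spec <- model$spec
  grads <- vector("list", upto)
  d <- dout
  for (i in rev(seq_len(upto))) {
    if (i <= model$frozen) break
    need_dx <- i > 1L && (i - 1L) > model$frozen
    # the input-layer dx is never needed either, but need_dx already
    # excludes i == 1
    bk <- conv_block_backward(model$params$encoder[[i]], caches[[i]], d,
                              spec, need_dx)
    grads[[i]] <- bk$grads
    d <- bk$dx
    if (is.null(d)) break
  }
  grads
}

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}

cnn_forward <- function(model, x, training = FALSE, want_cache = FALSE) {
  enc <- encoder_forward(model, x, training, want_cache = want_cache)
  latent_dim <- model$spec$latent_dim
  n <- dim(enc$out)[5]
  Z <- matrix(enc$out, latent_dim, n)
  logits <- crossprod(model$params$dense$W, Z) + model$params$dense$b
  probs <- softmax_cols(logits)
  list(probs = probs, logits = logits, Z = Z,
       latent_dims = dim(enc$out), caches = enc$caches,
       encoder = enc$encoder)
}

cnn_backward <- function(model, fwd, dlogits) {
  dW <- fwd$Z %*% t(dlogits)
  db <- rowSums(dlogits)
  dZ <- model$params$dense$W %*% dlogits
  dlat <- array(dZ, fwd$latent_dims)
  enc_grads <- encoder_backward(model, fwd$caches, dlat)
  list(encoder = enc_grads, dense = list(W = dW, b = db))
}

decoder_forward <- function(model, z, training = FALSE, want_cache = FALSE) {
  spec <- model$spec
  n_layers <- spec$n_layers
  dec <- model$params$decoder
  caches <- vector("list", n_layers)
  h <- z
  for (i in seq_len(n_layers)) {
    blk <- dec[[i]]
    if (i < n_layers) {
      conv <- cpp_convt3d_fwd(h, blk$W, blk$b, spec$stride, spec$pad)
      bn <- cpp_bn3d_fwd(conv, blk$gamma, blk$beta, blk$rmean, blk$rvar,
                         BN_EPS, BN_MOMENTUM, training)
      act <- cpp_lrelu_fwd(bn$y, spec$negative_slope)
      if (training) {
        dec[[i]]$rmean <- bn$running_mean
        dec[[i]]$rvar <- bn$running_var
      }
      if (want_cache) {
        caches[[i]] <- list(x = h, conv = conv, bn_y = bn$y,
                            bn_mean = bn$mean, bn_var = bn$var,
                            bn_train = training)
      }
      h <- act
    } else {
      conv <- cpp_convt3d_fwd(h, blk$W, blk$b, spec$stride, spec$pad)
      act <- if (spec$output_activation == "tanh") tanh(conv)
             else 1 / (1 + exp(-conv))
      if (want_cache) caches[[i]] <- list(x = h, y = act)
      h <- act
    }
  }
  list(out = h, caches = caches, decoder = dec)
}

decoder_backward <- function(model, caches, dout) {
  spec <- model$spec
  n_layers <- spec$n_layers
  grads <- vector("list", n_layers)
  d <- dout
  for (i in rev(seq_len(n_layers))) {
    blk <- model$params$decoder[[i]]
    cache <- caches[[i]]
    if (i == n_layers) {
      dconv <- if (spec$output_activation == "tanh") d * (1 - cache$y^2)
               else d * cache$y * (1 - cache$y)
      ct <- cpp_convt3d_bwd(cache$x, blk$W, dconv, spec$stride, spec$pad)
      grads[[i]] <- list(W = ct$dw, b = ct$db)
      d <- ct$dx
    } else {
      dbn_y <- cpp_lrelu_bwd(cache$bn_y, d, spec$negative_slope)
      mean <- if (cache$bn_train) cache$bn_mean else blk$rmean
      var <- if (cache$bn_train) cache$bn_var else blk$rvar
      bn <- cpp_bn3d_bwd(cache$conv, dbn_y, blk$gamma, mean, var, BN_EPS,
                         cache$bn_train)
      ct <- cpp_convt3d_bwd(cache$x, blk$W, bn$dx, spec$stride, spec$pad)
      grads[[i]] <- list(W = ct$dw, b = ct$db,
                         gamma = bn$dgamma, beta = bn$dbeta)
      d <- ct$dx
    }
  }
  list(grads = grads, dz = d)
}

cae_forward <- function(model, x, training = FALSE, want_cache = FALSE) {
  enc <- encoder_forward(model, x, training, want_cache = want_cache)
  dec <- decoder_forward(model, enc$out, training, want_cache = want_cache)
  list(out = dec$out, enc = enc, dec = dec)
}

cae_backward <- function(model, fwd, dout) {
  dec <- decoder_backward(model, fwd$dec$caches, dout)
  enc_grads <- encoder_backward(model, fwd$enc$caches, dec$dz)
  list(encoder = enc_grads, decoder = dec$grads)
}

#' Class probabilities for a batch of preprocessed maps
#'
#' Runs the classifier in inference mode (batch-norm running statistics).
#'
#' @param model a trained `stl_cnn`.
#' @param x 5-d array (D, H, W, 1, N) of preprocessed maps, or a list of
#'   [stat_map]s.
#' @return matrix of class probabilities, `n_classes` x N; columns sum
#'   to 1.
#' @export
predict_cnn <- function(model, x) {
  x <- as_batch_array(x)
  spec <- model$spec
  feats <- cpp_encoder_infer(x, model$params$encoder, spec$n_layers,
                             spec$negative_slope, spec$stride, spec$pad)
  Z <- matrix(feats, spec$latent_dim, dim(x)[5])
  softmax_cols(crossprod(model$params$dense$W, Z) + model$params$dense$b)
}

#' Reconstruct maps with a trained autoencoder
#'
#' @param model a trained `stl_cae`.
#' @param x 5-d array or list of [stat_map]s.
#' @return 5-d array of reconstructions with the input's shape.
#' @export
reconstruct_cae <- function(model, x) {
  x <- as_batch_array(x)
  spec <- model$spec
  cpp_cae_infer(x, model$params$encoder, model$params$decoder,
                spec$negative_slope, spec$stride, spec$pad,
                if (spec$output_activation == "tanh") 0L else 1L)
}

# list of stat_maps or 3-d/5-d array -> (D,H,W,1,N) array
as_batch_array <- function(x) {
  if (is.list(x) && !is.array(x)) {
    arrs <- lapply(x, function(m) if (inherits(m, "stat_map")) m$data else m)
    d <- dim(arrs[[1]])
    out <- array(0, c(d, 1L, length(arrs)))
    for (i in seq_along(arrs)) out[, , , 1L, i] <- arrs[[i]]
    return(out)
  }
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) != 5L) stopf("expected a 5-d batch array (D,H,W,C,N)")
  x
}
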