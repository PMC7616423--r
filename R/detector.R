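#' Configuration for the IED detector (modified EEGNet)
#'
#' A compact EEGNet-style classifier for 64 x 12 segments: a temporal
#' convolution shared across the 12 channels, a depthwise spatial
#' convolution collapsing the channel axis, and a separable temporal
#' convolution, with exponential-linear activations, dropout, and a dense
#' sigmoid head.  Two deliberate modifications to stock EEGNet: every batch
#' normalization stage is removed, and every pooling stage uses max pooling.
#'
#' @param temporal_filters number of temporal filters F1 (default 8).
#' @param depth_multiplier spatial filters per temporal filter D (default 2).
#' @param separable_filters pointwise output filters F2 (default 16).
#' @param temporal_kernel temporal kernel length in samples (default 32,
#'   half the segment length); must not exceed 64.
#' @param separable_kernel depthwise kernel of the separable stage
#'   (default 16).
#' @param dropout_rate dropout probability (default 0.25).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size minibatch size (default 32).
#' @param n_epochs training epochs (default 100).
#' @param seed integer seed.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(temporal_filters = 8L, depth_multiplier = 2L,
                            separable_filters = 16L, temporal_kernel = 32L,
                            separable_kernel = 16L, dropout_rate = 0.25,
                            learning_rate = 1e-3, batch_size = 32L,
                            n_epochs = 100L, seed = 1L) {
  cfg <- list(temporal_filters = as.integer(temporal_filters),
              depth_multiplier = as.integer(depth_multiplier),
              separable_filters = as.integer(separable_filters),
              temporal_kernel = as.integer(temporal_kernel),
              separable_kernel = as.integer(separable_kernel),
              dropout_rate = dropout_rate, learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              n_epochs = as.integer(n_epochs), seed = as.integer(seed))
  if (any(c(cfg$temporal_filters, cfg$depth_multiplier,
            cfg$separable_filters) < 1L)) {
    stop_invalid("all filter counts must be >= 1")
  }
  if (cfg$temporal_kernel > 64L) {
    stop_invalid("temporal_kernel cannot exceed the 64-sample segment")
  }
  structure(cfg, class = "detector_config")
}

det_pools <- function() c(4L, 8L)   # EEGNet pooling factors; 64 -> 16 -> 2

detector_architecture <- function() {
  c("temporal_conv", "depthwise_spatial_conv", "elu", "max_pool", "dropout",
    "separable_conv_depthwise", "separable_conv_pointwise", "elu",
    "max_pool", "dropout", "dense_sigmoid")
}

init_detector_params <- function(cfg) {
  F1 <- cfg$temporal_filters
  D <- cfg$depth_multiplier
  F2 <- cfg$separable_filters
  kt <- cfg$temporal_kernel
  ks <- cfg$separable_kernel
  t_out <- 64L %/% prod(det_pools())
  list(
    t_W = glorot(kt, F1, c(kt, F1)),
    t_b = numeric(F1),
    sp_W = glorot(12L, D, c(12L, D, F1)),
    sp_b = numeric(F1 * D),
    dw_W = glorot(ks, F1 * D, c(ks, F1 * D)),
    dw_b = numeric(F1 * D),
    pw_W = glorot(F1 * D, F2, c(F1 * D, F2)),
    pw_b = numeric(F2),
    fc_W = glorot(t_out * F2, 1L, c(t_out * F2, 1L)),
    fc_b = numeric(1L))
}

# (B*T) x 12 -> ((12B)*T) x 1: each (segment, channel) pair becomes its own
# batch element so the shared temporal conv is an ordinary 1-channel conv
det_to_perchan <- function(M, B) {
  Tn <- nrow(M) / B
  A <- array(M, c(B, Tn, 12L))
  matrix(aperm(A, c(1L, 3L, 2L)), B * 12L * Tn, 1L)
}

det_from_perchan <- function(dM1, B) {
  Tn <- nrow(dM1) / (12L * B)
  A <- array(dM1, c(B, 12L, Tn))
  matrix(aperm(A, c(1L, 3L, 2L)), B * Tn, 12L)
}

# ((12B)*T) x F1 -> (B*T) x (12*F1), column index c + 12*(f-1)
det_to_spatial <- function(O, B, F1) {
  Tn <- nrow(O) / (12L * B)
  A <- array(O, c(B, 12L, Tn, F1))
  matrix(aperm(A, c(1L, 3L, 2L, 4L)), B * Tn, 12L * F1)
}

det_from_spatial <- function(dO, B, F1) {
  Tn <- nrow(dO) / B
  A <- array(dO, c(B, Tn, 12L, F1))
  matrix(aperm(A, c(1L, 3L, 2L, 4L)), B * 12L * Tn, F1)
}

# depthwise temporal conv: independent kernel per feature channel
nn_dwconv_fwd <- function(M, W, b, B) {
  k <- nrow(W)
  C <- ncol(M)
  Z <- nn_im2col(M, B, k)
  out <- matrix(0, nrow(M), C)
  for (j in seq_len(k)) {
    out <- out + Z[, ((j - 1L) * C + 1L):(j * C), drop = FALSE] *
      matrix(W[j, ], nrow(M), C, byrow = TRUE)
  }
  out <- out + matrix(b, nrow(out), C, byrow = TRUE)
  list(out = out, Z = Z, k = k)
}

nn_dwconv_bwd <- function(dY, cache, W, B) {
  k <- cache$k
  C <- ncol(dY)
  Tn <- nrow(dY) / B
  dW <- matrix(0, k, C)
  dZ <- matrix(0, nrow(dY), k * C)
  for (j in seq_len(k)) {
    cols <- ((j - 1L) * C + 1L):(j * C)
    dW[j, ] <- colSums(cache$Z[, cols, drop = FALSE] * dY)
    dZ[, cols] <- dY * matrix(W[j, ], nrow(dY), C, byrow = TRUE)
  }
  pad_l <- (k - 1L) %/% 2L
  dMp <- matrix(0, B * (Tn + k - 1L), C)
  for (j in seq_len(k)) {
    rows <- ((j - 1L) * B + 1L):((j - 1L + Tn) * B)
    dMp[rows, ] <- dMp[rows, ] + dZ[, ((j - 1L) * C + 1L):(j * C)]
  }
  list(dM = dMp[(pad_l * B + 1L):((pad_l + Tn) * B), , drop = FALSE],
       dW = dW, db = colSums(dY))
}

detector_forward <- function(par, M, B, cfg, train = FALSE) {
  F1 <- cfg$temporal_filters
  D <- cfg$depth_multiplier
  pools <- det_pools()
  cache <- list()
  m1 <- det_to_perchan(M, B)
  tc <- nn_conv_fwd(m1, par$t_W, par$t_b, B * 12L)
  m2 <- det_to_spatial(tc$out, B, F1)
  # depthwise spatial conv: per temporal filter f, D filters over channels
  sp_out <- matrix(0, nrow(m2), F1 * D)
  for (f in seq_len(F1)) {
    Xf <- m2[, ((f - 1L) * 12L + 1L):(f * 12L), drop = FALSE]
    sp_out[, ((f - 1L) * D + 1L):(f * D)] <- Xf %*% par$sp_W[, , f]
  }
  sp_out <- sp_out + matrix(par$sp_b, nrow(sp_out), F1 * D, byrow = TRUE)
  e1 <- nn_elu_fwd(sp_out)
  p1 <- nn_maxpool_fwd(e1$out, B, pools[1L])
  dr1 <- nn_dropout_fwd(p1$out, cfg$dropout_rate, train)
  dw <- nn_dwconv_fwd(dr1$out, par$dw_W, par$dw_b, B)
  pw <- nn_dense_fwd(dw$out, par$pw_W, par$pw_b)
  e2 <- nn_elu_fwd(pw)
  p2 <- nn_maxpool_fwd(e2$out, B, pools[2L])
  dr2 <- nn_dropout_fwd(p2$out, cfg$dropout_rate, train)
  Tn <- nrow(dr2$out) / B
  flat <- dr2$out
  dim(flat) <- c(B, Tn * ncol(dr2$out))
  z <- nn_dense_fwd(flat, par$fc_W, par$fc_b)
  cache <- list(tc = tc, m2 = m2, sp_out = sp_out, e1 = e1, p1 = p1,
                dr1 = dr1, dw = dw, dw_in = dr1$out, e2 = e2, p2 = p2,
                dr2 = dr2, flat = flat,
                flat_dims = c(B * Tn, ncol(dr2$out)))
  list(p = as.numeric(nn_sigmoid(z)), z = as.numeric(z), cache = cache)
}

detector_backward <- function(par, cache, dz, B, cfg) {
  F1 <- cfg$temporal_filters
  D <- cfg$depth_multiplier
  g <- list()
  db <- nn_dense_bwd(matrix(dz, B, 1L), cache$flat, par$fc_W)
  g$fc_W <- db$dW; g$fc_b <- db$db
  dcur <- db$dX
  dim(dcur) <- cache$flat_dims
  dcur <- nn_dropout_bwd(dcur, cache$dr2)
  dcur <- nn_maxpool_bwd(dcur, cache$p2)
  dcur <- nn_elu_bwd(dcur, cache$e2, cache$e2$out)
  db <- nn_dense_bwd(dcur, cache$dw$out, par$pw_W)
  g$pw_W <- db$dW; g$pw_b <- db$db
  dwb <- nn_dwconv_bwd(db$dX, cache$dw, par$dw_W, B)
  g$dw_W <- dwb$dW; g$dw_b <- dwb$db
  dcur <- nn_dropout_bwd(dwb$dM, cache$dr1)
  dcur <- nn_maxpool_bwd(dcur, cache$p1)
  dcur <- nn_elu_bwd(dcur, cache$e1, cache$e1$out)
  g$sp_b <- colSums(dcur)
  g$sp_W <- array(0, dim(par$sp_W))
  dm2 <- matrix(0, nrow(cache$m2), ncol(cache$m2))
  for (f in seq_len(F1)) {
    colsX <- ((f - 1L) * 12L + 1L):(f * 12L)
    colsY <- ((f - 1L) * D + 1L):(f * D)
    dYf <- dcur[, colsY, drop = FALSE]
    g$sp_W[, , f] <- crossprod(cache$m2[, colsX, drop = FALSE], dYf)
    dm2[, colsX] <- dYf %*% t(par$sp_W[, , f])
  }
  dtc <- det_from_spatial(dm2, B, F1)
  cb <- nn_conv_bwd(dtc, cache$tc, par$t_W, B * 12L)
  g$t_W <- cb$dW; g$t_b <- cb$db
  g$d_input <- det_from_perchan(cb$dM, B)
  g
}

#' Build an untrained IED detector
#'
#' The returned model's `$architecture` lists its stages in order; it
#' contains no normalization layer and uses max pooling at every pooling
#' stage.
#'
#' @param cfg a [detector_config()].
#' @return object of class `ied_detector`.
#' @export
build_detector <- function(cfg = detector_config()) {
  stopifnot(inherits(cfg, "detector_config"))
  params <- with_seed(cfg$seed, init_detector_params(cfg))
  structure(list(params = params, cfg = cfg,
                 architecture = detector_architecture()),
            class = "ied_detector")
}

detector_predict_array <- function(params, cfg, x_stats, arr) {
  arr <- as_seg_array(arr)
  B <- dim(arr)[3L]
  M <- standardize_mat(segs_to_mat(arr), x_stats)
  detector_forward(params, M, B, cfg, train = FALSE)$p
}

#' Train the IED detector
#'
#' Minimizes binary cross-entropy with Adam; after every epoch the model is
#' scored on the validation set and the checkpoint with the best validation
#' accuracy is retained (ties broken toward the earlier epoch).  With an
#' empty validation set the final-epoch model is kept and a warning logged.
#'
#' @param train labelled [segment_set()] used for fitting.
#' @param val labelled [segment_set()] used for model selection (may be
#'   empty).
#' @param cfg a [detector_config()].
#' @param on which segment matrices to train on: `"y"` (intracranial /
#'   translated, default) or `"x"` (scalp).
#' @param verbose print per-epoch progress.
#' @return object of class `trained_detector` with fields `params`,
#'   `config`, `x_stats`, `training_history`, `architecture`.
#' @export
train_detector <- function(train, val, cfg = detector_config(),
                           on = c("y", "x"), verbose = FALSE) {
  stopifnot(inherits(train, "segment_set"), inherits(cfg, "detector_config"))
  on <- match.arg(on)
  xt <- if (on == "y") train$y else train$x
  if (is.null(xt)) stop_invalid("training set lacks '", on, "' segments")
  labs <- train$label
  if (length(unique(labs)) < 2L) {
    stop_invalid("training set must contain both IED and non-IED segments")
  }
  n <- length(labs)
  has_val <- !is.null(val) && n_segments(val) > 0L
  if (!has_val) {
    warning("empty validation set: keeping the final-epoch model")
  }
  xv <- if (has_val) { if (on == "y") val$y else val$x } else NULL
  x_stats <- channel_stats(matrix(aperm(xt, c(1L, 3L, 2L)), ncol = 12L))
  with_seed(cfg$seed, {
    par <- init_detector_params(cfg)
    opt <- adam_init(par)
    best <- list(acc = -Inf, par = par, epoch = 0L)
    hist <- vector("list", cfg$n_epochs)
    for (ep in seq_len(cfg$n_epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_loss <- ep_acc <- numeric(length(starts))
      for (s in seq_along(starts)) {
        bi <- idx[starts[s]:min(starts[s] + cfg$batch_size - 1L, n)]
        B <- length(bi)
        M <- standardize_mat(segs_to_mat(xt[, , bi, drop = FALSE]), x_stats)
        yb <- labs[bi]
        fw <- detector_forward(par, M, B, cfg, train = TRUE)
        p <- pmin(pmax(fw$p, 1e-7), 1 - 1e-7)
        ep_loss[s] <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
        ep_acc[s] <- mean((fw$p >= 0.5) == (yb == 1L))
        gr <- detector_backward(par, fw$cache, (fw$p - yb) / B, B, cfg)
        upd <- adam_step(par, gr[names(par)], opt, cfg$learning_rate,
                         beta1 = 0.9)
        par <- upd$params; opt <- upd$state
      }
      val_acc <- NA_real_
      if (has_val) {
        pv <- detector_predict_array(par, cfg, x_stats, xv)
        val_acc <- mean((pv >= 0.5) == (val$label == 1L))
        if (val_acc > best$acc) best <- list(acc = val_acc, par = par,
                                             epoch = ep)
      }
      hist[[ep]] <- data.frame(epoch = ep, train_loss = mean(ep_loss),
                               train_acc = mean(ep_acc), val_acc = val_acc)
      if (verbose) {
        message(sprintf("epoch %3d: loss=%.4f acc=%.3f val=%.3f", ep,
                        mean(ep_loss), mean(ep_acc), val_acc))
      }
    }
    final <- if (has_val && best$epoch > 0L) best$par else par
    structure(
      list(params = final, config = cfg, x_stats = x_stats, on = on,
           best_epoch = if (has_val) best$epoch else cfg$n_epochs,
           training_history = do.call(rbind, hist),
           architecture = detector_architecture()),
      class = "trained_detector")
  })
}

#' Predict IED probabilities
#'
#' Inference-mode (dropout disabled) and therefore deterministic:
#' repeated calls give identical vectors.  Thresholding at 0.5 yields the
#' hard labels used by the metrics module.
#'
#' @param det a `trained_detector`.
#' @param segments a [segment_set()] or a `64 x 12 x n` array.
#' @param on for a segment set, which matrices to score: `"y"` (default,
#'   intracranial or translated) or `"x"` (scalp).
#' @return numeric vector of probabilities in `[0, 1]`, one per segment.
#' @export
predict_proba <- function(det, segments, on = det$on %||% "y") {
  stopifnot(inherits(det, "trained_detector"))
  arr <- if (inherits(segments, "segment_set")) {
    a <- if (on == "y") segments$y else segments$x
    if (is.null(a)) stop_invalid("segment set lacks '", on, "' matrices")
    a
  } else segments
  detector_predict_array(det$params, det$config, det$x_stats, arr)
}

#' @export
print.trained_detector <- function(x, ...) {
  cat(sprintf(
    "<trained_detector> %d epochs (best %d), %d parameters, trained on '%s'\n",
    nrow(x$training_history), x$best_epoch, count_parameters(x$params),
    x$on))
  invisible(x)
}
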