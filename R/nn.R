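# Minimal vectorized neural-net primitives with hand-written backprop.
#
# Activation layout: a batch of B segments of T time steps and C feature
# channels is stored as a (B*T) x C matrix with row index b + B*(t-1)
# (batch fastest).  With that layout a time shift is a contiguous row-block
# shift, so 1-D "same" convolution over time reduces to im2col plus one
# BLAS matrix product, and per-segment statistics fall out of a c(B, T, C)
# dim<- reshape.  All layers are pure functions returning the forward
# output plus whatever cache backprop needs; gradients are exact and are
# finite-difference-checked in the test suite.

# --- initializers ----------------------------------------------------------

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# --- conv1d (same padding over time) ---------------------------------------

# im2col: Z[, ((j-1)*C+1):(j*C)] holds the input shifted by tap j
nn_im2col <- function(M, B, k) {
  Tn <- nrow(M) / B
  C <- ncol(M)
  pad_l <- (k - 1L) %/% 2L
  pad_r <- k - 1L - pad_l
  Mp <- rbind(matrix(0, B * pad_l, C), M, matrix(0, B * pad_r, C))
  Z <- matrix(0, B * Tn, k * C)
  for (j in seq_len(k)) {
    Z[, ((j - 1L) * C + 1L):(j * C)] <-
      Mp[((j - 1L) * B + 1L):((j - 1L + Tn) * B), , drop = FALSE]
  }
  Z
}

nn_conv_fwd <- function(M, W, b, B) {
  k <- nrow(W) / ncol(M)
  Z <- nn_im2col(M, B, k)
  out <- Z %*% W
  out <- out + matrix(b, nrow(out), length(b), byrow = TRUE)
  list(out = out, Z = Z, k = k, Cin = ncol(M))
}

nn_conv_bwd <- function(dY, cache, W, B) {
  k <- cache$k
  Cin <- cache$Cin
  Tn <- nrow(dY) / B
  dW <- crossprod(cache$Z, dY)
  db <- colSums(dY)
  dZ <- dY %*% t(W)
  pad_l <- (k - 1L) %/% 2L
  pad_r <- k - 1L - pad_l
  dMp <- matrix(0, B * (Tn + k - 1L), Cin)
  for (j in seq_len(k)) {
    rows <- ((j - 1L) * B + 1L):((j - 1L + Tn) * B)
    dMp[rows, ] <- dMp[rows, ] + dZ[, ((j - 1L) * Cin + 1L):(j * Cin)]
  }
  dM <- dMp[(pad_l * B + 1L):((pad_l + Tn) * B), , drop = FALSE]
  list(dM = dM, dW = dW, db = db)
}

# --- per-segment time-axis normalization -----------------------------------

# zero mean / unit variance over the T time steps of each (segment, channel)
# pair, with a learnable per-channel affine; batch-independent by design.
nn_tnorm_fwd <- function(M, gamma, beta, B, eps = 1e-5) {
  Tn <- nrow(M) / B
  C <- ncol(M)
  A <- M; dim(A) <- c(B, Tn, C)
  mu <- colMeans(aperm(A, c(2L, 1L, 3L)))            # B x C
  rep_rows <- rep(seq_len(B), Tn)
  xc <- M - mu[rep_rows, , drop = FALSE]
  A2 <- xc * xc; dim(A2) <- c(B, Tn, C)
  v <- colMeans(aperm(A2, c(2L, 1L, 3L)))
  sd_full <- sqrt(v + eps)[rep_rows, , drop = FALSE]
  xhat <- xc / sd_full
  out <- xhat * matrix(gamma, B * Tn, C, byrow = TRUE) +
    matrix(beta, B * Tn, C, byrow = TRUE)
  list(out = out, xhat = xhat, sd_full = sd_full, rep_rows = rep_rows)
}

nn_tnorm_bwd <- function(dY, cache, gamma, B) {
  Tn <- nrow(dY) / B
  C <- ncol(dY)
  xhat <- cache$xhat
  dbeta <- colSums(dY)
  dgamma <- colSums(dY * xhat)
  dxhat <- dY * matrix(gamma, B * Tn, C, byrow = TRUE)
  A <- dxhat; dim(A) <- c(B, Tn, C)
  m1 <- colMeans(aperm(A, c(2L, 1L, 3L)))[cache$rep_rows, , drop = FALSE]
  A2 <- dxhat * xhat; dim(A2) <- c(B, Tn, C)
  m2 <- colMeans(aperm(A2, c(2L, 1L, 3L)))[cache$rep_rows, , drop = FALSE]
  dM <- (dxhat - m1 - xhat * m2) / cache$sd_full
  list(dM = dM, dgamma = dgamma, dbeta = dbeta)
}

# --- pooling / upsampling --------------------------------------------------

pool_idx <- function(B, T_out, stride) {
  base <- rep((seq_len(T_out) - 1L) * stride * B, each = B) + seq_len(B)
  lapply(seq_len(stride) - 1L, function(j) base + j * B)
}

nn_avgpool2_fwd <- function(M, B) {
  To <- nrow(M) / B / 2L
  ix <- pool_idx(B, To, 2L)
  list(out = 0.5 * (M[ix[[1L]], , drop = FALSE] + M[ix[[2L]], , drop = FALSE]),
       ix = ix, n_in = nrow(M))
}

nn_avgpool2_bwd <- function(dY, cache) {
  dM <- matrix(0, cache$n_in, ncol(dY))
  dM[cache$ix[[1L]], ] <- 0.5 * dY
  dM[cache$ix[[2L]], ] <- 0.5 * dY
  dM
}

nn_maxpool_fwd <- function(M, B, size) {
  To <- nrow(M) / B / size
  ix <- pool_idx(B, To, size)
  out <- M[ix[[1L]], , drop = FALSE]
  arg <- matrix(1L, nrow(out), ncol(out))
  for (j in seq_len(size)[-1L]) {
    sj <- M[ix[[j]], , drop = FALSE]
    upd <- sj > out
    out[upd] <- sj[upd]
    arg[upd] <- j
  }
  list(out = out, arg = arg, ix = ix, n_in = nrow(M))
}

nn_maxpool_bwd <- function(dY, cache) {
  dM <- matrix(0, cache$n_in, ncol(dY))
  for (j in seq_along(cache$ix)) {
    dM[cache$ix[[j]], ] <- dY * (cache$arg == j)
  }
  dM
}

# linear x2 upsampling over time (edge-replicated)
nn_upsample2_fwd <- function(M, B) {
  Tn <- nrow(M) / B
  i_odd <- rep((seq_len(Tn) - 1L) * 2L * B, each = B) + seq_len(B)
  i_even <- i_odd + B
  nxt <- c((B + 1L):(B * Tn), (B * (Tn - 1L) + 1L):(B * Tn))
  out <- matrix(0, 2L * B * Tn, ncol(M))
  out[i_odd, ] <- M
  out[i_even, ] <- 0.5 * (M + M[nxt, , drop = FALSE])
  list(out = out, i_odd = i_odd, i_even = i_even, B = B, Tn = Tn)
}

nn_upsample2_bwd <- function(dY, cache) {
  B <- cache$B; Tn <- cache$Tn
  dE <- dY[cache$i_even, , drop = FALSE]
  dM <- dY[cache$i_odd, , drop = FALSE] + 0.5 * dE
  if (Tn > 1L) {
    lo <- (B + 1L):(B * Tn)
    hi <- 1L:(B * (Tn - 1L))
    dM[lo, ] <- dM[lo, ] + 0.5 * dE[hi, , drop = FALSE]
  }
  last <- (B * (Tn - 1L) + 1L):(B * Tn)
  dM[last, ] <- dM[last, ] + 0.5 * dE[last, , drop = FALSE]
  dM
}

# --- activations / dropout / dense -----------------------------------------

nn_relu_fwd <- function(M) list(out = pmax(M, 0), mask = M > 0)
nn_relu_bwd <- function(dY, cache) dY * cache$mask

nn_elu_fwd <- function(M) {
  out <- M
  neg <- M < 0
  out[neg] <- exp(M[neg]) - 1
  list(out = out, neg = neg)
}
nn_elu_bwd <- function(dY, cache, out) {
  g <- matrix(1, nrow(dY), ncol(dY))
  g[cache$neg] <- out[cache$neg] + 1
  dY * g
}

nn_sigmoid <- function(z) 1 / (1 + exp(-z))

nn_dropout_fwd <- function(M, rate, train) {
  if (!train || rate <= 0) return(list(out = M, mask = NULL))
  mask <- (matrix(stats::runif(length(M)), nrow(M), ncol(M)) >= rate) /
    (1 - rate)
  list(out = M * mask, mask = mask)
}
nn_dropout_bwd <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

nn_dense_fwd <- function(X, W, b) {
  out <- X %*% W
  out + matrix(b, nrow(out), length(b), byrow = TRUE)
}
nn_dense_bwd <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

# --- Adam optimizer --------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# --- layout helpers --------------------------------------------------------

# 64 x 12 x n array -> (B*64) x 12 activation matrix (batch-fastest rows)
segs_to_mat <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(3L, 1L, 2L)), d[3L] * d[1L], d[2L])
}

# inverse of segs_to_mat
mat_to_segs <- function(M, B) {
  Tn <- nrow(M) / B
  aperm(array(M, c(B, Tn, ncol(M))), c(2L, 3L, 1L))
}
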