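#' Configuration for the scalp-to-intracranial GAN translator
#'
#' The generator is a 1-D U-net over the time axis of a 64 x 12 segment;
#' the discriminator is a time-axis CNN over the 64 x 24 channel-wise
#' concatenation of a scalp segment with a (real or estimated) intracranial
#' segment.  The generator objective couples the adversarial binary
#' cross-entropy with `lambda_l2` times the batch-mean Euclidean (Frobenius)
#' distance between the true and estimated intracranial segments.
#'
#' @param base_feature_channels feature channels at the first U-net level
#'   (doubled at every downsampling step; default 16).
#' @param n_levels number of pooling steps; 64 must be divisible by
#'   `2^n_levels` (default 3).
#' @param kernel_time odd time-axis kernel length (fixed default 5).
#' @param lambda_l2 nonnegative weight of the L2-distance regularizer
#'   (default 100).
#' @param dropout_rate discriminator dropout probability (default 0.25).
#' @param learning_rate Adam learning rate (default 1e-3; with the small
#'   parameter budget and the L2-dominated objective this converges stably
#'   where slower image-translation-style rates remain under-fitted at
#'   short schedules).
#' @param batch_size minibatch size (default 32).
#' @param n_epochs training epochs (default 100).
#' @param adversarial_mode `"non_saturating"` (default; the generator
#'   maximizes `log D` on fakes, sharing fixed points with the minimax
#'   objective but avoiding its early saturation) or `"minimax"` (the
#'   literal objective).
#' @param l2_squared use the squared Frobenius distance instead of the norm
#'   (default `FALSE`: the norm itself).
#' @param seed integer seed for initialization, batching, and dropout.
#' @return an object of class `translator_config`.
#' @export
translator_config <- function(base_feature_channels = 16L, n_levels = 3L,
                              kernel_time = 5L, lambda_l2 = 100,
                              dropout_rate = 0.25, learning_rate = 1e-3,
                              batch_size = 32L, n_epochs = 100L,
                              adversarial_mode = c("non_saturating",
                                                   "minimax"),
                              l2_squared = FALSE, seed = 1L) {
  adversarial_mode <- match.arg(adversarial_mode)
  cfg <- list(base_feature_channels = as.integer(base_feature_channels),
              n_levels = as.integer(n_levels),
              kernel_time = as.integer(kernel_time),
              lambda_l2 = lambda_l2, dropout_rate = dropout_rate,
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              n_epochs = as.integer(n_epochs),
              adversarial_mode = adversarial_mode,
              l2_squared = isTRUE(l2_squared), seed = as.integer(seed))
  if (cfg$kernel_time %% 2L == 0L) stop_invalid("kernel_time must be odd")
  if (cfg$n_levels < 1L) stop_invalid("n_levels must be >= 1")
  if (64L %% (2L^cfg$n_levels) != 0L) {
    stop_invalid("64 must be divisible by 2^n_levels")
  }
  if (cfg$lambda_l2 < 0) stop_invalid("lambda_l2 must be nonnegative")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    stop_invalid("dropout_rate must lie in [0, 1)")
  }
  structure(cfg, class = "translator_config")
}

gen_enc_width <- function(cfg, l) cfg$base_feature_channels * 2L^(l - 1L)

# --- generator -------------------------------------------------------------

init_generator_params <- function(cfg) {
  k <- cfg$kernel_time
  L <- cfg$n_levels
  p <- list()
  cin <- 12L
  for (l in seq_len(L)) {
    cout <- gen_enc_width(cfg, l)
    p[[paste0("e", l, "_W")]] <- glorot(k * cin, cout, c(k * cin, cout))
    p[[paste0("e", l, "_b")]] <- numeric(cout)
    p[[paste0("e", l, "_g")]] <- rep(1, cout)
    p[[paste0("e", l, "_be")]] <- numeric(cout)
    cin <- cout
  }
  cbot <- gen_enc_width(cfg, L + 1L)
  p$bo_W <- glorot(k * cin, cbot, c(k * cin, cbot))
  p$bo_b <- numeric(cbot)
  p$bo_g <- rep(1, cbot)
  p$bo_be <- numeric(cbot)
  fin <- cbot
  for (l in rev(seq_len(L))) {
    half <- fin %/% 2L
    skip <- gen_enc_width(cfg, l)
    p[[paste0("d", l, "_pW")]] <- glorot(fin, half, c(fin, half))
    p[[paste0("d", l, "_pb")]] <- numeric(half)
    cat_w <- half + skip
    p[[paste0("d", l, "_aW")]] <- glorot(k * cat_w, skip, c(k * cat_w, skip))
    p[[paste0("d", l, "_ab")]] <- numeric(skip)
    p[[paste0("d", l, "_bW")]] <- glorot(k * skip, skip, c(k * skip, skip))
    p[[paste0("d", l, "_bb")]] <- numeric(skip)
    p[[paste0("d", l, "_g")]] <- rep(1, skip)
    p[[paste0("d", l, "_be")]] <- numeric(skip)
    fin <- skip
  }
  w1 <- gen_enc_width(cfg, 1L)
  p$f_W <- glorot(w1, w1, c(w1, w1))
  p$f_b <- numeric(w1)
  p$o_W <- glorot(w1, 12L, c(w1, 12L))
  p$o_b <- numeric(12L)
  p
}

generator_forward <- function(par, M, B, cfg) {
  L <- cfg$n_levels
  cache <- list(enc = vector("list", L), dec = vector("list", L))
  cur <- M
  for (l in seq_len(L)) {
    cv <- nn_conv_fwd(cur, par[[paste0("e", l, "_W")]],
                      par[[paste0("e", l, "_b")]], B)
    no <- nn_tnorm_fwd(cv$out, par[[paste0("e", l, "_g")]],
                       par[[paste0("e", l, "_be")]], B)
    rl <- nn_relu_fwd(no$out)
    pl <- nn_avgpool2_fwd(rl$out, B)
    cache$enc[[l]] <- list(cv = cv, no = no, rl = rl, pl = pl,
                           skip = rl$out)
    cur <- pl$out
  }
  bcv <- nn_conv_fwd(cur, par$bo_W, par$bo_b, B)
  bno <- nn_tnorm_fwd(bcv$out, par$bo_g, par$bo_be, B)
  brl <- nn_relu_fwd(bno$out)
  cache$bot <- list(cv = bcv, no = bno, rl = brl)
  cur <- brl$out
  for (l in rev(seq_len(L))) {
    up <- nn_upsample2_fwd(cur, B)
    pin <- up$out
    pW <- par[[paste0("d", l, "_pW")]]
    pout <- nn_dense_fwd(pin, pW, par[[paste0("d", l, "_pb")]])
    prl <- nn_relu_fwd(pout)
    catm <- cbind(prl$out, cache$enc[[l]]$skip)
    acv <- nn_conv_fwd(catm, par[[paste0("d", l, "_aW")]],
                       par[[paste0("d", l, "_ab")]], B)
    arl <- nn_relu_fwd(acv$out)
    bcv2 <- nn_conv_fwd(arl$out, par[[paste0("d", l, "_bW")]],
                        par[[paste0("d", l, "_bb")]], B)
    no2 <- nn_tnorm_fwd(bcv2$out, par[[paste0("d", l, "_g")]],
                        par[[paste0("d", l, "_be")]], B)
    rl2 <- nn_relu_fwd(no2$out)
    cache$dec[[l]] <- list(up = up, pin = pin, prl = prl, catm = catm,
                           acv = acv, arl = arl, bcv = bcv2, no = no2,
                           rl = rl2, half = ncol(pW))
    cur <- rl2$out
  }
  fino <- nn_dense_fwd(cur, par$f_W, par$f_b)
  frl <- nn_relu_fwd(fino)
  out <- nn_dense_fwd(frl$out, par$o_W, par$o_b)
  cache$fin_in <- cur
  cache$frl <- frl
  list(out = out, cache = cache)
}

generator_backward <- function(par, cache, dout, B, cfg) {
  L <- cfg$n_levels
  g <- list()
  db <- nn_dense_bwd(dout, cache$frl$out, par$o_W)
  g$o_W <- db$dW; g$o_b <- db$db
  dcur <- nn_relu_bwd(db$dX, cache$frl)
  db <- nn_dense_bwd(dcur, cache$fin_in, par$f_W)
  g$f_W <- db$dW; g$f_b <- db$db
  dcur <- db$dX
  dskip <- vector("list", L)
  for (l in seq_len(L)) {                       # dec1 ran last -> first back
    dc <- cache$dec[[l]]
    dcur <- nn_relu_bwd(dcur, dc$rl)
    nb <- nn_tnorm_bwd(dcur, dc$no, par[[paste0("d", l, "_g")]], B)
    g[[paste0("d", l, "_g")]] <- nb$dgamma
    g[[paste0("d", l, "_be")]] <- nb$dbeta
    cb <- nn_conv_bwd(nb$dM, dc$bcv, par[[paste0("d", l, "_bW")]], B)
    g[[paste0("d", l, "_bW")]] <- cb$dW
    g[[paste0("d", l, "_bb")]] <- cb$db
    da <- nn_relu_bwd(cb$dM, dc$arl)
    ca <- nn_conv_bwd(da, dc$acv, par[[paste0("d", l, "_aW")]], B)
    g[[paste0("d", l, "_aW")]] <- ca$dW
    g[[paste0("d", l, "_ab")]] <- ca$db
    half <- dc$half
    dP <- ca$dM[, seq_len(half), drop = FALSE]
    dskip[[l]] <- ca$dM[, (half + 1L):ncol(ca$dM), drop = FALSE]
    dP <- nn_relu_bwd(dP, dc$prl)
    pb <- nn_dense_bwd(dP, dc$pin, par[[paste0("d", l, "_pW")]])
    g[[paste0("d", l, "_pW")]] <- pb$dW
    g[[paste0("d", l, "_pb")]] <- pb$db
    dcur <- nn_upsample2_bwd(pb$dX, dc$up)
  }
  bo <- cache$bot
  dcur <- nn_relu_bwd(dcur, bo$rl)
  nb <- nn_tnorm_bwd(dcur, bo$no, par$bo_g, B)
  g$bo_g <- nb$dgamma; g$bo_be <- nb$dbeta
  cb <- nn_conv_bwd(nb$dM, bo$cv, par$bo_W, B)
  g$bo_W <- cb$dW; g$bo_b <- cb$db
  dcur <- cb$dM
  for (l in rev(seq_len(L))) {
    ec <- cache$enc[[l]]
    dsk <- nn_avgpool2_bwd(dcur, ec$pl) + dskip[[l]]
    dsk <- nn_relu_bwd(dsk, ec$rl)
    nb <- nn_tnorm_bwd(dsk, ec$no, par[[paste0("e", l, "_g")]], B)
    g[[paste0("e", l, "_g")]] <- nb$dgamma
    g[[paste0("e", l, "_be")]] <- nb$dbeta
    cb <- nn_conv_bwd(nb$dM, ec$cv, par[[paste0("e", l, "_W")]], B)
    g[[paste0("e", l, "_W")]] <- cb$dW
    g[[paste0("e", l, "_b")]] <- cb$db
    dcur <- cb$dM
  }
  g
}

# --- discriminator ---------------------------------------------------------

disc_widths <- function(cfg) cfg$base_feature_channels * c(2L, 4L, 8L)

init_discriminator_params <- function(cfg) {
  k <- cfg$kernel_time
  w <- disc_widths(cfg)
  p <- list()
  cin <- 24L
  for (i in seq_along(w)) {
    p[[paste0("c", i, "_W")]] <- glorot(k * cin, w[i], c(k * cin, w[i]))
    p[[paste0("c", i, "_b")]] <- numeric(w[i])
    cin <- w[i]
  }
  t_out <- 64L %/% 2L^length(w)
  p$fc_W <- glorot(t_out * cin, 1L, c(t_out * cin, 1L))
  p$fc_b <- numeric(1L)
  p
}

discriminator_forward <- function(par, M, B, cfg, train = FALSE) {
  w <- disc_widths(cfg)
  cache <- list(blocks = vector("list", length(w)))
  cur <- M
  for (i in seq_along(w)) {
    cv <- nn_conv_fwd(cur, par[[paste0("c", i, "_W")]],
                      par[[paste0("c", i, "_b")]], B)
    rl <- nn_relu_fwd(cv$out)
    dr <- nn_dropout_fwd(rl$out, cfg$dropout_rate, train)
    mp <- nn_maxpool_fwd(dr$out, B, 2L)
    cache$blocks[[i]] <- list(cv = cv, rl = rl, dr = dr, mp = mp)
    cur <- mp$out
  }
  Tn <- nrow(cur) / B
  flat <- cur
  dim(flat) <- c(B, Tn * ncol(cur))
  z <- nn_dense_fwd(flat, par$fc_W, par$fc_b)
  cache$flat <- flat
  cache$flat_dims <- c(B * Tn, ncol(cur))
  list(p = as.numeric(nn_sigmoid(z)), z = as.numeric(z), cache = cache)
}

# dz: gradient of the loss w.r.t. the pre-sigmoid logit, length B
discriminator_backward <- function(par, cache, dz, B, cfg) {
  g <- list()
  dzm <- matrix(dz, B, 1L)
  db <- nn_dense_bwd(dzm, cache$flat, par$fc_W)
  g$fc_W <- db$dW; g$fc_b <- db$db
  dcur <- db$dX
  dim(dcur) <- cache$flat_dims
  for (i in rev(seq_along(cache$blocks))) {
    bl <- cache$blocks[[i]]
    dcur <- nn_maxpool_bwd(dcur, bl$mp)
    dcur <- nn_dropout_bwd(dcur, bl$dr)
    dcur <- nn_relu_bwd(dcur, bl$rl)
    cb <- nn_conv_bwd(dcur, bl$cv, par[[paste0("c", i, "_W")]], B)
    g[[paste0("c", i, "_W")]] <- cb$dW
    g[[paste0("c", i, "_b")]] <- cb$db
    dcur <- cb$dM
  }
  g$d_input <- dcur
  g
}

#' Build an untrained generator
#'
#' @param cfg a [translator_config()].
#' @return object of class `gan_generator` with seeded initial parameters.
#' @export
build_generator <- function(cfg = translator_config()) {
  stopifnot(inherits(cfg, "translator_config"))
  params <- with_seed(cfg$seed, init_generator_params(cfg))
  structure(list(params = params, cfg = cfg), class = "gan_generator")
}

#' Build an untrained discriminator
#'
#' @param cfg a [translator_config()].
#' @return object of class `gan_discriminator`.
#' @export
build_discriminator <- function(cfg = translator_config()) {
  stopifnot(inherits(cfg, "translator_config"))
  params <- with_seed(cfg$seed + 1L, init_discriminator_params(cfg))
  structure(list(params = params, cfg = cfg), class = "gan_discriminator")
}

#' Apply a generator to a batch of scalp segments
#'
#' @param gen a `gan_generator` (or the `$generator` of a trained
#'   translator).
#' @param x `64 x 12 x n` array (or single 64 x 12 matrix).
#' @return `64 x 12 x n` array of estimated intracranial segments.
#' @export
generator_apply <- function(gen, x) {
  x <- as_seg_array(x)
  B <- dim(x)[3L]
  M <- segs_to_mat(x)
  out <- generator_forward(gen$params, M, B, gen$cfg)$out
  mat_to_segs(out, B)
}

#' Apply a discriminator to scalp/intracranial segment pairs
#'
#' The discriminator consumes the channel-axis concatenation
#' `(scalp columns 1-12, intracranial columns 13-24)`.
#'
#' @param disc a `gan_discriminator`.
#' @param x scalp `64 x 12 x n` array.
#' @param y intracranial `64 x 12 x n` array (real or estimated).
#' @return numeric vector of n probabilities in (0, 1); dropout is disabled,
#'   so repeated calls are identical.
#' @export
discriminator_apply <- function(disc, x, y) {
  x <- as_seg_array(x); y <- as_seg_array(y)
  if (!identical(dim(x), dim(y))) stop_invalid("x and y shapes differ")
  B <- dim(x)[3L]
  M <- cbind(segs_to_mat(x), segs_to_mat(y))
  discriminator_forward(disc$params, M, B, disc$cfg, train = FALSE)$p
}

as_seg_array <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  if (length(d) != 3L || d[1L] != 64L || d[2L] != 12L) {
    stop_invalid("expected a 64 x 12 x n segment array, got dims ",
                 paste(d, collapse = " x "))
  }
  x
}

# --- losses ----------------------------------------------------------------

#' Adversarial (min-max) objective estimate
#'
#' Batch estimate of `E[log D(X,Y)] + E[log(1 - D(X, G(X)))]` — the
#' quantity the discriminator ascends and the generator (through its second
#' term) descends.  Probabilities are clamped at 1e-7 before the logs.
#'
#' @param d_real discriminator probabilities on real pairs, in (0, 1).
#' @param d_fake discriminator probabilities on generated pairs.
#' @return scalar objective value (nonpositive; 0 at the discriminator's
#'   optimum).
#' @export
adversarial_value <- function(d_real, d_fake) {
  if (!length(d_real) || !length(d_fake)) {
    stop_invalid("adversarial_value needs non-empty probability batches")
  }
  eps <- 1e-7
  dr <- pmin(pmax(d_real, eps), 1 - eps)
  df <- pmin(pmax(d_fake, eps), 1 - eps)
  mean(log(dr)) + mean(log(1 - df))
}

#' Batch-mean Euclidean distance between segment batches
#'
#' Mean over the batch of the per-segment Frobenius norm `||Y - Yhat||_2`
#' (the norm itself, not its square, unless `squared = TRUE`).
#'
#' @param y_true,y_est `64 x 12 x n` arrays (or single matrices) of equal
#'   shape.
#' @param squared if `TRUE` return the mean squared norm.
#' @return scalar distance.
#' @export
l2_distance <- function(y_true, y_est, squared = FALSE) {
  y_true <- as_seg_array(y_true); y_est <- as_seg_array(y_est)
  if (!identical(dim(y_true), dim(y_est))) {
    stop_invalid("y_true and y_est shapes differ")
  }
  d2 <- apply((y_true - y_est)^2, 3L, sum)
  if (squared) mean(d2) else mean(sqrt(d2))
}

#' Generator objective (adversarial term plus weighted L2 distance)
#'
#' @param d_fake discriminator probabilities on generated pairs.
#' @param y_true,y_est true and estimated intracranial segment batches.
#' @param lambda_l2 nonnegative L2 weight.
#' @param adversarial_mode `"non_saturating"` or `"minimax"`; see
#'   [translator_config()].
#' @param squared use squared L2 distance.
#' @return scalar loss the generator descends.
#' @export
generator_objective <- function(d_fake, y_true, y_est, lambda_l2,
                                adversarial_mode = "non_saturating",
                                squared = FALSE) {
  if (lambda_l2 < 0) stop_invalid("lambda_l2 must be nonnegative")
  eps <- 1e-7
  df <- pmin(pmax(d_fake, eps), 1 - eps)
  adv <- switch(adversarial_mode,
                minimax = mean(log(1 - df)),
                non_saturating = -mean(log(df)),
                stop_invalid("unknown adversarial_mode"))
  adv + lambda_l2 * l2_distance(y_true, y_est, squared = squared)
}

# --- training --------------------------------------------------------------

channel_stats <- function(a) {
  m <- apply(a, 2L, mean)
  s <- apply(a, 2L, stats::sd)
  s[s < 1e-8] <- 1
  list(mean = m, sd = s)
}

standardize_mat <- function(M, st) {
  sweep(sweep(M, 2L, st$mean), 2L, st$sd, "/")
}

unstandardize_mat <- function(M, st) {
  sweep(sweep(M, 2L, st$sd, "*"), 2L, st$mean, "+")
}

#' Train the scalp-to-intracranial GAN
#'
#' Alternating per-batch updates: one discriminator step ascending the
#' adversarial objective (implemented as descending its negation), then one
#' generator step descending the adversarial term plus
#' `lambda_l2 * l2_distance`.  Segments are standardized per channel with
#' training-set statistics before entering either network; the stored
#' statistics invert the transform at inference.  Fully reproducible given
#' (data, config, seed).
#'
#' @param train a [segment_set()] whose every segment carries both `x` and
#'   `y` matrices.
#' @param cfg a [translator_config()].
#' @param verbose print per-epoch losses.
#' @return object of class `trained_translator`: fields `generator`,
#'   `discriminator`, `config`, `x_stats`, `y_stats`, and `loss_history`
#'   (per-epoch data.frame of the adversarial value, standardized L2
#'   estimate, L2 in uV, and generator loss).
#' @export
train_translator <- function(train, cfg = translator_config(),
                             verbose = FALSE) {
  stopifnot(inherits(train, "segment_set"),
            inherits(cfg, "translator_config"))
  if (is.null(train$y)) {
    stop_invalid("training segments must carry intracranial ground truth y")
  }
  n <- n_segments(train)
  if (n < 1L) stop_invalid("empty training set")
  x_stats <- channel_stats(matrix(aperm(train$x, c(1L, 3L, 2L)), ncol = 12L))
  y_stats <- channel_stats(matrix(aperm(train$y, c(1L, 3L, 2L)), ncol = 12L))
  with_seed(cfg$seed, {
    gpar <- init_generator_params(cfg)
    dpar <- init_discriminator_params(cfg)
    gopt <- adam_init(gpar)
    dopt <- adam_init(dpar)
    hist <- vector("list", cfg$n_epochs)
    for (ep in seq_len(cfg$n_epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_adv <- ep_l2 <- ep_lg <- ep_l2uv <- numeric(length(starts))
      for (s in seq_along(starts)) {
        bi <- idx[starts[s]:min(starts[s] + cfg$batch_size - 1L, n)]
        B <- length(bi)
        Mx <- standardize_mat(segs_to_mat(train$x[, , bi, drop = FALSE]),
                              x_stats)
        My <- standardize_mat(segs_to_mat(train$y[, , bi, drop = FALSE]),
                              y_stats)
        # --- discriminator step (generator forward reused below: G is
        # unchanged until its own update)
        gfwd <- generator_forward(gpar, Mx, B, cfg)
        yhat <- gfwd$out
        dreal <- discriminator_forward(dpar, cbind(Mx, My), B, cfg,
                                       train = TRUE)
        dfake <- discriminator_forward(dpar, cbind(Mx, yhat), B, cfg,
                                       train = TRUE)
        # descend -[log D(real) + log(1 - D(fake))]: logit gradients
        gr_real <- discriminator_backward(dpar, dreal$cache,
                                          (dreal$p - 1) / B, B, cfg)
        gr_fake <- discriminator_backward(dpar, dfake$cache,
                                          dfake$p / B, B, cfg)
        dgrads <- mapply(function(a, b) a + b,
                         gr_real[names(dpar)], gr_fake[names(dpar)],
                         SIMPLIFY = FALSE)
        upd <- adam_step(dpar, dgrads, dopt, cfg$learning_rate)
        dpar <- upd$params; dopt <- upd$state
        ep_adv[s] <- adversarial_value(dreal$p, dfake$p)
        # --- generator step (against the just-updated discriminator)
        dfake <- discriminator_forward(dpar, cbind(Mx, yhat), B, cfg,
                                       train = TRUE)
        dz <- if (cfg$adversarial_mode == "non_saturating") {
          (dfake$p - 1) / B
        } else {
          -dfake$p / B
        }
        dback <- discriminator_backward(dpar, dfake$cache, dz, B, cfg)
        dyhat_adv <- dback$d_input[, 13L:24L, drop = FALSE]
        diff <- yhat - My
        A2 <- diff^2; dim(A2) <- c(B, nrow(diff) / B * 12L)
        seg_norm <- sqrt(rowSums(A2))
        l2_std <- mean(seg_norm)
        dyhat_l2 <- if (cfg$l2_squared) {
          cfg$lambda_l2 * 2 * diff / B
        } else {
          cfg$lambda_l2 * diff /
            (B * pmax(seg_norm, 1e-8)[rep(seq_len(B), nrow(diff) / B)])
        }
        ggrads <- generator_backward(gpar, gfwd$cache,
                                     dyhat_adv + dyhat_l2, B, cfg)
        upd <- adam_step(gpar, ggrads, gopt, cfg$learning_rate)
        gpar <- upd$params; gopt <- upd$state
        adv_term <- if (cfg$adversarial_mode == "non_saturating") {
          -mean(log(pmax(dfake$p, 1e-7)))
        } else {
          mean(log(pmax(1 - dfake$p, 1e-7)))
        }
        l2_term <- if (cfg$l2_squared) mean(seg_norm^2) else l2_std
        ep_l2[s] <- l2_term
        ep_lg[s] <- adv_term + cfg$lambda_l2 * l2_term
        ep_l2uv[s] <- l2_distance(
          mat_to_segs(unstandardize_mat(My, y_stats), B),
          mat_to_segs(unstandardize_mat(yhat, y_stats), B))
      }
      hist[[ep]] <- data.frame(epoch = ep, l_gan = mean(ep_adv),
                               l2 = mean(ep_l2), l2_uv = mean(ep_l2uv),
                               l_g = mean(ep_lg))
      if (verbose) {
        message(sprintf("epoch %3d: L_GAN=%8.4f  L2=%7.3f  L_G=%9.3f",
                        ep, mean(ep_adv), mean(ep_l2), mean(ep_lg)))
      }
    }
    structure(
      list(generator = structure(list(params = gpar, cfg = cfg),
                                 class = "gan_generator"),
           discriminator = structure(list(params = dpar, cfg = cfg),
                                     class = "gan_discriminator"),
           config = cfg, x_stats = x_stats, y_stats = y_stats,
           loss_history = do.call(rbind, hist)),
      class = "trained_translator")
  })
}

#' Translate scalp segments into estimated intracranial segments
#'
#' Deterministic inference: standardizes with the stored training-set scalp
#' statistics, applies the generator, and inverts the intracranial
#' standardization so the output is in uV.
#'
#' @param model a `trained_translator`.
#' @param x `64 x 12 x n` array, single 64 x 12 matrix, or [segment_set()].
#' @return `64 x 12 x n` array of estimated intracranial segments (uV).
#' @export
translate <- function(model, x) {
  stopifnot(inherits(model, "trained_translator"))
  if (inherits(x, "segment_set")) x <- x$x
  x <- as_seg_array(x)
  B <- dim(x)[3L]
  M <- standardize_mat(segs_to_mat(x), model$x_stats)
  out <- generator_forward(model$generator$params, M, B, model$config)$out
  mat_to_segs(unstandardize_mat(out, model$y_stats), B)
}

#' Count trainable parameters
#'
#' @param model a `trained_translator`, `gan_generator`,
#'   `gan_discriminator`, or a raw named list of parameter arrays.
#' @return total number of trainable scalars.
#' @export
count_parameters <- function(model) {
  plists <- if (inherits(model, "trained_translator")) {
    list(model$generator$params, model$discriminator$params)
  } else if (inherits(model, c("gan_generator", "gan_discriminator",
                               "trained_detector"))) {
    list(model$params)
  } else if (is.list(model)) {
    list(model)
  } else stop_invalid("cannot count parameters of a ", class(model)[1L])
  sum(vapply(plists, function(p) sum(vapply(p, length, 1L)), 1))
}

#' @export
print.trained_translator <- function(x, ...) {
  cat(sprintf(
    "<trained_translator> %d epochs, %s parameters (G+D), lambda_l2=%g\n",
    nrow(x$loss_history), format(count_parameters(x), big.mark = ","),
    x$config$lambda_l2))
  invisible(x)
}
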