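test_that("translator configuration invariants are enforced", {
  expect_error(translator_config(kernel_time = 4), "odd")
  expect_error(translator_config(n_levels = 0), "n_levels")
  expect_error(translator_config(n_levels = 7), "divisible")
  expect_error(translator_config(lambda_l2 = -1), "nonnegative")
  expect_error(translator_config(dropout_rate = 1), "dropout")
})

test_that("generator halves time and doubles features along the contracting path", {
  cfg <- translator_config(seed = 4)
  gen <- build_generator(cfg)
  B <- 2L
  x <- array(rnorm(64 * 12 * B), c(64, 12, B))
  out <- generator_apply(gen, x)
  expect_equal(dim(out), c(64L, 12L, B))
  fw <- ieegmap:::generator_forward(gen$params, ieegmap:::segs_to_mat(x),
                                    B, cfg)
  t_lens <- vapply(fw$cache$enc, function(e) nrow(e$pl$out) / B, 1)
  expect_equal(t_lens, c(32, 16, 8))          # 64 -> 32 -> 16 -> 8
  widths <- vapply(fw$cache$enc, function(e) ncol(e$skip), 1L)
  expect_equal(widths, c(16L, 32L, 64L))      # doubling from base 16
  # single segment matrix also accepted
  one <- generator_apply(gen, x[, , 1])
  expect_equal(dim(one), c(64L, 12L, 1L))
})

test_that("discriminator maps concatenated pairs to a probability, scalp first", {
  cfg <- translator_config(seed = 4)
  disc <- build_discriminator(cfg)
  set.seed(1)
  x <- array(rnorm(64 * 12 * 3), c(64, 12, 3))
  y <- array(rnorm(64 * 12 * 3), c(64, 12, 3))
  p <- discriminator_apply(disc, x, y)
  expect_length(p, 3L)
  expect_true(all(p > 0 & p < 1))
  # concatenation order: (scalp 1-12, intracranial 13-24)
  M <- cbind(ieegmap:::segs_to_mat(x), ieegmap:::segs_to_mat(y))
  pm <- ieegmap:::discriminator_forward(disc$params, M, 3L, cfg,
                                        train = FALSE)$p
  expect_equal(p, pm)
  expect_false(isTRUE(all.equal(p, discriminator_apply(disc, y, x))))
  # dropout disabled at inference: deterministic
  expect_identical(p, discriminator_apply(disc, x, y))
  expect_error(discriminator_apply(disc, x, y[, , 1:2]), "differ")
})

test_that("adversarial value matches its closed forms and a BCE oracle", {
  expect_equal(adversarial_value(0.5, 0.5), 2 * log(0.5), tolerance = 1e-12)
  expect_equal(adversarial_value(1 - 1e-9, 1e-9), 0, tolerance = 1e-5)
  expect_error(adversarial_value(numeric(), 0.5), "non-empty")
  # independent elementwise log-loss oracle on 100 seeded batches
  set.seed(42)
  for (b in 1:100) {
    n <- sample(1:16, 1)
    dr <- runif(n, 1e-4, 1 - 1e-4)
    df <- runif(n, 1e-4, 1 - 1e-4)
    bce <- function(p, target) {
      -mean(target * log(p) + (1 - target) * log(1 - p))
    }
    oracle <- -(bce(dr, rep(1, n)) + bce(df, rep(0, n)))
    expect_equal(adversarial_value(dr, df), oracle, tolerance = 1e-6)
  }
})

test_that("l2 distance is the batch mean of per-segment Frobenius norms", {
  a <- array(1, c(64, 12, 1))
  z <- array(0, c(64, 12, 1))
  expect_equal(l2_distance(a, a), 0)
  expect_equal(l2_distance(a, z), sqrt(768), tolerance = 1e-12)
  # per-segment norms 3 and 5 average to 4
  two <- array(0, c(64, 12, 2))
  two[, , 1] <- 3 / sqrt(768)
  two[, , 2] <- 5 / sqrt(768)
  zz <- array(0, c(64, 12, 2))
  expect_equal(l2_distance(two, zz), 4, tolerance = 1e-12)
  expect_error(l2_distance(a, array(0, c(64, 12, 2))), "differ")
  # oracle equivalence on seeded random batches
  set.seed(9)
  for (b in 1:100) {
    n <- sample(1:8, 1)
    y1 <- array(rnorm(768 * n), c(64, 12, n))
    y2 <- array(rnorm(768 * n), c(64, 12, n))
    oracle <- mean(vapply(seq_len(n), function(i) {
      sqrt(sum((y1[, , i] - y2[, , i])^2))
    }, 1))
    expect_equal(l2_distance(y1, y2), oracle, tolerance = 1e-6)
  }
})

test_that("generator objective composes the adversarial and L2 terms", {
  set.seed(3)
  y <- array(rnorm(768 * 2), c(64, 12, 2))
  yh <- array(rnorm(768 * 2), c(64, 12, 2))
  df <- runif(4, 0.1, 0.9)
  # lambda = 0 reduces to the adversarial term alone
  expect_equal(generator_objective(df, y, yh, 0, "minimax"),
               mean(log(1 - df)))
  expect_equal(generator_objective(df, y, yh, 0, "non_saturating"),
               -mean(log(df)))
  # perfect reconstruction leaves only the adversarial term
  expect_equal(generator_objective(df, y, y, 100, "minimax"),
               mean(log(1 - df)))
  # adversarial term -1, l2 = 2, lambda = 100 -> 199
  df1 <- rep(1 - exp(-1), 3)                 # mean(log(1 - df1)) = -1
  y2 <- array(0, c(64, 12, 2))
  yh2 <- array(2 / sqrt(768), c(64, 12, 2))  # per-segment norm 2
  expect_equal(generator_objective(df1, y2, yh2, 100, "minimax"), 199,
               tolerance = 1e-9)
  expect_error(generator_objective(df, y, yh, -5), "nonnegative")
})

test_that("generator objective is non-decreasing in lambda when L2 > 0", {
  set.seed(5)
  y <- array(rnorm(768), c(64, 12, 1))
  yh <- array(rnorm(768), c(64, 12, 1))
  df <- runif(5, 0.05, 0.95)
  lams <- c(0, 0.5, 1, 10, 100, 1000)
  vals <- vapply(lams, function(l) generator_objective(df, y, yh, l), 1)
  expect_true(all(diff(vals) > 0))
})

test_that("parameter counting matches layer-arithmetic oracles and the budget", {
  # kernel-5 convolution, 12 in / 16 out, with bias: 5*12*16 + 16
  expect_equal(count_parameters(list(W = matrix(0, 5 * 12, 16),
                                     b = numeric(16))), 976)
  # dense 16 -> 12 with bias
  expect_equal(count_parameters(list(W = matrix(0, 16, 12),
                                     b = numeric(12))), 204)
  cfg <- translator_config()
  total <- count_parameters(build_generator(cfg)) +
    count_parameters(build_discriminator(cfg))
  expect_lte(total, 250000)
  expect_gte(3.12e6 / total, 12)
})

test_that("a discriminator ascent step does not decrease the minimax objective", {
  cfg <- translator_config(base_feature_channels = 4, n_levels = 2,
                           dropout_rate = 0, seed = 8)
  set.seed(31)
  B <- 8L
  x <- array(rnorm(768 * B), c(64, 12, B))
  y <- array(rnorm(768 * B), c(64, 12, B))
  yh <- array(rnorm(768 * B), c(64, 12, B))
  par <- build_discriminator(cfg)$params
  Mr <- cbind(ieegmap:::segs_to_mat(x), ieegmap:::segs_to_mat(y))
  Mf <- cbind(ieegmap:::segs_to_mat(x), ieegmap:::segs_to_mat(yh))
  value <- function(p) {
    adversarial_value(
      ieegmap:::discriminator_forward(p, Mr, B, cfg, FALSE)$p,
      ieegmap:::discriminator_forward(p, Mf, B, cfg, FALSE)$p)
  }
  v0 <- value(par)
  fr <- ieegmap:::discriminator_forward(par, Mr, B, cfg, FALSE)
  ff <- ieegmap:::discriminator_forward(par, Mf, B, cfg, FALSE)
  gr <- ieegmap:::discriminator_backward(par, fr$cache, (fr$p - 1) / B, B,
                                         cfg)
  gf <- ieegmap:::discriminator_backward(par, ff$cache, ff$p / B, B, cfg)
  for (nm in names(par)) {                    # small plain gradient step
    par[[nm]] <- par[[nm]] - 1e-3 * (gr[[nm]] + gf[[nm]])
  }
  expect_gte(value(par), v0)
})

test_that("translator training is reproducible and learns an easy identity map", {
  set.seed(12)
  n <- 32L
  x <- array(rnorm(768 * n), c(64, 12, n))
  segs <- segment_set(x, x + array(rnorm(768 * n, sd = 0.05),
                                   c(64, 12, n)),
                      rep(c(1L, 0L), n / 2), "T1")
  cfg <- translator_config(n_epochs = 8, seed = 17)
  m1 <- train_translator(segs, cfg)
  m2 <- train_translator(segs, cfg)
  expect_equal(m1$loss_history, m2$loss_history)
  expect_identical(m1$generator$params, m2$generator$params)
  # the standardized L2 estimate falls over training
  expect_lt(m1$loss_history$l2[8], m1$loss_history$l2[1])
  # inference: deterministic, shape-preserving, finite on zero input
  yh <- translate(m1, x[, , 1:3])
  expect_equal(dim(yh), c(64L, 12L, 3L))
  expect_identical(yh, translate(m1, x[, , 1:3]))
  expect_true(all(is.finite(translate(m1, array(0, c(64, 12, 2))))))
  # missing ground truth is rejected
  no_y <- segment_set(x, NULL, rep(c(1L, 0L), n / 2), "T1")
  expect_error(train_translator(no_y, cfg), "ground truth")
})
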