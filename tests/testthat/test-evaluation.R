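test_that("confusion-matrix metrics match their defining formulas", {
  # tp=65 fn=35 tn=70 fp=30 -> sen .65, spc .70, acc .675
  labels <- rep(c(1L, 0L), each = 100L)
  preds <- c(rep(1L, 65), rep(0L, 35), rep(0L, 70), rep(1L, 30))
  m <- compute_metrics(labels, preds, "S1")
  expect_equal(m$tp, 65L); expect_equal(m$fn, 35L)
  expect_equal(m$tn, 70L); expect_equal(m$fp, 30L)
  expect_equal(m$sen, 0.65)
  expect_equal(m$spc, 0.70)
  expect_equal(m$acc, 0.675)
  # perfect classifier
  p <- compute_metrics(labels, labels)
  expect_equal(c(p$acc, p$sen, p$spc), c(1, 1, 1))
  # all-positive on balanced labels
  ap <- compute_metrics(labels, rep(1L, 200))
  expect_equal(c(ap$acc, ap$sen, ap$spc), c(0.5, 1, 0))
  expect_error(compute_metrics(1, c(1, 0)), "equal length")
  expect_error(compute_metrics(integer(), integer()), "empty")
})

test_that("metric identities hold on random confusion counts", {
  set.seed(6)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    labels <- rbinom(n, 1, 0.5)
    preds <- rbinom(n, 1, 0.5)
    m <- compute_metrics(labels, preds)
    expect_equal(m$acc, (m$tp + m$tn) / n)
    if (m$tp + m$fn > 0) expect_equal(m$sen, m$tp / (m$tp + m$fn))
    if (m$tn + m$fp > 0) expect_equal(m$spc, m$tn / (m$tn + m$fp))
    expect_equal(m$tp + m$tn + m$fp + m$fn, n)
    # with balanced test sets, acc is exactly the SEN/SPC midpoint
    if (sum(labels == 1) == sum(labels == 0)) {
      expect_equal(m$acc, (m$sen + m$spc) / 2)
    }
  }
})

test_that("stratified 70/10/20 split partitions the segments", {
  segs <- random_segment_set(n = 100, seed = 4)
  segs$x[1, 1, ] <- seq_len(100)              # traceable segment identity
  sp <- split_intra(segs, seed = 3)
  expect_equal(n_segments(sp$train), 70L)
  expect_equal(n_segments(sp$val), 10L)
  expect_equal(n_segments(sp$test), 20L)
  ids <- sort(c(sp$train$x[1, 1, ], sp$val$x[1, 1, ], sp$test$x[1, 1, ]))
  expect_equal(ids, as.numeric(1:100))        # exhaustive and disjoint
  for (part in sp) {                          # both classes everywhere
    expect_setequal(unique(part$label), c(0L, 1L))
  }
  # reproducible
  sp2 <- split_intra(segs, seed = 3)
  expect_equal(sp$train$x, sp2$train$x)
  expect_error(split_intra(subset_segments(segs, 1:4), seed = 1),
               "too few")
  expect_error(split_intra(segs, fractions = c(0.5, 0.5, 0.5)), "summing")
})

test_that("average voting is the column mean and stays in the envelope", {
  expect_equal(average_vote(rbind(c(0.2, 0.6), c(0.4, 0.8))), c(0.3, 0.7))
  expect_equal(average_vote(c(0.1, 0.9)), c(0.1, 0.9))   # N = 1 identity
  expect_error(average_vote(list(c(0.1, 0.2), c(0.3))), "ragged")
  set.seed(8)
  pm <- matrix(runif(5 * 20), 5, 20)
  v <- average_vote(pm)
  expect_true(all(v >= apply(pm, 2, min) & v <= apply(pm, 2, max)))
  expect_true(all(v >= 0 & v <= 1))
})

test_that("training-subject selection applies the accuracy threshold", {
  reports <- do.call(rbind, list(
    compute_metrics(c(1, 0, 1, 0), c(1, 0, 1, 1), "S1"),
    compute_metrics(c(1, 0), c(1, 0), "S2"),
    compute_metrics(c(1, 0, 1, 0), c(0, 1, 0, 1), "S3")))
  reports$acc <- c(0.78, 0.95, 0.59)
  expect_equal(select_training_subjects(reports, 0.70), c("S1", "S2"))
  expect_equal(select_training_subjects(reports, 0),
               c("S1", "S2", "S3"))
  expect_error(select_training_subjects(reports, 1.01), "threshold")
})

test_that("LOSO covers every subject exactly once with N = 2 pairs per fold", {
  res <- tiny_loso()
  ids <- vapply(tiny_cohort(), function(p) p$subject_id, "")
  expect_setequal(res$per_subject$subject_id, ids)
  expect_equal(nrow(res$per_subject), 3L)
  expect_true(all(res$per_subject$n_models == 2L))
  # balanced extracted test sets: acc = (sen + spc) / 2 exactly
  expect_equal(res$per_subject$acc,
               (res$per_subject$sen + res$per_subject$spc) / 2)
  # the mean row is the unweighted subject mean
  expect_equal(res$mean$acc, mean(res$per_subject$acc))
  expect_error(run_inter_subject(tiny_cohort()[1:2], tiny_tcfg(),
                                 tiny_dcfg()), ">= 3")
})

test_that("intra-subject protocol reports a valid seeded run", {
  r <- fixture("tiny_intra", {
    run_intra_subject(tiny_cohort()[[1]], tiny_tcfg(), tiny_dcfg(),
                      seed = 2)
  })
  m <- r$metrics
  expect_s3_class(m, "metrics_report")
  expect_equal(m$subject_id, "S1")
  expect_equal(m$tp + m$tn + m$fp + m$fn, n_segments(r$split$test))
  expect_true(m$acc >= 0 && m$acc <= 1)
  expect_true(is.finite(r$corr_translated) && is.finite(r$corr_baseline))
  # test segments are balanced, so the metric midpoint identity holds
  expect_equal(m$acc, (m$sen + m$spc) / 2)
})
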