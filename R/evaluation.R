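#' Confusion-matrix metrics (ACC / SEN / SPC)
#'
#' Sensitivity measures the ability to correctly detect IEDs
#' (`tp / (tp + fn)`), specificity the ability to correctly detect non-IEDs
#' (`tn / (tn + fp)`), and accuracy the overall proportion correct.
#'
#' @param labels binary ground-truth vector (1 = IED).
#' @param predictions binary predicted vector of equal length.
#' @param subject_id optional subject identifier carried into the report.
#' @return object of class `metrics_report`: a one-row data.frame with
#'   `subject_id`, counts `tp`, `tn`, `fp`, `fn`, and proportions `acc`,
#'   `sen`, `spc`.
#' @export
compute_metrics <- function(labels, predictions, subject_id = NA_character_) {
  if (length(labels) != length(predictions)) {
    stop_invalid("labels and predictions must have equal length")
  }
  if (!length(labels)) stop_invalid("empty inputs")
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  if (!all(c(labels, predictions) %in% c(0L, 1L))) {
    stop_invalid("labels and predictions must be binary (0/1)")
  }
  tp <- sum(labels == 1L & predictions == 1L)
  tn <- sum(labels == 0L & predictions == 0L)
  fp <- sum(labels == 0L & predictions == 1L)
  fn <- sum(labels == 1L & predictions == 0L)
  out <- data.frame(subject_id = subject_id, tp = tp, tn = tn, fp = fp,
                    fn = fn,
                    acc = (tp + tn) / length(labels),
                    sen = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                    spc = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' Stratified train/validation/test split
#'
#' Splits a segment set into disjoint, exhaustive parts stratified by label
#' with a seeded shuffle; the standard intra-subject protocol uses 70% /
#' 10% / 20%.
#'
#' @param segs a [segment_set()].
#' @param fractions numeric length-3 vector summing to 1.
#' @param seed seed for the shuffle.
#' @return named list of [segment_set()]s: `train`, `val`, `test`.
#' @export
split_intra <- function(segs, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  stopifnot(inherits(segs, "segment_set"))
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    stop_invalid("fractions must be three numbers summing to 1")
  }
  with_seed(seed, {
    parts <- list(train = integer(), val = integer(), test = integer())
    for (cl in c(1L, 0L)) {
      idx <- sample(which(segs$label == cl))
      n_c <- length(idx)
      n_tr <- round(fractions[1L] * n_c)
      n_va <- round(fractions[2L] * n_c)
      if (n_tr < 1L || n_va < 1L || n_c - n_tr - n_va < 1L) {
        stop_invalid("too few segments of class ", cl,
                     " for a non-empty three-way split")
      }
      parts$train <- c(parts$train, idx[seq_len(n_tr)])
      parts$val <- c(parts$val, idx[n_tr + seq_len(n_va)])
      parts$test <- c(parts$test, idx[(n_tr + n_va + 1L):n_c])
    }
    lapply(parts, function(ix) subset_segments(segs, sort(ix)))
  })
}

#' Average-vote ensemble of model probabilities
#'
#' @param probability_rows `N x m` matrix (or vector for N = 1): one row of
#'   m segment probabilities per model.
#' @return vector of m column-wise mean probabilities.
#' @export
average_vote <- function(probability_rows) {
  if (is.list(probability_rows)) {
    lens <- lengths(probability_rows)
    if (length(unique(lens)) != 1L) {
      stop_invalid("ragged probability rows: lengths ",
                   paste(lens, collapse = ", "))
    }
    probability_rows <- do.call(rbind, probability_rows)
  }
  if (is.vector(probability_rows)) {
    probability_rows <- matrix(probability_rows, nrow = 1L)
  }
  if (nrow(probability_rows) < 1L) stop_invalid("need at least one model")
  colMeans(probability_rows)
}

#' Select training subjects by intra-subject accuracy
#'
#' Formalizes "subjects whose IEDs are detected with high accuracy in the
#' intra-subject approach" as intra-subject accuracy at or above a
#' threshold (default 0.70).  At use time the held-out test subject is
#' additionally excluded by the caller.
#'
#' @param intra_reports list of `metrics_report` rows (or a stacked
#'   data.frame), one per candidate subject.
#' @param threshold minimum intra-subject accuracy (default 0.70).
#' @return character vector of selected subject ids.
#' @export
select_training_subjects <- function(intra_reports, threshold = 0.70) {
  df <- if (is.data.frame(intra_reports)) intra_reports else
    do.call(rbind, intra_reports)
  keep <- df$subject_id[df$acc >= threshold]
  if (!length(keep)) {
    stop_invalid("no subject reaches intra-subject accuracy ", threshold,
                 "; lower the selection threshold")
  }
  as.character(keep)
}

#' Intra-subject protocol: translate, detect, score
#'
#' Extracts balanced segments, splits them 70/10/20 (stratified, seeded),
#' trains one translator on the training part, maps all parts through it,
#' trains one detector on the translated training part (validation part for
#' checkpoint selection), and reports test-part metrics.  No test segment
#' influences any fitting step.
#'
#' @param paired a preprocessed [paired_recording()].
#' @param tcfg a [translator_config()].
#' @param dcfg a [detector_config()].
#' @param seed protocol seed (segmentation, split).
#' @param fractions train/val/test fractions.
#' @param scalp_baseline also train an identically configured detector on
#'   the raw scalp segments and report its test accuracy (for the
#'   translation-gain comparison).
#' @return list with `metrics` (a `metrics_report`), `corr_translated` and
#'   `corr_baseline` (held-out mean per-segment Pearson correlation of the
#'   translated, resp. raw scalp, segments with the true intracranial
#'   segments under the identity channel pairing), and, when requested,
#'   `metrics_scalp` for the scalp-trained detector.
#' @export
run_intra_subject <- function(paired, tcfg = translator_config(),
                              dcfg = detector_config(), seed = 1L,
                              fractions = c(0.7, 0.1, 0.2),
                              scalp_baseline = FALSE) {
  segs <- extract_segments(paired, seed = seed)
  sp <- split_intra(segs, fractions, seed = derive_seed(seed, 1L))
  trans <- train_translator(sp$train, tcfg)
  tr_y <- translate(trans, sp$train)
  va_y <- translate(trans, sp$val)
  te_y <- translate(trans, sp$test)
  tr_set <- segment_set(sp$train$x, tr_y, sp$train$label,
                        sp$train$subject_id, sp$train$peak_sample)
  va_set <- segment_set(sp$val$x, va_y, sp$val$label, sp$val$subject_id,
                        sp$val$peak_sample)
  det <- train_detector(tr_set, va_set, dcfg, on = "y")
  pred <- as.integer(predict_proba(det, te_y) >= 0.5)
  metrics <- compute_metrics(sp$test$label, pred, paired$subject_id)
  out <- list(
    metrics = metrics,
    corr_translated = mean_segment_correlation(te_y, sp$test$y),
    corr_baseline = mean_segment_correlation(sp$test$x, sp$test$y),
    translator = trans, detector = det, split = sp)
  if (scalp_baseline) {
    det_x <- train_detector(sp$train, sp$val, dcfg, on = "x")
    pred_x <- as.integer(predict_proba(det_x, sp$test, on = "x") >= 0.5)
    out$metrics_scalp <- compute_metrics(sp$test$label, pred_x,
                                         paired$subject_id)
  }
  out
}

# mean over segments of the mean over the 12 identity-paired channels of
# the Pearson correlation between the two 64-sample traces
mean_segment_correlation <- function(a, b) {
  n <- dim(a)[3L]
  vals <- vapply(seq_len(n), function(i) {
    cc <- vapply(1:12, function(ch) {
      sa <- a[, ch, i]; sb <- b[, ch, i]
      if (stats::sd(sa) < 1e-12 || stats::sd(sb) < 1e-12) 0
      else stats::cor(sa, sb)
    }, 1)
    mean(cc)
  }, 1)
  mean(vals)
}

#' Inter-subject protocol: leave-one-subject-out with average voting
#'
#' For each held-out subject: training subjects are those whose
#' intra-subject accuracy reaches `threshold` (computed without the
#' held-out subject); one translator G_n is trained per selected subject on
#' that subject's full balanced segment set; every selected subject's scalp
#' segments are mapped through each G_n and one detector per G_n is trained
#' on that translator's pooled outputs; the N detectors' probabilities on
#' the held-out subject's segments (mapped through the matching G_n) are
#' averaged and thresholded at 0.5.
#'
#' @param cohort list of preprocessed [paired_recording()]s (>= 3).
#' @param tcfg a [translator_config()].
#' @param dcfg a [detector_config()].
#' @param threshold intra-subject accuracy threshold for the training pool.
#' @param seed protocol seed.
#' @return list with `per_subject` (stacked `metrics_report` rows plus an
#'   `n_models` column), `mean` (unweighted mean ACC/SEN/SPC row), and
#'   `intra_reports` (the per-subject intra-subject metrics used for
#'   selection).
#' @export
run_inter_subject <- function(cohort, tcfg = translator_config(),
                              dcfg = detector_config(), threshold = 0.70,
                              seed = 1L) {
  if (length(cohort) < 3L) stop_invalid("LOSO needs a cohort of >= 3")
  ids <- vapply(cohort, function(p) p$subject_id, "")
  intra <- lapply(seq_along(cohort), function(i) {
    run_intra_subject(cohort[[i]], tcfg, dcfg,
                      seed = derive_seed(seed, i))$metrics
  })
  intra_df <- do.call(rbind, intra)
  segs <- lapply(seq_along(cohort), function(i) {
    extract_segments(cohort[[i]], seed = derive_seed(seed, 100L + i))
  })
  translators <- vector("list", length(cohort))   # G_n, one per subject
  rows <- vector("list", length(cohort))
  for (k in seq_along(cohort)) {
    pool <- setdiff(select_training_subjects(intra_df[-k, , drop = FALSE],
                                             threshold), ids[k])
    if (!length(pool)) {
      stop_invalid("empty training pool for held-out subject ", ids[k])
    }
    probs <- matrix(0, length(pool), n_segments(segs[[k]]))
    for (j in seq_along(pool)) {
      n_idx <- match(pool[j], ids)
      if (is.null(translators[[n_idx]])) {
        translators[[n_idx]] <- train_translator(segs[[n_idx]], tcfg)
      }
      g_n <- translators[[n_idx]]
      mapped <- lapply(match(pool, ids), function(m) {
        s <- segs[[m]]
        segment_set(s$x, translate(g_n, s), s$label, s$subject_id,
                    s$peak_sample)
      })
      # no validation split in LOSO: the final-epoch model is used, so the
      # empty-validation fallback warning is expected and silenced here
      det <- suppressWarnings(
        train_detector(combine_segments(mapped), NULL, dcfg, on = "y"))
      probs[j, ] <- predict_proba(det, translate(g_n, segs[[k]]))
    }
    voted <- average_vote(probs)
    rep_k <- compute_metrics(segs[[k]]$label, as.integer(voted >= 0.5),
                             ids[k])
    rep_k$n_models <- length(pool)
    rows[[k]] <- rep_k
  }
  per_subject <- do.call(rbind, rows)
  list(per_subject = per_subject,
       mean = data.frame(acc = mean(per_subject$acc),
                         sen = mean(per_subject$sen),
                         spc = mean(per_subject$spc)),
       intra_reports = intra_df)
}
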