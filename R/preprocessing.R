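#' @importFrom signal butter filtfilt freqz
NULL

#' The 12 temporal/frontal scalp channels used for translation
#'
#' Scalp-to-intracranial mapping concatenates the scalp segment with the
#' 12-contact intracranial segment, so exactly 12 scalp channels are kept:
#' the temporal and frontal electrodes where IEDs project most strongly.
#'
#' @return character vector of 12 channel names, in translation order.
#' @export
translation_channels <- function() {
  c("Fp1", "F3", "F7", "C3", "T3", "Fp2", "F4", "F8", "C4", "T4", "Fz", "Cz")
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward-backward (`filtfilt`) per channel,
#' so spike peak latencies are preserved for peak-centred segmentation.
#'
#' @param rec an [eeg_recording()].
#' @param low,high cut-off frequencies in Hz (defaults 1 and 70, the
#'   standard clinical EEG band).
#' @param order filter order (default 4).
#' @return filtered [eeg_recording()] of identical shape and labels.
#' @export
bandpass <- function(rec, low = 1, high = 70, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop_invalid("cut-offs must satisfy 0 < low < high < sampling_rate/2 ",
                 "(got ", low, ", ", high, " with Nyquist ", nyq, ")")
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- apply(rec$data, 2, function(x) signal::filtfilt(bf, x))
  eeg_recording(out, rec$sampling_rate, rec$labels)
}

#' Zero-phase notch filter
#'
#' Second-order IIR notch (quality factor `q`, default 30) applied
#' forward-backward per channel; rejects the mains frequency while leaving
#' the rest of the passband essentially untouched.
#'
#' @param rec an [eeg_recording()].
#' @param freq notch frequency in Hz (default 50, European mains).
#' @param q quality factor; the -3 dB bandwidth is `freq / q`.
#' @return filtered [eeg_recording()].
#' @export
notch <- function(rec, freq = 50, q = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(freq > 0 && freq < nyq)) {
    stop_invalid("notch frequency must lie in (0, sampling_rate/2)")
  }
  flt <- design_notch(freq, rec$sampling_rate, q)
  out <- apply(rec$data, 2, function(x) signal::filtfilt(flt, x))
  eeg_recording(out, rec$sampling_rate, rec$labels)
}

# biquad notch (Audio-EQ-cookbook form), returned as a signal::Arma filter
design_notch <- function(freq, sampling_rate, q) {
  w0 <- 2 * pi * freq / sampling_rate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

#' Common average reference
#'
#' Subtracts the across-channel mean at every time sample; applied to scalp
#' recordings only in the standard pipeline.  The across-channel mean of the
#' output is exactly zero at every sample.
#'
#' @param rec an [eeg_recording()] with at least 2 channels.
#' @return re-referenced [eeg_recording()].
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(rec$data) < 2L) {
    stop_invalid("common average reference needs >= 2 channels ",
                 "(it would zero a single channel)")
  }
  out <- rec$data - rowMeans(rec$data)
  eeg_recording(out, rec$sampling_rate, rec$labels)
}

#' Select and reorder scalp channels
#'
#' @param rec an [eeg_recording()].
#' @param wanted channel names to keep, in output order; defaults to the 12
#'   temporal/frontal names of [translation_channels()].
#' @return [eeg_recording()] with `length(wanted)` columns in `wanted` order.
#' @export
select_scalp_channels <- function(rec, wanted = translation_channels()) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(wanted, rec$labels)
  if (length(missing)) {
    stop_invalid("channel(s) not present in recording: ",
                 paste(missing, collapse = ", "))
  }
  eeg_recording(rec$data[, wanted, drop = FALSE], rec$sampling_rate, wanted)
}

#' Standard preprocessing pipeline for a paired recording
#'
#' Band-pass (1-70 Hz) and notch (50 Hz) filter both modalities, re-reference
#' the scalp channels to the common average, and reduce the scalp montage to
#' the 12 translation channels.  The intracranial recording is filtered
#' identically but not re-referenced.
#'
#' @param paired a [paired_recording()].
#' @param low,high,notch_freq filter parameters in Hz.
#' @param channels scalp channels to keep (default [translation_channels()]).
#' @return preprocessed [paired_recording()].
#' @export
preprocess_paired <- function(paired, low = 1, high = 70, notch_freq = 50,
                              channels = translation_channels()) {
  stopifnot(inherits(paired, "paired_recording"))
  seeg <- notch(bandpass(paired$seeg, low, high), notch_freq)
  seeg <- select_scalp_channels(common_average_reference(seeg), channels)
  ieeg <- notch(bandpass(paired$ieeg, low, high), notch_freq)
  paired_recording(seeg, ieeg, paired$ied_peaks, paired$subject_id,
                   paired$event_info)
}

# --- segments --------------------------------------------------------------

#' Construct a segment set
#'
#' Column-bound storage for peak-centred 64 x 12 windows: `x` holds scalp
#' segments and `y` (optionally) time-aligned intracranial segments, both as
#' `64 x 12 x n` arrays; `label` is 1 for IED, 0 for non-IED.
#'
#' @param x `64 x 12 x n` array of scalp segments (uV).
#' @param y matching array of intracranial segments, or `NULL`.
#' @param label integer vector in `{0, 1}`, length `n`.
#' @param subject_id character vector, length `n` (recycled if length 1).
#' @param peak_sample integer vector of 0-based source peak indices
#'   (`NA` for non-IED segments).
#' @return an object of class `segment_set`.
#' @export
segment_set <- function(x, y = NULL, label = integer(),
                        subject_id = character(), peak_sample = NULL) {
  n <- if (length(dim(x)) == 3L) dim(x)[3L] else 0L
  check_seg_array <- function(a, what) {
    d <- dim(a)
    if (length(d) != 3L || d[1L] != 64L || d[2L] != 12L) {
      stop_invalid(what, " segments must form a 64 x 12 x n array")
    }
  }
  if (n > 0) check_seg_array(x, "scalp")
  if (!is.null(y)) {
    check_seg_array(y, "intracranial")
    if (dim(y)[3L] != n) stop_invalid("x and y segment counts differ")
  }
  label <- as.integer(label)
  if (length(label) != n) stop_invalid("need one label per segment")
  if (n > 0 && !all(label %in% c(0L, 1L))) {
    stop_invalid("labels must be 0 (non-IED) or 1 (IED)")
  }
  if (length(subject_id) == 1L) subject_id <- rep(subject_id, n)
  peak_sample <- if (is.null(peak_sample)) rep(NA_integer_, n) else
    as.integer(peak_sample)
  structure(
    list(x = x, y = y, label = label, subject_id = as.character(subject_id),
         peak_sample = peak_sample,
         class_counts = c(n_ied = sum(label == 1L),
                          n_non_ied = sum(label == 0L))),
    class = "segment_set")
}

#' Number of segments in a set
#' @param segs a [segment_set()].
#' @return integer count.
#' @export
n_segments <- function(segs) length(segs$label)

#' Subset a segment set by index
#' @param segs a [segment_set()].
#' @param idx integer indices to keep.
#' @return a [segment_set()].
#' @export
subset_segments <- function(segs, idx) {
  segment_set(segs$x[, , idx, drop = FALSE],
              if (!is.null(segs$y)) segs$y[, , idx, drop = FALSE],
              segs$label[idx], segs$subject_id[idx], segs$peak_sample[idx])
}

#' Concatenate segment sets
#' @param ... [segment_set()] objects (or a single list of them).
#' @return a [segment_set()].
#' @export
combine_segments <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1L]], "segment_set")) {
    sets <- sets[[1L]]
  }
  sets <- Filter(function(s) n_segments(s) > 0L, sets)
  if (!length(sets)) stop_invalid("no non-empty segment sets to combine")
  bind3 <- function(as) array(unlist(as, use.names = FALSE),
                              dim = c(64L, 12L, sum(sapply(as, function(a)
                                dim(a)[3L]))))
  y <- if (all(sapply(sets, function(s) !is.null(s$y)))) {
    bind3(lapply(sets, `[[`, "y"))
  } else NULL
  segment_set(bind3(lapply(sets, `[[`, "x")), y,
              unlist(lapply(sets, `[[`, "label")),
              unlist(lapply(sets, `[[`, "subject_id")),
              unlist(lapply(sets, `[[`, "peak_sample")))
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments (%d IED / %d non-IED), %d subject(s)\n",
              n_segments(x), x$class_counts[["n_ied"]],
              x$class_counts[["n_non_ied"]],
              length(unique(x$subject_id))))
  invisible(x)
}

#' Extract balanced IED / non-IED segments
#'
#' One IED segment is cut per annotated peak `p`, covering the half-open
#' 0-based window `[p - 32, p + 32)` (64 samples) on both modalities.
#' Non-IED segments are drawn from stretches whose windows stay clear of a
#' guard interval of `guard` samples around every annotated peak, on a
#' non-overlapping 64-sample grid, and the class counts are equalized by
#' seeded random subsampling of the majority class.
#'
#' @param paired a preprocessed [paired_recording()] whose scalp recording
#'   has exactly 12 channels.
#' @param half_width half window width in samples (default 32).
#' @param guard guard interval in samples around each peak that non-IED
#'   windows must not touch (default 64).
#' @param seed seed for the non-IED draw and majority subsampling.
#' @return a balanced [segment_set()].
#' @export
extract_segments <- function(paired, half_width = 32L, guard = 64L,
                             seed = 1L) {
  stopifnot(inherits(paired, "paired_recording"))
  hw <- as.integer(half_width)
  if (ncol(paired$seeg$data) != 12L || ncol(paired$ieeg$data) != 12L) {
    stop_invalid("extract_segments expects a preprocessed recording with 12 ",
                 "scalp and 12 intracranial channels; run preprocess_paired()")
  }
  n <- nrow(paired$seeg$data)
  peaks <- paired$ied_peaks
  ok <- peaks >= hw & peaks <= n - hw
  if (any(!ok)) {
    warning(sum(!ok), " peak(s) too close to a recording edge were skipped")
    peaks <- peaks[ok]
  }
  cut_win <- function(mat, centre) {
    mat[(centre - hw + 1L):(centre + hw), , drop = FALSE]  # 0-based window
  }
  with_seed(seed, {
    # candidate non-IED centres: 64-sample grid, clear of every guard zone
    allowed <- rep(TRUE, n)
    for (p in peaks) {
      lo <- max(1L, p - guard - hw + 2L)       # rows touching the guard zone
      hi <- min(n, p + guard + hw + 1L)
      allowed[lo:hi] <- FALSE
    }
    grid <- seq(hw, n - hw, by = 2L * hw)
    cand <- grid[allowed[grid + 1L]]
    n_ied <- length(peaks)
    n_bg <- min(n_ied, length(cand))
    if (n_ied > n_bg) {                        # subsample majority class
      peaks <- sort(sample(peaks, n_bg))
      n_ied <- n_bg
    }
    bg <- if (n_bg > 0) sort(sample(cand, n_bg)) else integer()
    centres <- c(peaks, bg)
    m <- length(centres)
    x <- array(0, c(2L * hw, 12L, m))
    y <- array(0, c(2L * hw, 12L, m))
    for (i in seq_len(m)) {
      x[, , i] <- cut_win(paired$seeg$data, centres[i])
      y[, , i] <- cut_win(paired$ieeg$data, centres[i])
    }
    segment_set(x, y, rep(c(1L, 0L), c(n_ied, n_bg)),
                if (m > 0L) paired$subject_id else character(),
                c(peaks, rep(NA_integer_, n_bg)))
  })
}
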