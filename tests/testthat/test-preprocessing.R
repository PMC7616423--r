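test_that("band-pass matches its frequency-response oracle in pass and stop bands", {
  fs <- 200
  bf <- signal::butter(4, c(1, 70) / (fs / 2), type = "pass")
  gain_at <- function(f) filtfilt_gain(bf, f, fs)
  # 10 Hz sine: steady-state amplitude within 5% of 1, and equal to oracle
  r10 <- bandpass(sine_recording(10), 1, 70)
  expect_equal(steady_amp(r10), 1, tolerance = 0.05)
  expect_equal(steady_amp(r10), gain_at(10), tolerance = 0.01)
  # 90 Hz sine: attenuated by >= 20 dB, matching the oracle
  r90 <- bandpass(sine_recording(90), 1, 70)
  expect_lt(steady_amp(r90), 10^(-20 / 20))
  expect_equal(steady_amp(r90), gain_at(90), tolerance = 0.15)
  # DC is below the 1 Hz cut-off
  dc <- eeg_recording(matrix(1, 2000, 2), fs, c("a", "b"))
  out <- bandpass(dc, 1, 70)
  expect_lt(max(abs(out$data[400:1600, ])), 0.01)
})

test_that("notch rejects the mains frequency and preserves the passband", {
  fs <- 200
  flt <- ieegmap:::design_notch(50, fs, 30)
  gain_at <- function(f) filtfilt_gain(flt, f, fs)
  r50 <- notch(sine_recording(50), 50)
  expect_lt(steady_amp(r50), 10^(-30 / 20))
  expect_lt(gain_at(50), 10^(-30 / 20))
  r10 <- notch(sine_recording(10), 50)
  expect_equal(steady_amp(r10), 1, tolerance = 0.05)
  expect_equal(gain_at(10), 1, tolerance = 0.01)
  z <- notch(eeg_recording(matrix(0, 1000, 3), fs, c("a", "b", "c")), 50)
  expect_true(all(z$data == 0))
})

test_that("filters reject cut-offs outside the Nyquist range", {
  r <- sine_recording(10)
  expect_error(bandpass(r, 0, 70), "cut-offs")
  expect_error(bandpass(r, 70, 1), "cut-offs")
  expect_error(bandpass(r, 1, 120), "cut-offs")
  expect_error(notch(r, 150), "notch")
})

test_that("band-pass and notch commute in the passband", {
  set.seed(4)
  rec <- eeg_recording(matrix(rnorm(4000), ncol = 2), 200, c("a", "b"))
  ab <- notch(bandpass(rec), 50)
  ba <- bandpass(notch(rec, 50))
  mid <- 500:1500
  expect_equal(ab$data[mid, ], ba$data[mid, ], tolerance = 1e-6)
})

test_that("common average reference zeroes the across-channel mean", {
  one <- eeg_recording(matrix(c(1, 3), 1, 2), 200, c("a", "b"))
  expect_equal(as.numeric(common_average_reference(one)$data), c(-1, 1))
  set.seed(1)
  rec <- eeg_recording(matrix(rnorm(500 * 8), 500, 8), 200,
                       paste0("c", 1:8))
  out <- common_average_reference(rec)
  expect_true(all(abs(rowMeans(out$data)) < 1e-12))
  # idempotent on already zero-mean input
  out2 <- common_average_reference(out)
  expect_equal(out$data, out2$data)
  single <- eeg_recording(matrix(1:5, 5, 1), 200, "a")
  expect_error(common_average_reference(single), "2 channels")
})

test_that("channel selection returns the printed 12 temporal/frontal names in order", {
  p <- small_subject()
  sel <- select_scalp_channels(p$seeg)
  expect_equal(sel$labels,
               c("Fp1", "F3", "F7", "C3", "T3", "Fp2", "F4", "F8", "C4",
                 "T4", "Fz", "Cz"))
  expect_equal(ncol(sel$data), 12L)
  expect_equal(sel$data[, "T3"], unname(p$seeg$data[, "T3"]))
  # identity selection
  idn <- select_scalp_channels(p$seeg, p$seeg$labels)
  expect_equal(idn$data, p$seeg$data)
  expect_error(select_scalp_channels(sel, c("Fp1", "Oz")), "Oz")
})

test_that("IED windows are peak-centred half-open 64-sample cuts", {
  n <- 3000
  ramp <- matrix(rep(0:(n - 1), 12), n, 12)   # value == 0-based sample index
  peaks <- c(100L, 900L, 2000L)
  paired <- paired_recording(
    eeg_recording(ramp, 200, translation_channels()),
    eeg_recording(ramp, 200, fo_channel_names()),
    peaks, "T1")
  segs <- extract_segments(paired, seed = 1)
  expect_equal(unname(segs$class_counts), c(3L, 3L))
  i1 <- which(segs$label == 1L)
  for (k in seq_along(i1)) {
    # window [p-32, p+32): first value p-32, last p+31
    expect_equal(segs$x[1, 1, i1[k]], peaks[k] - 32)
    expect_equal(segs$x[64, 1, i1[k]], peaks[k] + 31)
    expect_equal(dim(segs$x[, , i1[k]]), c(64L, 12L))
  }
  # non-IED windows stay clear of every guard interval
  bg <- which(segs$label == 0L)
  centres <- segs$x[33, 1, bg]                # row 33 holds sample c
  for (cc in centres) {
    expect_true(all(abs(cc - peaks) > 64L))
    expect_true(all(cc - 32 > peaks + 64 | cc + 31 < peaks - 64))
  }
})

test_that("segment extraction balances classes and handles zero peaks", {
  p <- small_subject_pp()
  segs <- extract_segments(p, seed = 2)
  expect_s3_class(segs, "segment_set")
  expect_equal(segs$class_counts[["n_ied"]], segs$class_counts[["n_non_ied"]])
  expect_equal(dim(segs$x)[1:2], c(64L, 12L))
  expect_equal(dim(segs$y)[1:2], c(64L, 12L))
  expect_true(all(segs$label %in% c(0L, 1L)))
  none <- paired_recording(
    eeg_recording(matrix(0, 2000, 12), 200, translation_channels()),
    eeg_recording(matrix(0, 2000, 12), 200, fo_channel_names()),
    integer(), "T0")
  z <- extract_segments(none, seed = 1)
  expect_equal(n_segments(z), 0L)
})

test_that("non-IED windows never overlap guard intervals across random layouts", {
  for (s in 1:5) {
    set.seed(s)
    n <- 6000L
    peaks <- sort(sample(seq(200L, n - 200L), 8L))
    peaks <- peaks[c(TRUE, diff(peaks) > 200)]
    ramp <- matrix(rep(0:(n - 1), 12), n, 12)
    paired <- paired_recording(
      eeg_recording(ramp, 200, translation_channels()),
      eeg_recording(ramp, 200, fo_channel_names()), peaks, "P")
    segs <- extract_segments(paired, seed = s)
    bg <- which(segs$label == 0L)
    centres <- segs$x[33, 1, bg]
    for (cc in centres) {
      expect_true(all(cc - 32 > peaks + 64 | cc + 31 < peaks - 64))
    }
    expect_equal(sum(segs$label == 1L), sum(segs$label == 0L))
  }
})

test_that("full preprocessing pipeline emits a 12+12 channel paired recording", {
  pp <- small_subject_pp()
  expect_equal(ncol(pp$seeg$data), 12L)
  expect_equal(ncol(pp$ieeg$data), 12L)
  expect_equal(pp$seeg$labels, translation_channels())
  expect_identical(pp$ied_peaks, small_subject()$ied_peaks)
})
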