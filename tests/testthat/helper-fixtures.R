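# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# small synthetic subject (40 IEDs, 100 s) for fast structural tests
small_subject_cfg <- function(seed = 7L) {
  synthesis_config(n_subjects = 1L, duration_s = 100, seed = seed,
                   n_ieds_per_subject = 40L)
}

small_subject <- function() {
  fixture("small_subject", simulate_subject(small_subject_cfg(), 1L))
}

small_subject_pp <- function() {
  fixture("small_subject_pp", preprocess_paired(small_subject()))
}

# tiny 3-subject cohort + LOSO run used by evaluation and protocol tests
tiny_cohort <- function() {
  fixture("tiny_cohort", {
    cfg <- synthesis_config(n_subjects = 3L, duration_s = 100,
                            n_ieds_per_subject = 30L, seed = 21L)
    lapply(make_cohort(cfg), preprocess_paired)
  })
}

tiny_tcfg <- function() {
  translator_config(n_epochs = 2L, seed = 5L)
}

tiny_dcfg <- function() {
  detector_config(n_epochs = 2L, seed = 6L)
}

tiny_loso <- function() {
  fixture("tiny_loso", {
    run_inter_subject(tiny_cohort(), tiny_tcfg(), tiny_dcfg(),
                      threshold = 0, seed = 9L)
  })
}

# random balanced labelled segment set with both modalities
random_segment_set <- function(n = 24L, seed = 1L, offset = 0) {
  set.seed(seed)
  x <- array(stats::rnorm(64 * 12 * n), c(64, 12, n))
  y <- array(stats::rnorm(64 * 12 * n), c(64, 12, n))
  lab <- rep(c(1L, 0L), length.out = n)
  x[, , lab == 1L] <- x[, , lab == 1L] + offset
  segment_set(x, y, lab, "T1")
}

# sine-wave recording for filter tests
sine_recording <- function(freq, fs = 200, dur = 10, n_ch = 2) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  eeg_recording(matrix(rep(sin(2 * pi * freq * t), n_ch), ncol = n_ch),
                fs, paste0("ch", seq_len(n_ch)))
}

# |H(f)|^2 of a digital filter applied forward-backward (filtfilt):
# the designed-filter frequency-response oracle
filtfilt_gain <- function(flt, f, fs) {
  w <- 2 * pi * f / fs
  H <- function(coef) {
    vapply(w, function(wi) {
      sum(coef * exp(-1i * wi * (seq_along(coef) - 1)))
    }, complex(1))
  }
  Mod(H(flt$b) / H(flt$a))^2
}

# steady-state amplitude of a filtered sine (transients trimmed)
steady_amp <- function(rec, trim = 400) {
  mid <- rec$data[(trim + 1):(nrow(rec$data) - trim), 1]
  sqrt(2) * stats::sd(mid)
}
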