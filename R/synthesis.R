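#' Configuration for the synthetic paired-EEG cohort generator
#'
#' Describes a cohort of subjects for which simultaneous scalp (20-channel)
#' and intracranial foramen-ovale (12-contact) recordings are simulated with
#' annotated interictal epileptiform discharges (IEDs).  The simulator
#' emulates the recording conventions of concurrent scalp/intracranial
#' epilepsy monitoring: 200 Hz sampling, per-subject IED counts in the
#' clinically reported 50-953 range, spike-plus-slow-wave morphology, and a
#' scalp-visible fraction of IEDs in the historically observed 9-22% range
#' (default 0.15).
#'
#' @param n_subjects number of subjects in the cohort.
#' @param duration_s recording duration per subject in seconds; `NA` (the
#'   default) chooses `max(300, 2.5 * n_ieds)` so that events always fit
#'   with their refractory gaps.
#' @param sampling_rate sampling rate in Hz (default 200).
#' @param n_ieds_per_subject IED count per subject; `NA` (the default) draws
#'   a count uniformly in `[50, 953]` independently per subject.
#' @param visibility_fraction fraction of IEDs whose noise-free scalp
#'   projection exceeds the scalp background RMS (default 0.15).
#' @param ied_amplitude_uv nominal IED source amplitude in uV (default 300);
#'   per-event amplitudes jitter uniformly within +/-20%.
#' @param ieeg_snr_db ratio (dB) of the nominal intracranial spike peak to
#'   the intracranial background RMS (default 15).
#' @param seeg_attenuation scalar skull attenuation in (0, 1) applied to the
#'   scalp projection of every source (default 0.4).
#' @param seeg_noise_uv scalp colored-noise RMS in uV (default 7); the 10 Hz
#'   posterior rhythm scales with it, so 0 yields a noise-free scalp.
#' @param noise_color_exponent spectral slope alpha of the 1/f^alpha
#'   background (default 1).
#' @param artifact_rate eye-blink-like scalp artifact events per minute
#'   (default 5).
#' @param spike_width_ms,slow_wave_width_ms IED template component widths.
#' @param seed integer master seed; identical config + seed gives a
#'   bit-identical cohort.
#' @return an object of class `synthesis_config`.
#' @export
synthesis_config <- function(n_subjects = 18L,
                             duration_s = NA,
                             sampling_rate = 200,
                             n_ieds_per_subject = NA,
                             visibility_fraction = 0.15,
                             ied_amplitude_uv = 300,
                             ieeg_snr_db = 15,
                             seeg_attenuation = 0.4,
                             seeg_noise_uv = 7,
                             noise_color_exponent = 1,
                             artifact_rate = 5,
                             spike_width_ms = 70,
                             slow_wave_width_ms = 350,
                             seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), duration_s = duration_s,
    sampling_rate = sampling_rate, n_ieds_per_subject = n_ieds_per_subject,
    visibility_fraction = visibility_fraction,
    ied_amplitude_uv = ied_amplitude_uv, ieeg_snr_db = ieeg_snr_db,
    seeg_attenuation = seeg_attenuation, seeg_noise_uv = seeg_noise_uv,
    noise_color_exponent = noise_color_exponent,
    artifact_rate = artifact_rate, spike_width_ms = spike_width_ms,
    slow_wave_width_ms = slow_wave_width_ms, seed = as.integer(seed))
  validate_synthesis_config(cfg)
  structure(cfg, class = "synthesis_config")
}

validate_synthesis_config <- function(cfg) {
  if (cfg$n_subjects < 1L) stop_invalid("n_subjects must be >= 1")
  if (!(cfg$visibility_fraction > 0 && cfg$visibility_fraction <= 1)) {
    stop_invalid("visibility_fraction must lie in (0, 1]")
  }
  if (!(cfg$seeg_attenuation > 0 && cfg$seeg_attenuation < 1)) {
    stop_invalid("seeg_attenuation must lie in (0, 1)")
  }
  if (cfg$spike_width_ms <= 0 || cfg$slow_wave_width_ms <= 0) {
    stop_invalid("template widths must be positive")
  }
  if (cfg$spike_width_ms >= cfg$slow_wave_width_ms) {
    stop_invalid("spike_width_ms must be smaller than slow_wave_width_ms")
  }
  # the sharp component's bandwidth reaches roughly 1000/spike_width_ms Hz
  if (cfg$sampling_rate <= 2 * 1000 / cfg$spike_width_ms) {
    stop_invalid("sampling_rate must exceed twice the template's highest ",
                 "frequency (~", round(1000 / cfg$spike_width_ms), " Hz)")
  }
  if (cfg$seeg_noise_uv < 0 || cfg$artifact_rate < 0) {
    stop_invalid("noise and artifact amplitudes/rates must be non-negative")
  }
  if (!is.na(cfg$n_ieds_per_subject) && cfg$n_ieds_per_subject < 1) {
    stop_invalid("n_ieds_per_subject must be >= 1 (or NA to draw 50-953)")
  }
  invisible(cfg)
}

# --- IED template ----------------------------------------------------------

#' Spike-plus-slow-wave IED template
#'
#' Builds the canonical interictal discharge transient: a sharp spike
#' (asymmetric Gaussian, faster rise than decay) followed by a lower,
#' broader slow wave (half-sine).  The waveform's absolute maximum sits on
#' the sharp component and equals `amplitude`.
#'
#' @param sampling_rate sampling rate in Hz.
#' @param spike_width_ms width of the sharp component, ms.
#' @param slow_wave_width_ms width of the following slow wave, ms; must
#'   exceed `spike_width_ms`.
#' @param amplitude peak amplitude in uV; 0 gives an all-zero waveform.
#' @param seed optional seed controlling small shape jitter (slow-wave
#'   amplitude ratio, decay asymmetry); same arguments + seed give an
#'   identical array.
#' @return list with `waveform` (numeric vector) and `peak_index`
#'   (0-based index of the absolute peak).
#' @export
ied_template <- function(sampling_rate, spike_width_ms = 70,
                         slow_wave_width_ms = 350, amplitude = 100,
                         seed = NULL) {
  if (sampling_rate <= 0) stop_invalid("sampling_rate must be positive")
  if (spike_width_ms <= 0 || slow_wave_width_ms <= 0) {
    stop_invalid("template widths must be positive")
  }
  if (spike_width_ms >= slow_wave_width_ms) {
    stop_invalid("spike_width_ms must be smaller than slow_wave_width_ms")
  }
  jit <- with_seed(seed, {
    if (is.null(seed)) c(ratio = 0.375, asym = 1.5)
    else c(ratio = stats::runif(1, 0.30, 0.45),
           asym = stats::runif(1, 1.3, 1.7))
  })
  sw <- spike_width_ms / 1000
  lw <- slow_wave_width_ms / 1000
  dur <- sw + 1.15 * lw
  n <- ceiling(dur * sampling_rate) + 1L
  t <- (seq_len(n) - 1) / sampling_rate
  tp <- sw / 2
  sig_rise <- sw / 6
  sig_fall <- sw / 6 * jit[["asym"]]
  spike <- ifelse(t < tp,
                  exp(-0.5 * ((t - tp) / sig_rise)^2),
                  exp(-0.5 * ((t - tp) / sig_fall)^2))
  t0 <- sw                               # slow wave starts as the spike ends
  slow <- ifelse(t >= t0 & t <= t0 + lw,
                 jit[["ratio"]] * sin(pi * (t - t0) / lw), 0)
  w <- spike + slow
  if (amplitude == 0) {
    w <- w * 0
    peak <- which.max(spike) - 1L       # morphological peak position
  } else {
    w <- w * (amplitude / max(abs(w)))
    peak <- which.max(abs(w)) - 1L
  }
  list(waveform = as.numeric(w), peak_index = as.integer(peak))
}

# --- geometry and noise ----------------------------------------------------

scalp_channel_names <- function() {
  c("Fp1", "F3", "F7", "C3", "T3", "P3", "T5", "O1",
    "Fp2", "F4", "F8", "C4", "T4", "P4", "T6", "O2",
    "Fz", "Cz", "Pz", "Oz")
}

fo_channel_names <- function() {
  c(paste0("LFO", 1:6), paste0("RFO", 1:6))
}

# approximate 2-D scalp coordinates (unit head) for the 20 electrodes
scalp_coords <- function() {
  m <- rbind(
    Fp1 = c(-0.31, 0.95), F3 = c(-0.45, 0.52), F7 = c(-0.81, 0.59),
    C3 = c(-0.50, 0.00), T3 = c(-1.00, 0.00), P3 = c(-0.45, -0.52),
    T5 = c(-0.81, -0.59), O1 = c(-0.31, -0.95),
    Fp2 = c(0.31, 0.95), F4 = c(0.45, 0.52), F8 = c(0.81, 0.59),
    C4 = c(0.50, 0.00), T4 = c(1.00, 0.00), P4 = c(0.45, -0.52),
    T6 = c(0.81, -0.59), O2 = c(0.31, -0.95),
    Fz = c(0.00, 0.50), Cz = c(0.00, 0.00), Pz = c(0.00, -0.50),
    Oz = c(0.00, -0.95))
  m[scalp_channel_names(), , drop = FALSE]
}

# FO contact coordinates: two 6-contact bundles near the temporal regions
fo_coords <- function() {
  y <- seq(-0.15, 0.20, length.out = 6)
  rbind(cbind(-0.85, y), cbind(0.85, y))
}

# 1/f^alpha background, one column per channel, scaled to `rms` per channel
colored_noise <- function(n, n_ch, alpha, rms, sampling_rate) {
  raw <- matrix(stats::rnorm(n * n_ch), n, n_ch)
  if (rms == 0) return(raw * 0)
  f <- seq(0, sampling_rate, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, sampling_rate - f)       # two-sided frequency axis
  f[f < f[2L]] <- f[2L]                 # keep DC finite
  h <- f^(-alpha / 2)
  out <- apply(raw, 2, function(x) Re(stats::fft(stats::fft(x) * h,
                                                 inverse = TRUE)) / n)
  out <- sweep(out, 2, apply(out, 2, stats::sd), "/") * rms
  out
}

# --- subject simulation ----------------------------------------------------

#' Simulate one subject's paired scalp/intracranial recording
#'
#' Forward model: each IED event is a spike-plus-slow-wave source with a
#' subject-fixed focal spatial weight vector over the 12 intracranial
#' contacts (unit L2 norm).  Intracranial channels receive the near-field
#' projection plus low-amplitude 1/f^alpha noise.  Scalp channels receive
#' the same sources through a distance-based mixing matrix, scaled so the
#' strongest scalp channel's peak equals `seeg_attenuation` times the source
#' amplitude, plus stronger spatially correlated colored noise, a 10 Hz
#' posterior rhythm, and intermittent eye-blink-like frontal artifacts.  For
#' a `1 - visibility_fraction` share of events the scalp gain is further
#' suppressed so the clean projection falls below the scalp noise floor
#' (35% of the background RMS).  `ied_peaks` annotates every event's peak
#' regardless of scalp visibility, mirroring intracranially based
#' annotation.
#'
#' @param cfg a [synthesis_config()].
#' @param subject_index 1-based subject number; also the sub-seed index, so
#'   `simulate_subject(cfg, i)` reproduces cohort member `i` exactly.
#' @return a [paired_recording()] with `event_info` columns
#'   `peak`, `amplitude_uv`, `visible`, `scalp_gain`.
#' @export
simulate_subject <- function(cfg, subject_index) {
  validate_synthesis_config(cfg)
  fs <- cfg$sampling_rate
  with_seed(derive_seed(cfg$seed, subject_index), {
    n_ied <- if (is.na(cfg$n_ieds_per_subject)) {
      sample(50:953, 1L)
    } else as.integer(cfg$n_ieds_per_subject)
    dur <- if (is.na(cfg$duration_s)) max(300, ceiling(2.5 * n_ied)) else
      cfg$duration_s
    n <- as.integer(round(dur * fs))

    # subject-fixed source geometry
    side <- sample(c(0L, 6L), 1L)                 # dominant bundle
    centre <- side + sample(1:6, 1L)
    w_ieeg <- exp(-((1:12 - centre)^2) / (2 * 1.5^2)) *
      (1 + 0.15 * stats::rnorm(12))
    w_ieeg <- abs(w_ieeg) / sqrt(sum(w_ieeg^2))   # unit-norm, focal
    sc <- scalp_coords()
    fo <- fo_coords()
    d2 <- outer(seq_len(20), seq_len(12), function(i, j) {
      (sc[i, 1] - fo[j, 1])^2 + (sc[i, 2] - fo[j, 2])^2 + 0.6^2
    })
    mix <- exp(-d2 / (2 * 0.5^2))                 # skull blur / volume spread
    p_scalp <- as.numeric(mix %*% w_ieeg)
    p_scalp <- p_scalp / max(abs(p_scalp)) * cfg$seeg_attenuation

    # event placement: uniform with >= 1 s refractory gap, 100-sample margin
    gap <- as.integer(fs)
    margin <- 100L
    span <- n - 2L * margin - (n_ied - 1L) * gap
    if (span <= n_ied) {
      stop_invalid("duration too short to place ", n_ied,
                   " IEDs with 1 s refractory gaps")
    }
    peaks <- sort(sample.int(span, n_ied)) + margin +
      (seq_len(n_ied) - 1L) * gap                 # 0-based peak samples
    amps <- cfg$ied_amplitude_uv * stats::runif(n_ied, 0.8, 1.2)
    ratio_jit <- stats::runif(n_ied, 0.30, 0.45)
    asym_jit <- stats::runif(n_ied, 1.3, 1.7)
    n_vis <- round(cfg$visibility_fraction * n_ied)
    visible <- rep(FALSE, n_ied)
    visible[sample.int(n_ied, n_vis)] <- TRUE

    # noise draws are made after all event draws and always in this order,
    # so zeroing noise amplitudes leaves the event stream untouched
    sigma_i <- if (is.finite(cfg$ieeg_snr_db)) {
      cfg$ied_amplitude_uv * max(w_ieeg) / 10^(cfg$ieeg_snr_db / 20)
    } else 0
    noise_i <- colored_noise(n, 12L, cfg$noise_color_exponent, sigma_i, fs)
    noise_s <- colored_noise(n, 20L, cfg$noise_color_exponent,
                             cfg$seeg_noise_uv, fs)
    if (cfg$seeg_noise_uv > 0) {                  # spatial correlation
      dch <- outer(seq_len(20), seq_len(20), function(i, j) {
        (sc[i, 1] - sc[j, 1])^2 + (sc[i, 2] - sc[j, 2])^2
      })
      cmat <- exp(-dch / (2 * 0.4^2))
      cmat <- cmat / sqrt(rowSums(cmat^2))        # preserve channel RMS
      noise_s <- noise_s %*% t(cmat)
    }
    alpha_phase <- stats::runif(20, 0, 2 * pi)
    alpha_w <- exp(-((sc[, 2] + 0.95)^2) / (2 * 0.6^2))  # posterior emphasis
    tvec <- (seq_len(n) - 1) / fs
    alpha_env <- 0.5 * (1 + sin(2 * pi * 0.1 * tvec))
    alpha_amp <- 0.7 * cfg$seeg_noise_uv
    for (ch in seq_len(20)) {
      noise_s[, ch] <- noise_s[, ch] + alpha_amp * alpha_w[ch] *
        alpha_env * sin(2 * pi * 10 * tvec + alpha_phase[ch])
    }
    n_art <- stats::rpois(1, cfg$artifact_rate * dur / 60)
    art_pos <- stats::runif(max(n_art, 1L), 0.05, 0.95) * n
    art_amp <- stats::runif(max(n_art, 1L), 80, 150)
    art_wid <- stats::runif(max(n_art, 1L), 0.3, 0.5)
    blink_w <- blink_weights()

    ieeg <- noise_i
    seeg <- noise_s
    scalp_gain <- numeric(n_ied)
    for (e in seq_len(n_ied)) {
      tpl <- ied_shape(fs, cfg$spike_width_ms, cfg$slow_wave_width_ms,
                       ratio_jit[e], asym_jit[e])
      idx <- peaks[e] - tpl$peak_index + seq_along(tpl$waveform)  # 1-based
      keep <- idx >= 1L & idx <= n
      src <- amps[e] * tpl$waveform[keep]
      ieeg[idx[keep], ] <- ieeg[idx[keep], ] + src %*% t(w_ieeg)
      win <- intersect((peaks[e] - 31L):(peaks[e] + 32L), idx[keep])
      src_win <- amps[e] * tpl$waveform[match(win, idx)]
      rms1 <- sqrt(mean((src_win %*% t(p_scalp))^2))
      g <- if (visible[e]) 1 else {
        if (cfg$seeg_noise_uv > 0) min(1, 0.35 * cfg$seeg_noise_uv / rms1)
        else 0
      }
      scalp_gain[e] <- g
      seeg[idx[keep], ] <- seeg[idx[keep], ] + g * src %*% t(p_scalp)
    }
    if (n_art > 0) {
      for (a in seq_len(n_art)) {
        wd <- as.integer(art_wid[a] * fs)
        i0 <- as.integer(art_pos[a])
        idx <- i0 + seq_len(wd)
        idx <- idx[idx >= 1L & idx <= n]
        shape <- sin(pi * seq_along(idx) / length(idx))^2
        seeg[idx, ] <- seeg[idx, ] + art_amp[a] * shape %*% t(blink_w)
      }
    }

    paired_recording(
      seeg = eeg_recording(seeg, fs, scalp_channel_names()),
      ieeg = eeg_recording(ieeg, fs, fo_channel_names()),
      ied_peaks = peaks,
      subject_id = paste0("S", subject_index),
      event_info = data.frame(peak = peaks, amplitude_uv = amps,
                              visible = visible, scalp_gain = scalp_gain))
  })
}

# raw (unit-amplitude) template used per event; shares the ied_template
# morphology but takes jitter parameters explicitly so the per-event RNG
# stream stays flat
ied_shape <- function(fs, spike_width_ms, slow_wave_width_ms, ratio, asym) {
  sw <- spike_width_ms / 1000
  lw <- slow_wave_width_ms / 1000
  n <- ceiling((sw + 1.15 * lw) * fs) + 1L
  t <- (seq_len(n) - 1) / fs
  tp <- sw / 2
  spike <- ifelse(t < tp, exp(-0.5 * ((t - tp) / (sw / 6))^2),
                  exp(-0.5 * ((t - tp) / (sw / 6 * asym))^2))
  slow <- ifelse(t >= sw & t <= sw + lw, ratio * sin(pi * (t - sw) / lw), 0)
  w <- spike + slow
  w <- w / max(abs(w))
  list(waveform = w, peak_index = which.max(abs(w)) - 1L)
}

# fixed frontal eye-blink topography over the 20 scalp channels
blink_weights <- function() {
  w <- c(Fp1 = 1, Fp2 = 1, F7 = 0.65, F8 = 0.65, F3 = 0.55, F4 = 0.55,
         Fz = 0.5)
  out <- stats::setNames(rep(0.08, 20), scalp_channel_names())
  out[names(w)] <- w
  as.numeric(out)
}

#' Generate a seeded synthetic cohort
#'
#' Runs [simulate_subject()] once per subject with deterministically derived
#' per-subject sub-seeds; subject ids are `"S1"`, `"S2"`, ...  Identical
#' config (including seed) yields a bit-identical cohort.
#'
#' @param cfg a [synthesis_config()].
#' @return list of [paired_recording()] objects, length `cfg$n_subjects`.
#' @export
make_cohort <- function(cfg) {
  validate_synthesis_config(cfg)
  lapply(seq_len(cfg$n_subjects), function(i) simulate_subject(cfg, i))
}
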