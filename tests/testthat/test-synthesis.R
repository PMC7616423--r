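test_that("IED template has spike-then-slow-wave morphology at the requested amplitude", {
  tpl <- ied_template(200, spike_width_ms = 70, slow_wave_width_ms = 350,
                      amplitude = 100, seed = 1)
  w <- tpl$waveform
  expect_gte(length(w), 0.42 * 200)
  expect_equal(max(abs(w)), 100)
  expect_equal(which.max(abs(w)) - 1L, tpl$peak_index)
  # the absolute peak sits on the sharp component, before the slow wave
  spike_end <- ceiling(0.070 * 200)
  expect_lt(tpl$peak_index, spike_end)
  slow_part <- w[(spike_end + 2):length(w)]
  expect_gt(max(abs(slow_part)), 0)          # a slow wave exists ...
  expect_lt(max(abs(slow_part)), 100)        # ... and is lower than the spike
  expect_gt(which.max(abs(slow_part)) + spike_end, tpl$peak_index)
})

test_that("IED template zero-amplitude and determinism contracts hold", {
  z <- ied_template(200, amplitude = 0, seed = 3)
  expect_true(all(z$waveform == 0))
  a <- ied_template(200, amplitude = 80, seed = 11)
  b <- ied_template(200, amplitude = 80, seed = 11)
  expect_identical(a, b)
  c <- ied_template(200, amplitude = 80, seed = 12)
  expect_false(identical(a$waveform, c$waveform))
})

test_that("IED template rejects invalid parameters", {
  expect_error(ied_template(0), "sampling_rate")
  expect_error(ied_template(200, spike_width_ms = -5), "positive")
  expect_error(ied_template(200, spike_width_ms = 400,
                            slow_wave_width_ms = 300), "smaller")
})

test_that("simulated subject conserves events with well-placed peaks", {
  p <- small_subject()
  expect_equal(length(p$ied_peaks), 40L)
  expect_equal(nrow(p$event_info), 40L)
  n <- nrow(p$seeg$data)
  expect_true(all(p$ied_peaks >= 32 & p$ied_peaks <= n - 32))
  expect_true(all(diff(p$ied_peaks) >= p$sampling_rate))  # 1 s refractory
  expect_equal(ncol(p$seeg$data), 20L)
  expect_equal(ncol(p$ieeg$data), 12L)
  # bit-identical rerun
  q <- simulate_subject(small_subject_cfg(), 1L)
  expect_identical(p$seeg$data, q$seeg$data)
  expect_identical(p$ied_peaks, q$ied_peaks)
})

test_that("noise-free run recovers the skull attenuation scalar exactly", {
  cfg <- synthesis_config(n_subjects = 1, duration_s = 120,
                          n_ieds_per_subject = 40, visibility_fraction = 1,
                          seeg_attenuation = 0.5, seeg_noise_uv = 0,
                          ieeg_snr_db = Inf, artifact_rate = 0, seed = 5)
  p <- simulate_subject(cfg, 1L)
  for (e in seq_len(40)) {
    pk <- p$ied_peaks[e] + 1L                 # 0-based -> R row
    scalp_peak <- max(abs(p$seeg$data[pk, ]))
    expect_equal(scalp_peak, 0.5 * p$event_info$amplitude_uv[e],
                 tolerance = 1e-8)
  }
})

test_that("scalp visibility fraction is controlled and iEEG sees events better", {
  cfg <- synthesis_config(n_subjects = 1, n_ieds_per_subject = 200,
                          visibility_fraction = 0.15, seed = 13)
  noisy <- simulate_subject(cfg, 1L)
  # oracle: rerun with all noise amplitudes zeroed; event stream identical
  cfg0 <- synthesis_config(n_subjects = 1, n_ieds_per_subject = 200,
                           visibility_fraction = 0.15, seed = 13,
                           seeg_noise_uv = 0, ieeg_snr_db = Inf,
                           artifact_rate = 0)
  clean <- simulate_subject(cfg0, 1L)
  expect_identical(noisy$ied_peaks, clean$ied_peaks)
  win_rms <- function(mat, pk) {
    sqrt(mean(mat[(pk - 31):(pk + 32) + 1L, ]^2))
  }
  snr_clean <- vapply(clean$ied_peaks, win_rms, 1, mat = clean$seeg$data) /
    cfg$seeg_noise_uv
  expect_lt(abs(mean(snr_clean > 1) - 0.15), 0.05)
  # modality asymmetry on the noisy data
  bg_i <- sqrt(mean(noisy$ieeg$data^2))
  bg_s <- sqrt(mean(noisy$seeg$data^2))
  snr_i <- vapply(noisy$ied_peaks, win_rms, 1, mat = noisy$ieeg$data) / bg_i
  snr_s <- vapply(noisy$ied_peaks, win_rms, 1, mat = noisy$seeg$data) / bg_s
  expect_gt(mean(snr_i), mean(snr_s))
  expect_gt(median(snr_i), median(snr_s))
})

test_that("cohorts are deterministic with per-subject sub-seeds and S1.. ids", {
  cfg <- synthesis_config(n_subjects = 4, duration_s = 100,
                          n_ieds_per_subject = 20, seed = 3)
  co <- make_cohort(cfg)
  expect_equal(vapply(co, function(p) p$subject_id, ""),
               paste0("S", 1:4))
  co2 <- make_cohort(cfg)
  expect_identical(co, co2)
  # a cohort of one is exactly the first simulate_subject stream
  cfg1 <- synthesis_config(n_subjects = 1, duration_s = 100,
                           n_ieds_per_subject = 20, seed = 3)
  expect_identical(make_cohort(cfg1)[[1L]], simulate_subject(cfg1, 1L))
  # different subjects differ
  expect_false(identical(co[[1L]]$seeg$data, co[[2L]]$seeg$data))
})

test_that("impossible event packing raises a simulation error", {
  cfg <- synthesis_config(n_subjects = 1, duration_s = 30,
                          n_ieds_per_subject = 100, seed = 2)
  expect_error(simulate_subject(cfg, 1L), "duration too short")
})

test_that("invalid synthesis configurations are rejected", {
  expect_error(synthesis_config(visibility_fraction = 0), "visibility")
  expect_error(synthesis_config(seeg_attenuation = 1.2), "attenuation")
  expect_error(synthesis_config(n_subjects = 0), "n_subjects")
  expect_error(synthesis_config(sampling_rate = 20), "sampling_rate")
})
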