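# Run configuration: one YAML file, one global seed.
#
# Stage seeds derive from the global seed by fixed offsets so a single
# integer reproduces a whole run.

run_config_defaults <- function() {
  list(
    seed = 1L,
    synthesis = list(n_subjects = 18L, duration_s = NA,
                     sampling_rate = 200, n_ieds_per_subject = NA,
                     visibility_fraction = 0.15, ied_amplitude_uv = 300,
                     ieeg_snr_db = 15, seeg_attenuation = 0.4,
                     seeg_noise_uv = 7, noise_color_exponent = 1,
                     artifact_rate = 5, spike_width_ms = 70,
                     slow_wave_width_ms = 350),
    translator = list(base_feature_channels = 16L, n_levels = 3L,
                      kernel_time = 5L, lambda_l2 = 100,
                      dropout_rate = 0.25, learning_rate = 1e-3,
                      batch_size = 32L, n_epochs = 100L,
                      adversarial_mode = "non_saturating",
                      l2_squared = FALSE),
    detector = list(temporal_filters = 8L, depth_multiplier = 2L,
                    separable_filters = 16L, temporal_kernel = 32L,
                    separable_kernel = 16L, dropout_rate = 0.25,
                    learning_rate = 1e-3, batch_size = 32L,
                    n_epochs = 100L),
    evaluation = list(threshold = 0.70, fractions = c(0.7, 0.1, 0.2)),
    paths = list(cohort_dir = "cohort"))
}

merge_config <- function(defaults, user, where = "") {
  extra <- setdiff(names(user), names(defaults))
  if (length(extra)) {
    stop_invalid("unknown config key(s)", if (nzchar(where))
      paste0(" in ", where), ": ", paste(extra, collapse = ", "))
  }
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
                          !is.null(names(defaults[[nm]]))) {
      merge_config(defaults[[nm]], user[[nm]], nm)
    } else user[[nm]]
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML file with sections `synthesis`, `translator`, `detector`,
#' `evaluation`, `paths`, and a global `seed`; unspecified keys take the
#' package defaults, unknown keys are rejected.  Parse -> serialize ->
#' parse is the identity.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a named list of class `run_config`.
#' @export
load_run_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- merge_config(run_config_defaults(), user)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Save a run configuration as YAML
#'
#' @param cfg a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

run_synthesis_config <- function(cfg) {
  do.call(synthesis_config, c(cfg$synthesis, list(seed = cfg$seed)))
}

run_translator_config <- function(cfg) {
  do.call(translator_config,
          c(cfg$translator, list(seed = derive_seed(cfg$seed, 2L))))
}

run_detector_config <- function(cfg) {
  do.call(detector_config,
          c(cfg$detector, list(seed = derive_seed(cfg$seed, 3L))))
}
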