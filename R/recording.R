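#' Multichannel recording container
#'
#' A thin container for a time-by-channel real-valued signal matrix with its
#' sampling rate and channel labels.  All preprocessing operations consume
#' and return this type.
#'
#' @param data numeric matrix, time samples in rows, channels in columns (uV).
#' @param sampling_rate sampling rate in Hz.
#' @param labels character vector of channel names, one per column.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, labels) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number")
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(data)) {
    stop("`labels` must name every channel: got ", length(labels),
         " labels for ", ncol(data), " channels")
  }
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  colnames(data) <- labels
  structure(
    list(data = data, sampling_rate = sampling_rate, labels = labels),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              nrow(x$data) / x$sampling_rate))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Paired scalp/intracranial recording for one subject
#'
#' Bundles the two simultaneously recorded modalities on a shared sample
#' clock together with the intracranially annotated IED peak positions.
#' Peak indices are 0-based sample positions on the shared clock; every peak
#' `p` satisfies `32 <= p <= n_samples - 32` so that a full 64-sample
#' segment around it always fits.
#'
#' @param seeg `eeg_recording`, scalp EEG.
#' @param ieeg `eeg_recording`, intracranial (foramen-ovale) EEG.
#' @param ied_peaks integer vector of 0-based IED peak sample indices.
#' @param subject_id subject identifier string.
#' @param event_info optional data.frame of per-event simulator metadata
#'   (amplitudes, visibility flags); `NULL` for real data.
#' @return an object of class `paired_recording`.
#' @export
paired_recording <- function(seeg, ieeg, ied_peaks, subject_id,
                             event_info = NULL) {
  stopifnot(inherits(seeg, "eeg_recording"), inherits(ieeg, "eeg_recording"))
  if (nrow(seeg$data) != nrow(ieeg$data)) {
    stop("scalp and intracranial recordings must have equal sample counts ",
         "(simultaneous recording)")
  }
  if (seeg$sampling_rate != ieeg$sampling_rate) {
    stop("scalp and intracranial sampling rates differ")
  }
  n <- nrow(seeg$data)
  ied_peaks <- as.integer(round(ied_peaks))
  if (length(ied_peaks) &&
      (min(ied_peaks) < 32L || max(ied_peaks) > n - 32L)) {
    stop("every IED peak p must satisfy 32 <= p <= n_samples - 32 (0-based)")
  }
  structure(
    list(seeg = seeg, ieeg = ieeg, sampling_rate = seeg$sampling_rate,
         ied_peaks = ied_peaks, subject_id = as.character(subject_id),
         event_info = event_info),
    class = "paired_recording"
  )
}

#' @export
print.paired_recording <- function(x, ...) {
  cat(sprintf(
    "<paired_recording> subject %s: %d samples @ %g Hz, %d scalp + %d intracranial channels, %d IEDs\n",
    x$subject_id, nrow(x$seeg$data), x$sampling_rate,
    ncol(x$seeg$data), ncol(x$ieeg$data), length(x$ied_peaks)))
  invisible(x)
}
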