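# EDF and tabular I/O.
#
# The EDF writer/reader below implements the classic 16-bit European Data
# Format (fixed 256-byte header, 256 bytes per signal, little-endian int16
# records with per-channel physical/digital scaling) — enough to exchange
# recordings with standard EEG tooling.  EDF+ annotations are not used;
# IED peaks travel in a plain CSV sidecar instead.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @param patient_id,recording_id header identification strings.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient_id = "X", recording_id = "X") {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) {
    stop_invalid("EDF writer requires an integer sampling rate")
  }
  fs <- as.integer(round(fs))
  n_ch <- ncol(rec$data)
  n_rec <- nrow(rec$data) %/% fs
  if (n_rec < 1L) stop_invalid("recording shorter than one 1-s data record")
  data <- rec$data[seq_len(n_rec * fs), , drop = FALSE]
  pmin_ <- apply(data, 2, min)
  pmax_ <- apply(data, 2, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(pad_field(x, w), con, nchars = w,
                                 eos = NULL)
  wr("0", 8)
  wr(patient_id, 80)
  wr(recording_id, 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256L * (n_ch + 1L), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr(1, 8)
  wr(n_ch, 4)
  for (lab in rec$labels) wr(lab, 16)
  for (i in seq_len(n_ch)) wr("", 80)
  for (i in seq_len(n_ch)) wr("uV", 8)
  for (i in seq_len(n_ch)) wr(signif(pmin_[i], 7), 8)
  for (i in seq_len(n_ch)) wr(signif(pmax_[i], 7), 8)
  for (i in seq_len(n_ch)) wr(dmin, 8)
  for (i in seq_len(n_ch)) wr(dmax, 8)
  for (i in seq_len(n_ch)) wr("", 80)
  for (i in seq_len(n_ch)) wr(fs, 8)
  for (i in seq_len(n_ch)) wr("", 32)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(n_ch)) {
      dig <- round((data[rows, ch] - pmin_[ch]) * scale[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads a classic 16-bit EDF file whose signals share one sampling rate.
#'
#' @param path EDF file path.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  labels <- vapply(seq_len(n_ch), function(i) rd(16), "")
  for (i in seq_len(n_ch)) rd(80)
  for (i in seq_len(n_ch)) rd(8)
  pmin_ <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 1)
  pmax_ <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 1)
  dmin <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 1)
  dmax <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 1)
  for (i in seq_len(n_ch)) rd(80)
  spr <- vapply(seq_len(n_ch), function(i) as.integer(rd(8)), 1L)
  for (i in seq_len(n_ch)) rd(32)
  if (length(unique(spr)) != 1L) {
    stop_invalid("mixed per-signal sampling rates are not supported")
  }
  fs <- spr[1L] / rec_dur
  out <- matrix(0, n_rec * spr[1L], n_ch)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    for (ch in seq_len(n_ch)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L,
                     endian = "little")
      out[rows, ch] <- (dig - dmin[ch]) / (dmax[ch] - dmin[ch]) *
        (pmax_[ch] - pmin_[ch]) + pmin_[ch]
    }
  }
  eeg_recording(out, fs, labels)
}

#' Write IED peak annotations as CSV
#'
#' Columns: `subject_id`, `peak_sample` (0-based), `label`.
#'
#' @param paired a [paired_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(paired, path) {
  stopifnot(inherits(paired, "paired_recording"))
  df <- data.frame(subject_id = paired$subject_id,
                   peak_sample = paired$ied_peaks,
                   label = "IED")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an IED peak annotation CSV
#'
#' @param path CSV with columns `subject_id`, `peak_sample`, `label`.
#' @return data.frame of annotations (0-based `peak_sample`).
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "peak_sample", "label")
  if (!all(need %in% names(df))) {
    stop_invalid("annotation file must have columns ",
                 paste(need, collapse = ", "))
  }
  df$peak_sample <- as.integer(df$peak_sample)
  df
}

#' Write a synthetic cohort to disk
#'
#' One EDF per subject per modality (`<id>_scalp.edf`, `<id>_ieeg.edf`),
#' one annotation CSV per subject, and a JSON manifest.
#'
#' @param cohort list of [paired_recording()]s.
#' @param dir output directory (created if needed).
#' @param config optional [synthesis_config()] echoed into the manifest.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort, function(p) {
    id <- p$subject_id
    write_edf(p$seeg, file.path(dir, paste0(id, "_scalp.edf")),
              patient_id = id)
    write_edf(p$ieeg, file.path(dir, paste0(id, "_ieeg.edf")),
              patient_id = id)
    write_annotations(p, file.path(dir, paste0(id, "_annotations.csv")))
    list(subject_id = id,
         scalp_edf = paste0(id, "_scalp.edf"),
         ieeg_edf = paste0(id, "_ieeg.edf"),
         annotations = paste0(id, "_annotations.csv"),
         n_ieds = length(p$ied_peaks),
         n_samples = nrow(p$seeg$data),
         sampling_rate = p$sampling_rate)
  })
  manifest <- list(format = "ieegmap-cohort/1", subjects = entries)
  if (!is.null(config)) manifest$synthesis_config <- unclass(config)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(mp)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.json`.
#' @return list of [paired_recording()]s.
#' @export
read_cohort <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop_invalid("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mp)
  lapply(manifest$subjects, function(e) {
    ann <- read_annotations(file.path(dir, e$annotations))
    paired_recording(
      seeg = read_edf(file.path(dir, e$scalp_edf)),
      ieeg = read_edf(file.path(dir, e$ieeg_edf)),
      ied_peaks = ann$peak_sample,
      subject_id = e$subject_id)
  })
}
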