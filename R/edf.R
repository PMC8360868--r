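#' Construct an EEG recording object
#'
#' The unit of feature extraction: a multichannel waveform in microvolts
#' plus the subject metadata needed downstream (gestational age at birth,
#' postmenstrual age at the recording, morphine exposure).
#'
#' @param data numeric matrix, samples x channels, in microvolts.
#' @param fs_hz sampling rate in Hz (256 for the BrainZ monitors).
#' @param channels character vector of channel labels.
#' @param subject_id,recording_id opaque identifiers.
#' @param pma_weeks postmenstrual age at recording start, decimal weeks.
#' @param ga_weeks gestational age at birth, decimal weeks.
#' @param morphine logical, morphine given as sedation.
#' @param epoch_index ordinal of the serial recording (0 = first 72-h
#'   recording after birth).
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs_hz, channels = colnames(data),
                          subject_id = NA_character_,
                          recording_id = NA_character_,
                          pma_weeks = NA_real_, ga_weeks = NA_real_,
                          morphine = NA, epoch_index = 0L) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(data)))
  stopifnot(length(channels) == ncol(data), fs_hz > 0)
  if (!is.na(pma_weeks) && !is.na(ga_weeks) && pma_weeks < ga_weeks)
    stop("pma_weeks must be >= ga_weeks")
  colnames(data) <- channels
  structure(list(data = data, fs_hz = fs_hz, channels = channels,
                 subject_id = subject_id, recording_id = recording_id,
                 pma_weeks = pma_weeks, ga_weeks = ga_weeks,
                 morphine = morphine, epoch_index = as.integer(epoch_index)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s / %s: %d ch x %d samples @ %g Hz (%.1f s), PMA %.2f w\n",
              x$subject_id, x$recording_id, ncol(x$data), nrow(x$data),
              x$fs_hz, nrow(x$data) / x$fs_hz, x$pma_weeks))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @export
rec_duration <- function(rec) nrow(rec$data) / rec$fs_hz

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to a 16-bit EDF file
#'
#' Minimal continuous-recording EDF writer: one data record per second,
#' per-channel physical scaling chosen from the data range.  The waveform
#' is zero-padded to a whole number of records.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  data <- rec$data
  fs <- rec$fs_hz
  spr <- as.integer(round(fs))            # samples per 1-s record
  nrec <- as.integer(ceiling(nrow(data) / spr))
  if (nrow(data) < nrec * spr)
    data <- rbind(data, matrix(0, nrec * spr - nrow(data), ncol(data)))
  ns <- ncol(data)
  pmin_ <- pmax_ <- numeric(ns)
  dig <- matrix(0L, nrow(data), ns)
  for (j in seq_len(ns)) {
    amax <- max(abs(data[, j]), 1e-6)
    pmax_[j] <- ceiling(amax)
    pmin_[j] <- -pmax_[j]
    dig[, j] <- as.integer(round(data[, j] / pmax_[j] * 32767))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8),
    pad_ascii(rec$subject_id %||% "X", 80),
    pad_ascii(rec$recording_id %||% "X", 80),
    "01.01.00", "00.00.00",
    pad_ascii(256 + ns * 256, 8),
    pad_ascii("", 44),
    pad_ascii(nrec, 8),
    pad_ascii(1, 8),
    pad_ascii(ns, 4),
    paste(pad_ascii(rec$channels, 16), collapse = ""),
    paste(rep(pad_ascii("", 80), ns), collapse = ""),
    paste(rep(pad_ascii("uV", 8), ns), collapse = ""),
    paste(pad_ascii(pmin_, 8), collapse = ""),
    paste(pad_ascii(pmax_, 8), collapse = ""),
    paste(rep(pad_ascii(-32768L, 8), ns), collapse = ""),
    paste(rep(pad_ascii(32767L, 8), ns), collapse = ""),
    paste(rep(pad_ascii("", 80), ns), collapse = ""),
    paste(rep(pad_ascii(spr, 8), ns), collapse = ""),
    paste(rep(pad_ascii("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  # record-major layout: record r holds spr samples of each channel in turn
  idx <- matrix(seq_len(nrec * spr), nrow = spr)
  for (r in seq_len(nrec)) {
    block <- as.integer(dig[idx[, r], , drop = FALSE])
    writeBin(block, con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16); fld(80); fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin_ <- as.numeric(fld(8)); dmax_ <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  dat <- matrix(NA_real_, nrec * spr[1], ns)
  for (r in seq_len(nrec)) {
    for (j in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[j], size = 2, endian = "little")
      dat[((r - 1) * spr[j] + 1):(r * spr[j]), j] <-
        pmin_[j] + (v - dmin_[j]) * (pmax_[j] - pmin_[j]) / (dmax_[j] - dmin_[j])
    }
  }
  colnames(dat) <- labels
  list(data = dat, fs_hz = spr[1] / recdur, channels = labels)
}

normalize_channel_labels <- function(labels) {
  up <- toupper(gsub("[^A-Za-z0-9]", "", labels))
  out <- labels
  out[grepl("F3", up) & grepl("P3", up)] <- "F3-P3"
  out[grepl("F4", up) & grepl("P4", up)] <- "F4-P4"
  out
}

#' Read an EEG recording (EDF or CSV) with subject metadata
#'
#' Reads a 16-bit EDF file, or the package's CSV fallback dialect (a plain
#' CSV whose columns are channels in microvolts, sampled at
#' `metadata$fs_hz` or 256 Hz).  Channel labels matching the expected
#' bipolar derivations are normalized to `"F3-P3"` / `"F4-P4"`.
#'
#' @param path EDF or CSV file path.
#' @param metadata one-row data.frame (or list) with `subject_id`,
#'   `ga_weeks`, `morphine`, `recording_id`, `pma_weeks`, and optionally
#'   `epoch_index` and `fs_hz` for CSV input.
#' @return an [eeg_recording()].
#' @export
read_eeg <- function(path, metadata = list()) {
  md <- as.list(metadata)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    raw <- read_edf_raw(path)
  } else {
    tab <- read.csv(path, check.names = FALSE)
    raw <- list(data = as.matrix(tab), fs_hz = md$fs_hz %||% 256,
                channels = colnames(tab))
  }
  if (ncol(raw$data) < 1) stop("EEG file has no channels: ", path)
  labs <- normalize_channel_labels(raw$channels)
  if (anyDuplicated(labs)) stop("duplicate channel labels in ", path)
  if (abs(raw$fs_hz - 256) > 1e-9)
    warning(sprintf("sampling rate %g Hz differs from the expected 256 Hz; windows are defined in seconds so features remain computable", raw$fs_hz))
  eeg_recording(raw$data, fs_hz = raw$fs_hz, channels = labs,
                subject_id = md$subject_id %||% NA_character_,
                recording_id = md$recording_id %||% NA_character_,
                pma_weeks = md$pma_weeks %||% NA_real_,
                ga_weeks = md$ga_weeks %||% NA_real_,
                morphine = as.logical(md$morphine %||% NA),
                epoch_index = md$epoch_index %||% 0L)
}

#' Write a recording to disk
#'
#' Dispatches on the file extension: `.edf` uses [write_edf()], anything
#' else writes the CSV fallback dialect readable by [read_eeg()].
#'
#' @inheritParams write_edf
#' @export
write_eeg <- function(rec, path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) return(write_edf(rec, path))
  write.csv(as.data.frame(rec$data), path, row.names = FALSE)
  invisible(path)
}
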