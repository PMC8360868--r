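# Filtering chain and epoch/segment handling.
#
# The recorded signals are band-limited to 2-40 Hz: the bedside monitors
# already impose a 2 Hz analogue high-pass, so the digital chain applies a
# linear-phase FIR high-pass at 2 Hz followed by an FIR low-pass at 40 Hz
# (Hamming windowed-sinc, 1 Hz transition), each run forward-backward for
# zero phase, plus a zero-phase 50 Hz IIR notch for line interference.

fir_taps <- function(fs, cutoff_hz, type, transition_hz = 1) {
  ord <- ceiling(3.3 * fs / transition_hz)
  if (ord %% 2 == 1) ord <- ord + 1          # type-I (odd length) for HP
  signal::fir1(ord, cutoff_hz / (fs / 2), type = type)
}

# Delay-compensated FIR pass (symmetric taps, odd length).
fir_pass <- function(b, x) {
  nb <- length(b)
  d <- (nb - 1L) %/% 2L
  n <- length(x)
  y <- signal::fftfilt(b, c(x, numeric(nb)))
  y[(d + 1L):(d + n)]
}

fir_zerophase <- function(b, x) {
  y <- fir_pass(b, x)
  rev(fir_pass(b, rev(y)))
}

notch_coefs <- function(fs, f0 = 50, q = 30) {
  w0 <- 2 * pi * f0 / fs
  al <- sin(w0) / (2 * q)
  list(b = c(1, -2 * cos(w0), 1) / (1 + al),
       a = c(1, -2 * cos(w0) / (1 + al), (1 - al) / (1 + al)))
}

#' Band-pass and notch filter a recording
#'
#' Zero-phase 2--40 Hz FIR band-pass (high-pass then low-pass, Hamming
#' windowed-sinc, 1 Hz transition width, forward-backward) followed by a
#' zero-phase second-order 50 Hz notch.  Removes DC and out-of-band
#' artifact while leaving the 3--38 Hz passband gain within +/-0.5 dB.
#'
#' @param rec an [eeg_recording()].
#' @param config configuration list from [neomat_config()].
#' @return the filtered recording.
#' @export
bandpass_notch <- function(rec, config = neomat_config()) {
  fc <- config$filter
  fs <- rec$fs_hz
  bh <- fir_taps(fs, fc$hp_hz, "high", fc$transition_hz)
  bl <- fir_taps(fs, fc$lp_hz, "low", fc$transition_hz)
  need <- length(bh)
  if (nrow(rec$data) < need)
    stop(sprintf("recording too short to filter: %d samples, need at least %d",
                 nrow(rec$data), need))
  nc <- notch_coefs(fs, fc$notch_hz, fc$notch_q)
  out <- rec
  for (j in seq_len(ncol(rec$data))) {
    x <- fir_zerophase(bh, rec$data[, j])
    x <- fir_zerophase(bl, x)
    x <- signal::filtfilt(nc$b, nc$a, x)
    out$data[, j] <- x
  }
  out
}

# Per-sample artifact indicator: TRUE where the sample lies in a flat run
# (discrete derivative exactly zero for longer than flat_run_min_s) or is
# clipped at the amplitude rail, in any channel.  A programmatic stand-in
# for visual quality review.
artifact_mask <- function(data, fs, qc) {
  n <- nrow(data)
  bad <- logical(n)
  min_run <- qc$flat_run_min_s * fs
  for (j in seq_len(ncol(data))) {
    d0 <- c(FALSE, diff(data[, j]) == 0)
    r <- rle(d0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    long <- which(r$values & r$lengths > min_run)
    for (k in long) bad[(starts[k] - 1L):ends[k]] <- TRUE
    bad <- bad | abs(data[, j]) >= qc$clip_rail_uv
  }
  bad
}

#' Cut a recording into consecutive analysis epochs
#'
#' Non-overlapping epochs of `epoch_len_s` seconds (nominally 1 h).  Each
#' epoch is flagged `"clean"` unless more than the configured fraction of
#' its samples is flat-lined or clipped, in which case it is `"rejected"`.
#' A recording shorter than one epoch yields a single epoch of its true
#' duration.
#'
#' @param rec an [eeg_recording()].
#' @param epoch_len_s epoch duration in seconds.
#' @param config configuration list.
#' @return data.frame with columns `start_s`, `end_s`, `quality_flag`,
#'   `reject_fraction`.
#' @export
cut_epochs <- function(rec, epoch_len_s = NULL, config = neomat_config()) {
  epoch_len_s <- epoch_len_s %||% config$io$epoch_len_s
  stopifnot(epoch_len_s > 0)
  dur <- rec_duration(rec)
  fs <- rec$fs_hz
  starts <- seq(0, max(0, dur - epoch_len_s), by = epoch_len_s)
  if (length(starts) == 0) starts <- 0
  ends <- pmin(starts + epoch_len_s, dur)
  bad <- artifact_mask(rec$data, fs, config$qc)
  frac <- vapply(seq_along(starts), function(i) {
    idx <- (floor(starts[i] * fs) + 1L):floor(ends[i] * fs)
    mean(bad[idx])
  }, 0)
  data.frame(start_s = starts, end_s = ends,
             quality_flag = ifelse(frac > config$qc$flat_fraction_max,
                                   "rejected", "clean"),
             reject_fraction = frac)
}

#' Select the clean epochs used for feature extraction
#'
#' For a long (multi-day) recording: the best clean epoch (lowest artifact
#' fraction) of each 24-h day, up to three, mirroring the serial-EEG
#' protocol of one representative hour per day of the initial 72-h
#' recording.  For shorter recordings: the single best clean epoch.
#'
#' @param epochs data.frame from [cut_epochs()].
#' @return subset of `epochs`, ordered by start time.
#' @export
select_clean_epochs <- function(epochs) {
  clean <- epochs[epochs$quality_flag == "clean", , drop = FALSE]
  if (nrow(clean) == 0) return(clean)
  if (max(epochs$end_s) <= 86400) {
    return(clean[which.min(clean$reject_fraction), , drop = FALSE])
  }
  day <- floor(clean$start_s / 86400)
  picked <- do.call(rbind, lapply(split(clean, day), function(d)
    d[which.min(d$reject_fraction), , drop = FALSE]))
  picked <- picked[order(picked$start_s), , drop = FALSE]
  head(picked, 3)
}

segment_window_s <- function(purpose, config) {
  switch(purpose,
         spectral_25s = config$spectral$window_s,
         mse_100s = config$complexity$segment_s,
         sat_5min = config$sat$window_5min_s,
         stop("unknown segment purpose: ", purpose))
}

#' Tile an epoch with non-overlapping analysis segments
#'
#' @param epoch one row of the data.frame from [cut_epochs()].
#' @param purpose one of `"spectral_25s"`, `"mse_100s"`, `"sat_5min"`.
#' @param config configuration list.
#' @return data.frame of segment `start_s`/`end_s` (recording time);
#'   the trailing remainder shorter than one window is dropped.
#' @export
segmentize <- function(epoch, purpose, config = neomat_config()) {
  w <- segment_window_s(purpose, config)
  dur <- epoch$end_s - epoch$start_s
  k <- floor(dur / w)
  if (k < 1) return(data.frame(start_s = numeric(0), end_s = numeric(0),
                               purpose = character(0)))
  start <- epoch$start_s + (seq_len(k) - 1) * w
  data.frame(start_s = start, end_s = start + w, purpose = purpose)
}

# Extract one channel of one time interval as a numeric vector.
slice_samples <- function(rec, start_s, end_s, channel) {
  fs <- rec$fs_hz
  idx <- (floor(start_s * fs) + 1L):floor(end_s * fs)
  rec$data[idx, channel]
}
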