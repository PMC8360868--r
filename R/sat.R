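# NLEO-based detection of spontaneous activity transients (SATs) and the
# continuity features (SAT%, mean SAT% per 5 min, median interburst
# interval).

#' Nonlinear energy operator
#'
#' Four-sample quadratic energy tracker in the Plotkin--Swamy form used by
#' the published neonatal burst detector:
#' \eqn{\psi(n) = x(n)x(n-3) - x(n-1)x(n-2)}.  The first three output
#' samples are zero-padded so the output matches the input length.
#'
#' @param x numeric vector (microvolts).
#' @return numeric vector of instantaneous energy (uV^2).
#' @export
nleo <- function(x) {
  n <- length(x)
  if (n < 4) stop("nleo needs at least 4 samples")
  psi <- numeric(n)
  idx <- 4:n
  psi[idx] <- x[idx] * x[idx - 3L] - x[idx - 1L] * x[idx - 2L]
  psi
}

# Apply minimum-duration / gap-merging morphology to a boolean burst mask:
# 1) merge gaps shorter than min_gap_s into bursts, 2) drop bursts shorter
# than min_sat_s, 3) absorb remaining interior IBIs shorter than min_ibi_s
# (record edges keep their truncated state).
clean_mask <- function(mask, fs, min_sat_s, min_gap_s, min_ibi_s) {
  fill_short_gaps <- function(m, max_len) {
    r <- rle(m)
    k <- length(r$values)
    interior <- seq_len(k) > 1 & seq_len(k) < k
    r$values[!r$values & r$lengths < max_len & interior] <- TRUE
    inverse.rle(r)
  }
  mask <- fill_short_gaps(mask, min_gap_s * fs)
  r <- rle(mask)
  r$values[r$values & r$lengths < min_sat_s * fs] <- FALSE
  mask <- inverse.rle(r)
  fill_short_gaps(mask, min_ibi_s * fs)
}

#' Detect SAT events with the NLEO detector
#'
#' The absolute NLEO output is smoothed with a centred moving average
#' (`smooth_s`, default 1.5 s) and thresholded (default 1.5 uV^2 on the
#' smoothed absolute energy).  Bursts shorter than `min_sat_s` are
#' removed, gaps shorter than `min_gap_s` merged, and interior interburst
#' intervals shorter than `min_ibi_s` absorbed.  The complementary
#' intervals are the IBIs.
#'
#' @param x one channel of a band-pass filtered recording (microvolts).
#' @param fs sampling rate in Hz.
#' @param config configuration list; the `sat` block holds the detector
#'   constants.
#' @param ground_truth optional logical mask of the true burst state
#'   (synthetic data), carried through for validation.
#' @return object of class `sat_annotation`: list with `mask` (logical per
#'   sample), `sat_events`, `ibi_events` (data.frames of start/end
#'   seconds), `fs`, and optionally `ground_truth`.
#' @export
detect_sats <- function(x, fs, config = neomat_config(), ground_truth = NULL) {
  p <- config$sat
  if (length(x) < p$smooth_s * fs)
    stop("record shorter than the NLEO smoothing window")
  energy <- moving_average(abs(nleo(x)), round(p$smooth_s * fs))
  mask <- energy > p$threshold
  mask <- clean_mask(mask, fs, p$min_sat_s, p$min_gap_s, p$min_ibi_s)
  structure(list(mask = mask,
                 sat_events = mask_to_intervals(mask, fs),
                 ibi_events = mask_to_intervals(!mask, fs),
                 fs = fs, ground_truth = ground_truth),
            class = "sat_annotation")
}

#' @export
print.sat_annotation <- function(x, ...) {
  cat(sprintf("<sat_annotation> %d SAT events, %d IBIs, SAT%% = %.1f over %.1f s\n",
              nrow(x$sat_events), nrow(x$ibi_events),
              100 * mean(x$mask), length(x$mask) / x$fs))
  invisible(x)
}

#' Continuity features from a SAT annotation
#'
#' SAT percentage over the whole record, the mean SAT percentage over
#' complete non-overlapping 5-min windows, and the median IBI duration.
#' IBIs truncated by the record boundaries are excluded from the median;
#' a fully continuous record reports `ibi_median_s = 0` with
#' `ibi_flag = "no_complete_ibi"`.
#'
#' @param ann a `sat_annotation`.
#' @param config configuration list.
#' @return named list with `sat_pct_total`, `sat_pct_5min_mean`,
#'   `ibi_median_s` (percentages on the 0--100 scale) and `ibi_flag`.
#' @export
continuity_features <- function(ann, config = neomat_config()) {
  fs <- ann$fs
  n <- length(ann$mask)
  w <- round(config$sat$window_5min_s * fs)
  sat_pct_total <- 100 * mean(ann$mask)
  k <- n %/% w
  sat5 <- if (k >= 1) {
    mean(vapply(seq_len(k), function(i)
      100 * mean(ann$mask[((i - 1L) * w + 1L):(i * w)]), 0))
  } else NA_real_
  ibi <- ann$ibi_events
  # drop boundary-truncated IBIs
  complete <- ibi[ibi$start_s > 0 & ibi$end_s < n / fs, , drop = FALSE]
  if (nrow(complete) == 0) {
    ibi_median <- 0
    flag <- "no_complete_ibi"
  } else {
    ibi_median <- median(complete$end_s - complete$start_s)
    flag <- "ok"
  }
  list(sat_pct_total = sat_pct_total, sat_pct_5min_mean = sat5,
       ibi_median_s = ibi_median, ibi_flag = flag)
}

#' Dice overlap, sensitivity and specificity of a detected burst mask
#'
#' Compares the detected per-sample mask against a ground-truth mask
#' (synthetic recordings carry one).
#'
#' @param detected,truth logical vectors of equal length.
#' @return named numeric vector `dice`, `sensitivity`, `specificity`.
#' @export
mask_agreement <- function(detected, truth) {
  stopifnot(length(detected) == length(truth))
  tp <- sum(detected & truth)
  fp <- sum(detected & !truth)
  fn <- sum(!detected & truth)
  tn <- sum(!detected & !truth)
  c(dice = 2 * tp / (2 * tp + fp + fn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp))
}
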