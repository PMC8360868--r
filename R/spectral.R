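# Welch spectra and the six spectral features (four relative band powers,
# SEF75, SEF90) computed per 25-s segment.

#' Welch power spectral density of one segment
#'
#' Averaged modified periodograms: Hann sub-windows of `welch_sub_s`
#' seconds (default 4 s, ~0.25 Hz resolution) with 50% overlap inside the
#' segment.  One-sided density scaled so that the integral over frequency
#' equals the signal variance (Parseval).
#'
#' @param x numeric vector, one channel of one segment, microvolts.
#' @param fs sampling rate in Hz.
#' @param config configuration list.
#' @return object of class `psd_estimate`: list with `freq` (Hz) and
#'   `power` (uV^2/Hz).
#' @export
welch_psd <- function(x, fs, config = neomat_config()) {
  nwin <- round(config$spectral$welch_sub_s * fs)
  step <- max(1L, round(nwin * (1 - config$spectral$welch_overlap)))
  if (length(x) < nwin) stop("segment shorter than one Welch sub-window")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / nwin)   # periodic Hann
  u <- sum(w^2)
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  nf <- nwin %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)]
    seg <- seg - mean(seg)
    X <- fft(seg * w)[seq_len(nf)]
    acc <- acc + (Mod(X)^2) / (fs * u)
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even nwin)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nwin %% 2L == 0L) dbl[nf] <- 1
  structure(list(freq = (seq_len(nf) - 1L) * fs / nwin, power = p * dbl),
            class = "psd_estimate")
}

# Integral of the PSD over [lo, hi) by bin sums (each bin of width df
# covers [f, f + df)), with half-open edges so shared band boundaries are
# counted exactly once.
psd_band_power <- function(psd, lo, hi) {
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= lo & psd$freq < hi
  sum(psd$power[sel]) * df
}

#' Relative band powers from a PSD
#'
#' Fractions of total power in the delta (2--4 Hz), theta (4--8 Hz), alpha
#' (8--12 Hz), and beta (12--30 Hz) bands, each relative to the 2--30 Hz
#' reference band (the union of the four bands; content below 2 Hz is
#' removed by the high-pass filter and 30--40 Hz belongs to no band).
#'
#' @param psd a `psd_estimate`.
#' @param config configuration list.
#' @return named numeric vector `rel_delta`, `rel_theta`, `rel_alpha`,
#'   `rel_beta`, summing to one.
#' @export
band_powers <- function(psd, config = neomat_config()) {
  e <- config$spectral$band_edges
  ref <- config$spectral$ref_band
  tot <- psd_band_power(psd, ref[1], ref[2])
  if (tot <= 0) stop("zero total power in reference band; spectral features undefined")
  p <- vapply(seq_len(length(e) - 1L),
              function(i) psd_band_power(psd, e[i], e[i + 1L]), 0)
  setNames(p / tot, c("rel_delta", "rel_theta", "rel_alpha", "rel_beta"))
}

#' Spectral edge frequency
#'
#' Smallest frequency below which `edge` of the reference-band (2--30 Hz)
#' power lies, linearly interpolated inside the crossing bin.
#'
#' @param psd a `psd_estimate`.
#' @param edge cumulative power fraction in (0, 1), e.g. 0.75 or 0.9.
#' @param config configuration list.
#' @return frequency in Hz.
#' @export
spectral_edge <- function(psd, edge, config = neomat_config()) {
  stopifnot(edge > 0, edge < 1)
  ref <- config$spectral$ref_band
  df <- psd$freq[2] - psd$freq[1]
  sel <- which(psd$freq >= ref[1] & psd$freq < ref[2])
  p <- psd$power[sel] * df
  tot <- sum(p)
  if (tot <= 0) stop("zero total power in reference band; SEF undefined")
  target <- edge * tot
  cum <- cumsum(p)
  i <- which(cum >= target)[1]
  f0 <- psd$freq[sel[i]]
  prev <- if (i == 1) 0 else cum[i - 1]
  f0 + df * (target - prev) / p[i]
}

#' All six spectral features of one segment
#'
#' @param x segment samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param config configuration list.
#' @return named numeric vector with the four relative band powers and
#'   `sef75`, `sef90`.
#' @export
spectral_features <- function(x, fs, config = neomat_config()) {
  psd <- welch_psd(x, fs, config)
  c(band_powers(psd, config),
    sef75 = spectral_edge(psd, 0.75, config),
    sef90 = spectral_edge(psd, 0.90, config))
}
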