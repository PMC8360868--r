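#' Band-limited coloured noise
#'
#' Gaussian noise synthesised in the frequency domain with power spectral
#' density proportional to \eqn{1/f^\alpha} inside `band` and zero outside.
#' Used by the waveform simulator (preterm EEG background has a steep
#' low-frequency-dominated spectrum) and by test fixtures.
#'
#' @param n number of samples.
#' @param fs sampling rate in Hz.
#' @param alpha spectral tilt exponent (0 = white, 1 = pink, 2 = brown).
#' @param band length-2 Hz interval retained; `NULL` keeps the full band.
#' @param rms target root-mean-square amplitude of the output.
#' @return numeric vector of length `n`, zero mean, RMS equal to `rms`.
#' @export
colored_noise <- function(n, fs, alpha = 0, band = NULL, rms = 1) {
  nf <- n %/% 2L
  f <- seq_len(nf) * fs / n
  amp <- f^(-alpha / 2)
  if (!is.null(band)) amp[f < band[1] | f > band[2]] <- 0
  # Hermitian spectrum with random Gaussian real/imag parts
  re <- rnorm(nf) * amp
  im <- rnorm(nf) * amp
  spec <- complex(real = re, imaginary = im)
  full <- complex(length.out = n)
  full[2:(nf + 1L)] <- spec
  if (n %% 2L == 0L) {
    full[nf + 1L] <- complex(real = re[nf], imaginary = 0)
    full[(nf + 2L):n] <- Conj(spec[(nf - 1L):1L])
  } else {
    full[(nf + 2L):n] <- Conj(spec[nf:1L])
  }
  x <- Re(fft(full, inverse = TRUE)) / n
  s <- sqrt(mean(x^2))
  if (s > 0) x <- x * (rms / s)
  x
}

# Centered moving average with edge shrinkage (window truncated at the
# record boundaries so no samples are lost).
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- width %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (width - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Convert a logical mask to a data.frame of (start_s, end_s) intervals for
# runs of TRUE.  end_s is exclusive; sample i covers [i-1, i)/fs seconds.
mask_to_intervals <- function(mask, fs) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start_s = starts[keep] / fs, end_s = ends[keep] / fs)
}

intervals_to_mask <- function(intervals, n, fs) {
  mask <- logical(n)
  if (nrow(intervals) == 0) return(mask)
  for (i in seq_len(nrow(intervals))) {
    a <- max(1L, floor(intervals$start_s[i] * fs) + 1L)
    b <- min(n, ceiling(intervals$end_s[i] * fs))
    if (b >= a) mask[a:b] <- TRUE
  }
  mask
}

# Trapezoidal quadrature on an arbitrary grid.
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
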