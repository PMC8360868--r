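# Multiscale entropy per 100-s segment and the complexity features
# (complexity index, small-scale slope, curve maximum).

#' Coarse-grain a series at scale tau
#'
#' Non-overlapping means of `tau` consecutive samples; the trailing
#' remainder is dropped, so the output has `floor(n/tau)` samples.
#'
#' @param x numeric vector.
#' @param tau positive integer scale.
#' @export
coarse_grain <- function(x, tau) {
  tau <- as.integer(tau)
  stopifnot(tau >= 1, length(x) >= tau)
  if (tau == 1L) return(x)
  k <- length(x) %/% tau
  colMeans(matrix(x[seq_len(k * tau)], nrow = tau))
}

#' Sample entropy
#'
#' \eqn{-\ln(A/B)} where B counts template pairs of length `m` within
#' Chebyshev distance `r` (strict inequality, self-matches excluded, both
#' counts over the first `n - m` templates) and A counts the same for
#' length `m + 1`.  Returns `NA` with a `reason` attribute when either
#' count is zero or `r` is not positive (degenerate input), so the caller
#' can exclude the segment instead of imputing.
#'
#' @param x numeric vector.
#' @param m template length (default 2).
#' @param r tolerance in the units of `x` (absolute, not a fraction of SD).
#' @return entropy in nats, or flagged `NA`.
#' @export
sample_entropy <- function(x, m = 2, r) {
  if (r <= 0)
    return(structure(NA_real_, reason = "nonpositive tolerance"))
  if (length(x) <= m + 1)
    return(structure(NA_real_, reason = "series too short"))
  cnt <- sampen_counts_cpp(as.numeric(x), as.integer(m), as.numeric(r))
  if (cnt[["B"]] == 0) return(structure(NA_real_, reason = "no m-matches"))
  if (cnt[["A"]] == 0) return(structure(NA_real_, reason = "no (m+1)-matches"))
  -log(cnt[["A"]] / cnt[["B"]])
}

#' Multiscale entropy curve of one segment
#'
#' Sample entropy of the coarse-grained series for scales 1..20, with
#' `m = 2` and tolerance `r = r_factor x SD` of the original (scale-1)
#' segment, held fixed across scales (the standard multiscale-entropy
#' convention).  `r` is computed per segment and per channel because the
#' amplitude of preterm EEG is strongly nonstationary across an hour.
#'
#' @param x segment samples (nominally 100 s).
#' @param config configuration list (`complexity` block: `m`, `r_factor`,
#'   `scales_max`).
#' @return object of class `mse_curve`: list with `scales`, `sampen`,
#'   `params`, and `flag` (`"ok"` or the first undefined-scale reason).
#' @export
mse_curve <- function(x, config = neomat_config()) {
  p <- config$complexity
  s <- sd(x)
  scales <- seq_len(p$scales_max)
  if (!is.finite(s) || s == 0) {
    return(structure(list(scales = scales,
                          sampen = rep(NA_real_, length(scales)),
                          params = p, flag = "degenerate (zero SD)"),
                     class = "mse_curve"))
  }
  r <- p$r_factor * s
  se <- vapply(scales, function(tau)
    as.numeric(sample_entropy(coarse_grain(x, tau), p$m, r)), 0)
  flag <- if (anyNA(se)) "undefined at some scale" else "ok"
  structure(list(scales = scales, sampen = se, params = p, flag = flag),
            class = "mse_curve")
}

#' @export
print.mse_curve <- function(x, ...) {
  cat(sprintf("<mse_curve> scales 1..%d, max %.3f nats [%s]\n",
              max(x$scales), suppressWarnings(max(x$sampen, na.rm = TRUE)),
              x$flag))
  invisible(x)
}

#' Complexity features from a multiscale entropy curve
#'
#' Complexity index = trapezoidal area under the curve over scales 1..20;
#' small-scale slope = ordinary least-squares slope over scales 1..5;
#' curve maximum.  A flagged (partially undefined) curve yields `NA`s.
#'
#' @param curve an `mse_curve`.
#' @param config configuration list.
#' @return named numeric vector `complexity_index`, `slope_small`,
#'   `mse_max`.
#' @export
complexity_features <- function(curve, config = neomat_config()) {
  if (curve$flag != "ok")
    return(c(complexity_index = NA_real_, slope_small = NA_real_,
             mse_max = NA_real_))
  rng <- config$complexity$small_scale_range
  small <- curve$scales >= rng[1] & curve$scales <= rng[2]
  slope <- coef(lm(curve$sampen[small] ~ curve$scales[small]))[[2]]
  c(complexity_index = trapz(curve$scales, curve$sampen),
    slope_small = slope,
    mse_max = max(curve$sampen))
}
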