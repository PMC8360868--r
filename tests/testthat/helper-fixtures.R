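# Shared fixtures, built in code at test time.

FS <- 256

sinusoid <- function(f, dur_s, fs = FS, amp = 1, phase = 0) {
  amp * sin(2 * pi * f * seq_len(round(dur_s * fs)) / fs + phase)
}

rms <- function(x) sqrt(mean(x^2))

# O(N^2) brute-force sample-entropy pair counts (vectorised; the
# independent oracle for the compiled kernel).  Same convention: both
# counts over the first n - m templates, Chebyshev distance, strict
# inequality, unordered pairs, no self-matches.
sampen_counts_brute <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  d <- abs(outer(x[1:nt], x[1:nt], "-"))
  match_m <- d < r
  for (k in 1:(m - 1)) {
    dk <- abs(outer(x[(1 + k):(nt + k)], x[(1 + k):(nt + k)], "-"))
    match_m <- match_m & (dk < r)
  }
  dm <- abs(outer(x[(1 + m):(nt + m)], x[(1 + m):(nt + m)], "-"))
  match_m1 <- match_m & (dm < r)
  c(A = (sum(match_m1) - nt) / 2, B = (sum(match_m) - nt) / 2)
}

# Small tier-A cohort for statistics tests (faster than the full design).
small_cohort <- function(seed = 1, n_subjects = 20) {
  simulate_feature_cohort(cohort_design(n_subjects), lme_params(), seed)
}
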