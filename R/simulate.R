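# Two-tier synthetic preterm cohort generator.
#
# Tier A draws per-recording feature values directly from the fitted
# mixed-effects brain-age model (random intercept and slope per subject),
# giving exact statistical ground truth for parameter-recovery checks.
# Tier B synthesises trace-discontinu EEG waveforms -- high-amplitude SAT
# bursts separated by low-amplitude interburst intervals, with the burst
# fraction rising and the IBI shrinking as PMA increases -- with a
# per-sample ground-truth burst mask, validating the signal-processing
# chain by construction.

#' Cohort design: sizes and ranges of the simulated study
#'
#' Defaults emulate the study conditions: 52 neonates contributing about
#' 115 usable recordings, GA at birth 24.71--27.86 weeks, recordings at
#' birth and then weekly, PMA at recording 24.71--31.86 weeks, morphine
#' given to 26/43 infants.  Retention probabilities per serial time point
#' reproduce the observed counts (46, 26, 17, 16, 9, 1 recordings at weeks
#' 0..5).
#'
#' @param n_subjects number of neonates.
#' @return list of design parameters.
#' @export
cohort_design <- function(n_subjects = 52) {
  list(n_subjects = n_subjects,
       ga_range = c(24.71, 27.86),
       pma_max = 31.86,
       p_retain = c(46, 26, 17, 16, 9, 1) / 52,   # weeks 0..5 after birth
       morphine_prob = 26 / 43,
       pma_center = 28)
}

#' Mixed-model parameters per feature (tier A)
#'
#' Fixed slope `b` per week of PMA and marginal feature--PMA correlation
#' `rho` for each of the twelve features, with the fixed intercept anchored
#' by a plausible feature value at 28 weeks.  Random-effect spread defaults
#' to 10% of the fixed-effect excursion over the ~7-week PMA range for the
#' intercept and 25% of the fixed slope for the slope; the residual SD is
#' then solved so that the marginal correlation with PMA matches `rho`.
#' SAT percentages are simulated on the 0--1 fraction scale, on which a
#' slope of 0.08/week gives a plausible excursion across 24--32 weeks.
#'
#' @return data.frame, one row per feature, with columns `feature`, `rho`,
#'   `b`, `a`, `sd_u0`, `sd_u1`, `sd_e`.
#' @export
lme_params <- function() {
  p <- data.frame(
    feature = feature_names(),
    rho = c(-0.12, -0.02, 0.15, 0.19, 0.13, 0.26,
            0.52, 0.51, -0.29, 0.73, 0.70, 0.72),
    b = c(-3.29, -2.60, 13.57, 13.17, 0.29, 0.34,
          0.08, 0.08, -0.24, 0.28, 35.43, 4.52),
    v28 = c(0.55, 0.22, 0.12, 0.11, 8, 14,
            0.35, 0.35, 8, 30, 0.05, 1.8)
  )
  var_pma <- 3.2   # design variance of PMA across the simulated cohort
  p$a <- p$v28 - 28 * p$b
  p$sd_u0 <- 0.10 * abs(p$b) * 7
  p$sd_u1 <- 0.25 * abs(p$b)
  noise_var <- p$b^2 * var_pma * (1 / p$rho^2 - 1)
  p$sd_e <- sqrt(pmax(noise_var - p$sd_u0^2 - p$sd_u1^2 * var_pma,
                      (0.2 * p$b)^2))
  p$v28 <- NULL
  p
}

simulate_schedule <- function(design) {
  n <- design$n_subjects
  ga <- runif(n, design$ga_range[1], design$ga_range[2])
  morphine <- rbinom(n, 1, design$morphine_prob) == 1
  rows <- lapply(seq_len(n), function(i) {
    keep <- runif(6) < design$p_retain
    if (!any(keep)) keep[1] <- TRUE
    wk <- which(keep) - 1L
    pma <- ga[i] + wk
    wk <- wk[pma <= design$pma_max]
    pma <- pma[pma <= design$pma_max]
    if (length(wk) == 0) { wk <- 0L; pma <- ga[i] }
    data.frame(subject_id = sprintf("S%02d", i),
               recording_id = sprintf("S%02d_R%d", i, wk),
               epoch_index = wk, ga_weeks = ga[i], morphine = morphine[i],
               pma_weeks = pma)
  })
  do.call(rbind, rows)
}

#' Simulate a feature-space cohort from the mixed model (tier A)
#'
#' For each feature, \eqn{y_{ij} = a + b \cdot PMA_{ij} + u_{0i} +
#' u_{1i}(PMA_{ij} - 28) + \epsilon_{ij}} with independent Gaussian
#' subject-level random intercepts/slopes and residuals.  The generating
#' parameters and realised random effects are stored in the `"truth"`
#' attribute.
#'
#' @param design from [cohort_design()].
#' @param params from [lme_params()]; rows can be edited (e.g. set SDs to
#'   zero for a noiseless cohort or `b = 0` for a null simulation).
#' @param seed integer RNG seed; same seed, same cohort.
#' @return cohort data.frame (metadata plus one column per feature) with a
#'   `"truth"` attribute.
#' @export
simulate_feature_cohort <- function(design = cohort_design(),
                                    params = lme_params(), seed = 1) {
  set.seed(seed)
  sched <- simulate_schedule(design)
  n <- design$n_subjects
  subj <- match(sched$subject_id, unique(sched$subject_id))
  ranef <- list()
  for (k in seq_len(nrow(params))) {
    pr <- params[k, ]
    u0 <- rnorm(n, 0, pr$sd_u0)
    u1 <- rnorm(n, 0, pr$sd_u1)
    e <- rnorm(nrow(sched), 0, pr$sd_e)
    sched[[pr$feature]] <- pr$a + pr$b * sched$pma_weeks +
      u0[subj] + u1[subj] * (sched$pma_weeks - design$pma_center) + e
    ranef[[pr$feature]] <- data.frame(subject_id = unique(sched$subject_id),
                                      u0 = u0, u1 = u1)
  }
  attr(sched, "truth") <- list(design = design, params = params,
                               ranef = ranef, seed = seed)
  sched
}

#' Waveform-generator parameters (tier B)
#'
#' PMA-dependent trace-discontinu model:
#' \itemize{
#'   \item burst fraction `clamp(0.35 + 0.08 (PMA - 28), 0.05, 0.95)`;
#'   \item median IBI duration shrinking from ~40 s at 24 weeks towards a
#'     3-s floor (the deep discontinuity of the most immature tracings
#'     resolving with maturation); burst durations follow from the
#'     fraction; both lognormal;
#'   \item burst amplitude decaying exponentially from ~50 uV RMS at 24
#'     weeks towards a ~6 uV asymptote (immature SATs are very high
#'     amplitude), over a deeply suppressed 2--2.5 uV RMS interburst floor
#'     that rises slightly with maturation (discontinuity becomes
#'     shallower);
#'   \item waveform content a mixture of a stereotyped narrowband slow
#'     (2--4 Hz) component and a broadband fast (4--30 Hz, 1/f) component
#'     whose weight grows with PMA -- the delta-brush-like fast activity
#'     that appears during maturation and drives the rise in signal
#'     complexity;
#'   \item 0.8-s raised-cosine envelope ramps (SAT onsets and decays are
#'     gradual, not square).
#' }
#'
#' @return list of parameters/functions consumed by [simulate_eeg()].
#' @export
wave_params <- function() {
  list(
    burst_fraction = function(pma) pmin(pmax(0.35 + 0.08 * (pma - 28), 0.05), 0.95),
    ibi_median_s = function(pma) pmax(3, 40 - 4 * (pma - 24)),
    dur_sdlog = 0.35,
    min_burst_s = 1.2, min_ibi_s = 1.5,
    burst_rms_uv = function(pma) 44 * exp(-0.35 * (pma - 24)) + 6,
    burst_rms_sdlog = 0.25,
    ibi_rms_uv = function(pma) pmin(2.5, pmax(2, 2 + 0.33 * (pma - 28))),
    fast_weight = function(pma) pmin(pmax(0.1 + 0.12 * (pma - 24), 0.05), 0.9),
    floor_fast_weight_max = 0.4,   # interburst periods stay slow-dominated
    slow_band = c(2, 4), fast_band = c(4, 30), fast_alpha = 1,
    ramp_s = 0.8,
    n_channels = 2L, fs_hz = 256
  )
}

#' Simulate a trace-discontinu EEG recording (tier B)
#'
#' Alternating burst/IBI renewal process shared across the two channels,
#' with independent noise realisations per channel and a per-sample
#' ground-truth burst mask.
#'
#' @param pma postmenstrual age in weeks (24--40).
#' @param duration_s record duration in seconds (>= 10).
#' @param params from [wave_params()].
#' @param seed integer RNG seed.
#' @param metadata optional list merged into the recording metadata
#'   (`subject_id`, `recording_id`, `ga_weeks`, `morphine`,
#'   `epoch_index`).
#' @return list with `rec` (an [eeg_recording()]), `truth_mask` (logical
#'   per sample), and `events` (true burst intervals).
#' @export
simulate_eeg <- function(pma, duration_s, params = wave_params(), seed = 1,
                         metadata = list()) {
  stopifnot(pma >= 24, pma <= 40)
  if (duration_s < 10) stop("duration_s must be at least 10 s")
  set.seed(seed)
  fs <- params$fs_hz
  n <- round(duration_s * fs)
  frac <- params$burst_fraction(pma)
  ibi_med <- params$ibi_median_s(pma)
  burst_med <- frac / (1 - frac) * ibi_med
  burst_rms <- params$burst_rms_uv(pma)
  floor_rms <- params$ibi_rms_uv(pma)
  wf <- params$fast_weight(pma)

  # renewal sequence of alternating IBI / burst intervals
  t <- runif(1, 0, ibi_med)   # random phase: start inside an IBI
  bursts <- NULL
  while (t < duration_s) {
    bd <- max(params$min_burst_s, rlnorm(1, log(burst_med), params$dur_sdlog))
    bursts <- rbind(bursts, data.frame(start_s = t, end_s = min(t + bd, duration_s)))
    t <- t + bd + max(params$min_ibi_s,
                      rlnorm(1, log(ibi_med), params$dur_sdlog))
  }
  mask <- intervals_to_mask(bursts, n, fs)

  # amplitude envelope: interburst floor, raised-cosine shoulders
  env <- rep(floor_rms, n)
  ramp_n <- round(params$ramp_s * fs)
  for (i in seq_len(nrow(bursts))) {
    a <- floor(bursts$start_s[i] * fs) + 1L
    b <- min(n, ceiling(bursts$end_s[i] * fs))
    rms_b <- rlnorm(1, log(burst_rms), params$burst_rms_sdlog)
    len <- b - a + 1L
    shape <- rep(1, len)
    k <- min(ramp_n, len %/% 2L)
    if (k > 0) {
      up <- (1 - cos(pi * seq_len(k) / k)) / 2
      shape[seq_len(k)] <- up
      shape[len - k + seq_len(k)] <- rev(up)
    }
    env[a:b] <- pmax(env[a:b], floor_rms + (rms_b - floor_rms) * shape)
  }

  # Waveform content: stereotyped narrowband slow component plus a
  # maturation-weighted broadband fast component (independent noise per
  # channel).  Burst activity rides on top of a continuous low-amplitude
  # background whose fast weight is capped -- interburst periods stay
  # slow-dominated at every age.
  unit_mix <- function(w) {
    slow <- colored_noise(n, fs, alpha = 0, band = params$slow_band, rms = 1)
    fast <- colored_noise(n, fs, alpha = params$fast_alpha,
                          band = params$fast_band, rms = 1)
    y <- sqrt(1 - w^2) * slow + w * fast
    y / sqrt(mean(y^2))
  }
  wf_floor <- min(wf, params$floor_fast_weight_max)
  data <- vapply(seq_len(params$n_channels), function(ch) {
    unit_mix(wf_floor) * floor_rms +
      unit_mix(wf) * (env - floor_rms)
  }, numeric(n))
  md <- metadata
  rec <- eeg_recording(data, fs_hz = fs,
                       channels = c("F3-P3", "F4-P4")[seq_len(params$n_channels)],
                       subject_id = md$subject_id %||% "SYN",
                       recording_id = md$recording_id %||% sprintf("SYN_pma%.1f", pma),
                       pma_weeks = pma,
                       ga_weeks = md$ga_weeks %||% min(pma, 27.9),
                       morphine = md$morphine %||% FALSE,
                       epoch_index = md$epoch_index %||% 0L)
  list(rec = rec, truth_mask = mask, events = bursts)
}

#' MRI coupling parameters (tier B/A)
#'
#' Each row defines one simulated MRI metric as a linear function of one
#' early-EEG feature plus GA and morphine covariates and Gaussian noise.
#' The default row couples mid-sagittal cerebellar width at term to the
#' SAT percentage with coefficient 0.13 (width units per unit SAT%); the
#' noise SD is chosen so the partial correlation of the coupled pair is
#' ~0.55, matching the strength of the strongest reported EEG--MRI
#' couplings, with mild GA and morphine covariate effects.
#'
#' @return data.frame of coupling rows.
#' @export
mri_coupling <- function() {
  data.frame(metric = "cerebellar_width_midsag", scan = "40w",
             eeg_feature = "sat_pct_total",
             intercept = 25, b_feat = 0.13, b_ga = 0.1, b_morphine = -0.1,
             sd_e = 0.06)
}

#' Simulate MRI metrics linearly coupled to early-EEG features
#'
#' Uses each subject's first recording (lowest `epoch_index`) as the early
#' EEG.  One output row per subject per scan; generating parameters are
#' stored in the `"truth"` attribute.
#'
#' @param cohort cohort table containing the coupled EEG features plus
#'   `ga_weeks` and `morphine`.
#' @param coupling from [mri_coupling()].
#' @param seed integer RNG seed.
#' @return MRI table: `subject_id`, `scan`, `pma_at_scan`, one column per
#'   metric.
#' @export
simulate_mri <- function(cohort, coupling = mri_coupling(), seed = 1) {
  set.seed(seed)
  first <- do.call(rbind, lapply(split(cohort, cohort$subject_id),
                                 function(d) d[which.min(d$epoch_index), ]))
  out <- NULL
  for (k in seq_len(nrow(coupling))) {
    cp <- coupling[k, ]
    scan_pma <- if (cp$scan == "30w") 30 else 40
    y <- cp$intercept + cp$b_feat * first[[cp$eeg_feature]] +
      cp$b_ga * first$ga_weeks + cp$b_morphine * as.numeric(first$morphine) +
      rnorm(nrow(first), 0, cp$sd_e)
    tab <- data.frame(subject_id = first$subject_id, scan = cp$scan,
                      pma_at_scan = scan_pma + runif(nrow(first), -0.5, 0.5))
    tab[[cp$metric]] <- y
    out <- if (is.null(out)) tab else merge(out, tab, all = TRUE)
  }
  rownames(out) <- NULL
  attr(out, "truth") <- list(coupling = coupling, seed = seed)
  out
}

#' Simulate a tier-B cohort of recordings and extract their features
#'
#' Generates `n_recordings` trace-discontinu recordings with PMA spread
#' evenly over `pma_range`, runs the full extraction pipeline on each, and
#' returns the cohort feature table (with the generated PMA as truth).
#'
#' @param n_recordings number of recordings.
#' @param duration_s duration of each recording in seconds.
#' @param pma_range PMA range covered, weeks.
#' @param seed integer RNG seed.
#' @param config configuration list.
#' @return cohort feature table from [extract_recording_features()].
#' @export
simulate_tierb_cohort <- function(n_recordings = 12, duration_s = 300,
                                  pma_range = c(25, 31.5), seed = 1,
                                  config = neomat_config()) {
  pma <- seq(pma_range[1], pma_range[2], length.out = n_recordings)
  rows <- lapply(seq_len(n_recordings), function(i) {
    sim <- simulate_eeg(pma[i], duration_s,
                        seed = as.integer((seed * 1000 + i) %% 2147483647),
                        metadata = list(subject_id = sprintf("B%02d", i),
                                        recording_id = sprintf("B%02d_R0", i)))
    extract_recording_features(sim$rec, config)
  })
  do.call(rbind, rows)
}
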