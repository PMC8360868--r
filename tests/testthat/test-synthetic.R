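test_that("tier-A cohort reproduces the study design", {
  cohort <- simulate_feature_cohort(seed = 5)
  expect_equal(length(unique(cohort$subject_id)), 52)
  expect_gt(nrow(cohort), 90)
  expect_lt(nrow(cohort), 140)
  expect_true(all(cohort$pma_weeks >= cohort$ga_weeks))
  expect_true(all(cohort$pma_weeks <= 31.86))
  expect_true(all(cohort$ga_weeks >= 24.71 & cohort$ga_weeks <= 27.86))
  # PMA strictly increasing within subject
  ok <- vapply(split(cohort$pma_weeks, cohort$subject_id),
               function(p) all(diff(p) > 0), TRUE)
  expect_true(all(ok))
  expect_true(all(feature_names() %in% names(cohort)))
})

test_that("same seed gives identical cohorts, different seeds differ", {
  a <- simulate_feature_cohort(seed = 3)
  b <- simulate_feature_cohort(seed = 3)
  attr(a, "truth") <- attr(b, "truth") <- NULL
  expect_identical(a, b)
  c <- simulate_feature_cohort(seed = 4)
  expect_false(isTRUE(all.equal(a$complexity_index,
                                c$complexity_index[seq_len(nrow(a))])))
})

test_that("zero-SD cohorts lie exactly on the generating line", {
  params <- lme_params()
  params$sd_u0 <- params$sd_u1 <- params$sd_e <- 0
  cohort <- simulate_feature_cohort(params = params, seed = 2)
  pr <- params[params$feature == "complexity_index", ]
  expect_equal(cohort$complexity_index, pr$a + pr$b * cohort$pma_weeks,
               tolerance = 1e-12)
})

test_that("tier-B burst fraction is monotone in PMA and reproducible", {
  p <- wave_params()
  expect_gt(p$burst_fraction(31), p$burst_fraction(25))
  s1 <- simulate_eeg(27, 60, seed = 8)
  s2 <- simulate_eeg(27, 60, seed = 8)
  expect_identical(s1$rec$data, s2$rec$data)
  expect_identical(s1$truth_mask, s2$truth_mask)
  # generated burst fraction rises with PMA under a seed schedule
  frac <- vapply(c(25, 28, 31), function(pma)
    mean(simulate_eeg(pma, 300, seed = 21)$truth_mask), 0)
  expect_true(all(diff(frac) > 0))
  expect_error(simulate_eeg(28, 5), "at least 10")
})

test_that("equal burst and interburst amplitude saturates the detector", {
  cfg <- neomat_config()
  p <- wave_params()
  p$burst_rms_uv <- function(pma) 15
  p$ibi_rms_uv <- function(pma) 15
  p$floor_fast_weight_max <- 1     # identical content everywhere
  sim <- simulate_eeg(28, 120, params = p, seed = 31)
  filt <- bandpass_notch(sim$rec, cfg)
  ann <- detect_sats(filt$data[, 1], FS, cfg)
  expect_gte(continuity_features(ann, cfg)$sat_pct_total, 95)
})

test_that("noiseless MRI coupling gives perfect partial correlation", {
  cohort <- small_cohort(seed = 6)
  cp <- mri_coupling()
  cp$sd_e <- 0
  cp$b_ga <- 0
  cp$b_morphine <- 0
  mri <- simulate_mri(cohort, cp, seed = 1)
  first <- do.call(rbind, lapply(split(cohort, cohort$subject_id),
                                 function(d) d[which.min(d$epoch_index), ]))
  j <- merge(first, mri, by = "subject_id")
  pc <- partial_correlation(j$sat_pct_total, j$cerebellar_width_midsag,
                            data.frame(ga = j$ga_weeks,
                                       mo = as.numeric(j$morphine)))
  expect_equal(pc$rho, 1, tolerance = 1e-9)
})
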