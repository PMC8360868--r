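test_that("NLEO matches closed forms", {
  expect_true(all(nleo(rep(3, 100)) == 0))
  expect_true(all(nleo(rep(0, 50)) == 0))
  # sinusoid: |psi| = (A^2/2)(cos w - cos 3w), constant after transient
  x <- sinusoid(4, 5, amp = 10)
  w <- 2 * pi * 4 / FS
  expected <- (10^2 / 2) * (cos(w) - cos(3 * w))
  expect_equal(expected, 1.912, tolerance = 1e-3)
  psi <- nleo(x)
  expect_equal(mean(abs(psi[1000:1200])), expected, tolerance = 1e-3)
  expect_error(nleo(c(1, 2, 3)), "at least 4")
})

test_that("detector handles degenerate and saturated inputs", {
  cfg <- neomat_config()
  z <- detect_sats(rep(0, 600 * FS), FS, cfg)
  expect_equal(nrow(z$sat_events), 0)
  expect_equal(nrow(z$ibi_events), 1)
  cf <- continuity_features(z, cfg)
  expect_equal(cf$sat_pct_total, 0)

  # continuous high-amplitude broadband activity: essentially all SAT
  set.seed(7)
  x <- colored_noise(600 * FS, FS, alpha = 1, band = c(2, 30), rms = 50)
  ann <- detect_sats(x, FS, cfg)
  cf <- continuity_features(ann, cfg)
  expect_gte(cf$sat_pct_total, 95)
  expect_error(detect_sats(rnorm(10), FS, cfg), "shorter than")
})

test_that("detector recovers tier-B ground truth masks", {
  cfg <- neomat_config()
  sim <- simulate_eeg(28, 300, seed = 42)
  filt <- bandpass_notch(sim$rec, cfg)
  ann <- detect_sats(filt$data[, 1], FS, cfg, ground_truth = sim$truth_mask)
  agr <- mask_agreement(ann$mask, sim$truth_mask)
  expect_gte(agr[["dice"]], 0.90)
  # events and mask are mutually consistent and tile the record
  tot <- sum(ann$sat_events$end_s - ann$sat_events$start_s) +
    sum(ann$ibi_events$end_s - ann$ibi_events$start_s)
  expect_equal(tot, length(ann$mask) / FS, tolerance = 1e-6)
  expect_equal(sum(ann$sat_events$end_s - ann$sat_events$start_s) * FS,
               sum(ann$mask), tolerance = 2 * nrow(ann$sat_events))
})

test_that("continuity features match constructed masks", {
  cfg <- neomat_config()
  # alternating 3-s SAT / 3-s IBI over 10 min
  mask <- rep(rep(c(TRUE, FALSE), each = 3 * FS), length.out = 600 * FS)
  ann <- structure(list(mask = mask,
                        sat_events = neomat:::mask_to_intervals(mask, FS),
                        ibi_events = neomat:::mask_to_intervals(!mask, FS),
                        fs = FS), class = "sat_annotation")
  cf <- continuity_features(ann, cfg)
  expect_equal(cf$sat_pct_total, 50)
  expect_equal(cf$sat_pct_5min_mean, 50)
  expect_equal(cf$ibi_median_s, 3.0)
  expect_equal(cf$ibi_flag, "ok")

  # all-burst record: flagged IBI median
  m2 <- rep(TRUE, 600 * FS)
  ann2 <- structure(list(mask = m2,
                         sat_events = neomat:::mask_to_intervals(m2, FS),
                         ibi_events = neomat:::mask_to_intervals(!m2, FS),
                         fs = FS), class = "sat_annotation")
  cf2 <- continuity_features(ann2, cfg)
  expect_equal(cf2$sat_pct_total, 100)
  expect_equal(cf2$ibi_median_s, 0)
  expect_equal(cf2$ibi_flag, "no_complete_ibi")
})

test_that("whole-record SAT% agrees with 5-min means on stationary input", {
  cfg <- neomat_config()
  sim <- simulate_eeg(29, 600, seed = 9)
  filt <- bandpass_notch(sim$rec, cfg)
  ann <- detect_sats(filt$data[, 1], FS, cfg)
  cf <- continuity_features(ann, cfg)
  expect_lt(abs(cf$sat_pct_total - cf$sat_pct_5min_mean), 2)
})
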