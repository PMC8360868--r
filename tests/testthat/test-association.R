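test_that("pearson matches exact cases", {
  x <- 1:20
  expect_equal(pearson(x, 2 * x + 1)$rho, 1)
  set.seed(14)
  y <- -x + rnorm(20, sd = 3)
  expect_lt(pearson(x, y)$rho, 0)
  expect_equal(pearson(x, rep(1, 20))$flag, "zero variance")
  set.seed(15)
  big <- pearson(rnorm(10000), rnorm(10000))
  expect_lt(abs(big$rho), 0.03)
})

test_that("partial correlation equals the residualization/recursive oracle", {
  set.seed(16)
  n <- 200
  z <- rnorm(n)
  x <- 0.6 * z + rnorm(n)
  y <- -0.4 * z + rnorm(n)
  pc <- partial_correlation(x, y, data.frame(z = z))
  # recursive three-variable closed form
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(pc$rho, oracle, tolerance = 1e-10)
  # invariant to affine rescaling of the control
  pc2 <- partial_correlation(x, y, data.frame(z = 100 * z - 3))
  expect_equal(pc2$rho, pc$rho, tolerance = 1e-10)
})

test_that("shared confounder is removed; unrelated controls change nothing", {
  set.seed(17)
  n <- 500
  g <- rnorm(n)
  x <- g + rnorm(n, sd = 0.3)
  y <- g + rnorm(n, sd = 0.3)
  expect_gt(cor(x, y), 0.8)
  pc <- partial_correlation(x, y, data.frame(g = g))
  expect_lt(abs(pc$rho), 0.1)
  w <- rnorm(n)   # unrelated control
  pc2 <- partial_correlation(x, y, data.frame(w = w))
  expect_equal(pc2$rho, cor(x, y), tolerance = 0.01)
  # constant control dropped with warning
  expect_warning(partial_correlation(x, y, data.frame(c = rep(1, n))),
                 "degenerate")
})

test_that("multiple regression recovers exact and noiseless cases", {
  set.seed(18)
  n <- 60
  covars <- data.frame(ga_weeks = runif(n, 25, 28),
                       morphine = rbinom(n, 1, 0.5))
  x <- rnorm(n)
  y <- 2 + 0.5 * x + 1.5 * covars$ga_weeks - 0.7 * covars$morphine
  mr <- suppressWarnings(multiple_regression(y, x, covars))
  expect_equal(mr$b, 0.5, tolerance = 1e-10)
  expect_equal(mr$r2, 1, tolerance = 1e-10)
  # rank deficiency named
  covars$morphine <- 0
  expect_error(multiple_regression(y, x, covars), "morphine")
})

test_that("trajectory slopes and growth per week are exact", {
  cohort <- data.frame(subject_id = c("a", "a", "b"),
                       pma_weeks = c(28, 30, 27),
                       f = c(10, 14, 5))
  sl <- trajectory_slopes(cohort, "f")
  expect_equal(nrow(sl), 1)            # single-recording subject dropped
  expect_equal(sl$slope, 2.0)
  expect_equal(sl$n_points, 2)

  expect_equal(growth_per_week(40, 50, 30, 40), 1.0)
  expect_equal(growth_per_week(7, 7, 30, 40), 0)
  expect_error(growth_per_week(1, 2, 30, 30), "strictly greater")
  set.seed(19)
  m1 <- runif(10); m2 <- runif(10); p1 <- runif(10, 29, 31); p2 <- p1 + runif(10, 8, 12)
  expect_equal(growth_per_week(m1, m2, p1, p2), (m2 - m1) / (p2 - p1))
})

test_that("PMA adjustment orthogonalizes volumes against scan age", {
  set.seed(20)
  n <- 30
  mri <- data.frame(subject_id = sprintf("s%d", 1:n), scan = "40w",
                    pma_at_scan = runif(n, 39, 43))
  mri$vol <- 100 + 5 * mri$pma_at_scan + rnorm(n, sd = 3)
  adj <- adjust_volumes_for_pma(mri, "vol")
  expect_lt(abs(cor(adj$vol, adj$pma_at_scan)), 1e-10)
  expect_equal(mean(adj$vol), mean(mri$vol), tolerance = 1e-10)
  # exactly linear volumes collapse to the group mean
  mri$vol <- 2 * mri$pma_at_scan
  adj2 <- adjust_volumes_for_pma(mri, "vol")
  expect_equal(adj2$vol, rep(mean(mri$vol), n), tolerance = 1e-10)
  # PMA-independent volumes unchanged up to noise-fit wiggle
  mri$vol <- rnorm(n, 50, 1)
  adj3 <- adjust_volumes_for_pma(mri, "vol")
  expect_equal(adj3$vol, mri$vol, tolerance = 0.5)
  expect_warning(adjust_volumes_for_pma(mri[1:2, ], "vol"), "fewer than 3")
})

test_that("zero-variance mixed model is OLS; ladder tracks it closely", {
  params <- lme_params()
  params$sd_u0 <- params$sd_u1 <- 0   # no subject-level structure
  cohort <- simulate_feature_cohort(cohort_design(30), params, seed = 21)
  ols <- lm(complexity_index ~ pma_weeks, data = cohort)
  forced <- fit_lme_pma(cohort, "complexity_index", model = "ols")
  expect_equal(forced$slope, coef(ols)[["pma_weeks"]], tolerance = 1e-12)
  expect_equal(forced$intercept, coef(ols)[[1]], tolerance = 1e-9)
  fit <- fit_lme_pma(cohort, "complexity_index")
  expect_equal(fit$slope, coef(ols)[["pma_weeks"]], tolerance = 2e-2)
  # noiseless data: slope recovered exactly whatever the ladder does
  params$sd_e <- 0
  noiseless <- simulate_feature_cohort(cohort_design(30), params, seed = 22)
  fit0 <- fit_lme_pma(noiseless, "complexity_index")
  expect_equal(fit0$slope, 0.28, tolerance = 1e-8)
  expect_equal(fit0$R2_marginal, 1, tolerance = 1e-8)
})

test_that("mixed model recovers generating parameters on tier-A data", {
  cohort <- simulate_feature_cohort(seed = 23)
  fit <- fit_lme_pma(cohort, "complexity_index")
  expect_equal(fit$model_type, "random_slope")
  expect_gt(fit$rho, 0.5)
  # generating slope inside the fitted CI (single draw)
  expect_gt(0.28, fit$ci[1])
  expect_lt(0.28, fit$ci[2])
  tab <- fit_maturation_table(cohort, c("complexity_index", "ibi_median_s"))
  expect_equal(sign(tab$b), c(1, -1))
  expect_true(all(tab$ci_lo < tab$b & tab$b < tab$ci_hi))
})

test_that("association suite flags the true coupling and respects modes", {
  cohort <- simulate_feature_cohort(seed = 24)
  mri <- simulate_mri(cohort, mri_coupling(), seed = 24)
  res <- run_association_suite(cohort, mri, mode = "early",
                               features = c("sat_pct_total", "rel_theta"))
  expect_true(all(c("rho_partial", "b", "p_b", "significant") %in% names(res)))
  true_row <- res[res$eeg_feature == "sat_pct_total", ]
  expect_true(true_row$significant)
  expect_gt(true_row$rho_partial, 0.3)
  # deterministic re-run
  res2 <- run_association_suite(cohort, mri, mode = "early",
                                features = c("sat_pct_total", "rel_theta"))
  expect_identical(res, res2)
  expect_warning(empty <- run_association_suite(cohort, data.frame()), "empty")
  expect_equal(nrow(empty), 0)
  slopes <- run_association_suite(cohort, mri, mode = "slopes",
                                  features = c("complexity_index"))
  expect_true(nrow(slopes) >= 1)
})

test_that("per-subject slope estimates track the generated random slopes", {
  cohort <- simulate_feature_cohort(seed = 25)
  truth <- attr(cohort, "truth")
  sl <- trajectory_slopes(cohort, "complexity_index")
  re <- truth$ranef$complexity_index
  j <- merge(sl, re, by = "subject_id")
  j$gen <- 0.28 + j$u1
  sd_e <- truth$params$sd_e[truth$params$feature == "complexity_index"]
  # slope SE from the subject's own PMA spread
  j$se <- vapply(j$subject_id, function(s) {
    p <- cohort$pma_weeks[cohort$subject_id == s]
    sd_e / sqrt(sum((p - mean(p))^2))
  }, 0)
  within3 <- abs(j$slope - j$gen) <= 3 * j$se
  expect_gt(mean(within3), 0.9)
})
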