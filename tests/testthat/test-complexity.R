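test_that("coarse-graining averages non-overlapping blocks", {
  expect_equal(coarse_grain(c(1, 2, 3, 4), 1), c(1, 2, 3, 4))
  expect_equal(coarse_grain(c(1, 2, 3, 4), 2), c(1.5, 3.5))
  expect_equal(length(coarse_grain(rnorm(25600), 20)), 1280)
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5), 2), c(1.5, 3.5))  # remainder dropped
})

test_that("sample entropy equals the brute-force pair-count oracle exactly", {
  set.seed(8)
  cases <- list(
    rnorm(500),
    sinusoid(3, 500 / FS) + 0.3 * rnorm(500),
    cumsum(rnorm(2000)),          # strongly correlated
    rnorm(2000)
  )
  for (x in cases) {
    for (m in c(2, 3)) {
      r <- 0.2 * sd(x)
      fast <- neomat:::sampen_counts_cpp(x, m, r)
      brute <- sampen_counts_brute(x, m, r)
      expect_identical(unname(fast), unname(brute))
    }
  }
})

test_that("sample entropy closed forms and degenerate cases", {
  expect_equal(sample_entropy(rep(1, 100), 2, 0.5), 0)
  # strictly periodic 0,1,0,1,...: continuation deterministic
  expect_equal(sample_entropy(rep(c(0, 1), 100), 2, 0.1), 0)
  # iid Gaussian: SampEn -> -ln P(|X-Y| < r) = -ln erf(r/2)
  set.seed(9)
  g <- rnorm(20000)
  expect_equal(sample_entropy(g, 2, 0.2), -log(pracma::erf(0.1)),
               tolerance = 0.05)
  expect_true(is.na(sample_entropy(rnorm(100), 2, 0)))
  expect_true(is.na(sample_entropy(c(1, 2), 2, 0.5)))
})

test_that("sample entropy is invariant to affine scaling with r = r_factor * SD", {
  set.seed(10)
  x <- rnorm(3000)
  a <- sample_entropy(x, 2, 0.2 * sd(x))
  y <- 13 * x + 7
  b <- sample_entropy(y, 2, 0.2 * sd(y))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("MSE curves have the canonical white/pink shapes", {
  cfg <- neomat_config()
  set.seed(12)
  white <- mse_curve(rnorm(25600), cfg)
  expect_equal(white$flag, "ok")
  expect_lt(cor(white$scales, white$sampen, method = "spearman"), -0.9)

  pink <- mse_curve(colored_noise(25600, FS, alpha = 1, rms = 1), cfg)
  sl <- function(cv) coef(lm(cv$sampen[5:20] ~ cv$scales[5:20]))[[2]]
  expect_lt(abs(sl(pink)), 0.5 * abs(sl(white)))

  degen <- mse_curve(rep(0, 25600), cfg)
  expect_match(degen$flag, "degenerate")
  expect_true(all(is.na(complexity_features(degen, cfg))))
})

test_that("complexity features match quadrature and closed forms", {
  cfg <- neomat_config()
  mk <- function(v) structure(list(scales = 1:20, sampen = v,
                                   params = cfg$complexity, flag = "ok"),
                              class = "mse_curve")
  cf <- complexity_features(mk(rep(2, 20)), cfg)
  expect_equal(cf[["complexity_index"]], 19 * 2)
  expect_equal(cf[["slope_small"]], 0)
  expect_equal(cf[["mse_max"]], 2)

  cf2 <- complexity_features(mk(as.numeric(1:20)), cfg)
  expect_equal(cf2[["complexity_index"]], 199.5)
  expect_equal(cf2[["slope_small"]], 1)
  expect_equal(cf2[["mse_max"]], 20)

  set.seed(13)
  v <- runif(20)
  cf3 <- complexity_features(mk(v), cfg)
  oracle <- sum((v[-1] + v[-20]) / 2)   # unit-spaced trapezoid
  expect_equal(cf3[["complexity_index"]], oracle, tolerance = 1e-12)
})
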