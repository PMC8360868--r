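# Statistical analyses: feature-vs-PMA mixed models, EEG-vs-MRI partial
# correlation and multiple regression, per-subject maturation-trajectory
# slopes, growth per week, and PMA adjustment of brain volumes.

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list with `rho` and `p`; `rho = NA` with a flag when either
#'   variable has zero variance.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, flag = "zero variance"))
  ct <- cor.test(x, y)
  list(rho = unname(ct$estimate), p = ct$p.value, flag = "ok")
}

#' Mixed-effects brain-age model for one feature
#'
#' Fits `feature ~ 1 + PMA` with correlated random intercept and slope per
#' subject (REML).  On a singular random-effects fit the model falls back
#' to a random intercept only, then to ordinary least squares, logging the
#' step via the returned `model_type`.  Fixed-effect inference is Wald
#' (normal) with a 95% CI; `R2_marginal` / `R2_conditional` follow the
#' variance-partition definition (fixed-effect variance, respectively
#' fixed-plus-random, over total), and `rho` is the marginal Pearson
#' correlation between the feature and PMA.
#'
#' @param cohort cohort table with `subject_id`, `pma_weeks` and the
#'   feature column.
#' @param feature feature column name.
#' @param model `"auto"` (default) uses the fallback ladder; the other
#'   values force a specific rung.  `"ols"` is the model with the
#'   random-effect variances fixed at zero, which is exactly ordinary
#'   least squares.
#' @return object of class `lme_fit`: list with `slope`, `intercept`,
#'   `se`, `ci` (length 2), `p`, `model_type`
#'   (`"random_slope"`, `"random_intercept"`, `"ols"`), `rho`, `p_rho`,
#'   `R2_marginal`, `R2_conditional`, and the underlying `fit`.
#' @export
fit_lme_pma <- function(cohort, feature,
                        model = c("auto", "random_slope",
                                  "random_intercept", "ols")) {
  model <- match.arg(model)
  d <- cohort[is.finite(cohort[[feature]]), ]
  if (nrow(d) < 10) stop("need at least 10 non-missing rows for ", feature)
  d$y <- d[[feature]]
  # centre PMA inside the fit: with raw PMA (~28 weeks) the random
  # intercept and slope are almost perfectly correlated and the fit is
  # ill-conditioned; the slope is unaffected and the intercept is mapped
  # back to the raw scale below
  pma_c0 <- mean(d$pma_weeks)
  d$pma_c <- d$pma_weeks - pma_c0
  ctl <- lme4::lmerControl(calc.derivs = FALSE,
                           check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-2))
  fit <- NULL
  model_type <- "random_slope"
  if (model %in% c("auto", "random_slope")) {
    fit <- tryCatch(suppressWarnings(suppressMessages(
      lme4::lmer(y ~ pma_c + (pma_c | subject_id), data = d,
                 REML = TRUE, control = ctl))), error = function(e) NULL)
    if (model == "auto" && !is.null(fit) && lme4::isSingular(fit, tol = 1e-2))
      fit <- NULL
  }
  if (is.null(fit) && model %in% c("auto", "random_intercept")) {
    model_type <- "random_intercept"
    fit <- tryCatch(suppressWarnings(suppressMessages(
      lme4::lmer(y ~ pma_c + (1 | subject_id), data = d,
                 REML = TRUE, control = ctl))), error = function(e) NULL)
    if (model == "auto" && !is.null(fit) && lme4::isSingular(fit, tol = 1e-2))
      fit <- NULL
  }
  if (is.null(fit)) {
    model_type <- "ols"
    fit <- lm(y ~ pma_c, data = d)
  }
  if (model_type == "ols") {
    sm <- summary(fit)$coefficients
    slope <- sm["pma_c", "Estimate"]
    se <- sm["pma_c", "Std. Error"]
    p <- sm["pma_c", "Pr(>|t|)"]
    r2m <- r2c <- summary(fit)$r.squared
    int_c <- coef(fit)[[1]]
  } else {
    fe <- lme4::fixef(fit)
    slope <- fe[["pma_c"]]
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))[["pma_c"]]
    p <- 2 * pnorm(-abs(slope / se))
    yhat_fixed <- as.numeric(model.matrix(fit) %*% fe)
    var_f <- var(yhat_fixed)
    var_r <- var(fitted(fit) - yhat_fixed)
    var_e <- attr(lme4::VarCorr(fit), "sc")^2
    r2m <- var_f / (var_f + var_r + var_e)
    r2c <- (var_f + var_r) / (var_f + var_r + var_e)
    int_c <- fe[[1]]
  }
  ci <- slope + c(-1, 1) * 1.96 * se
  pr <- pearson(d$y, d$pma_weeks)
  structure(list(slope = slope,
                 intercept = int_c - slope * pma_c0,
                 se = se, ci = ci, p = p, model_type = model_type,
                 rho = pr$rho, p_rho = pr$p,
                 R2_marginal = r2m, R2_conditional = r2c, fit = fit),
            class = "lme_fit")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat(sprintf("<lme_fit %s> b = %.4f (%.4f; %.4f), p = %.3g; rho = %.3f, R2m = %.3f, R2c = %.3f\n",
              x$model_type, x$slope, x$ci[1], x$ci[2], x$p, x$rho,
              x$R2_marginal, x$R2_conditional))
  invisible(x)
}

#' Maturation table: mixed-model fit for every feature
#'
#' @param cohort cohort feature table.
#' @param features feature names (default all twelve).
#' @return data.frame with one row per feature: `rho`, `p_rho`,
#'   `R2_marginal`, `R2_conditional`, `b`, `ci_lo`, `ci_hi`, `p_b`,
#'   `model_type`.
#' @export
fit_maturation_table <- function(cohort, features = feature_names()) {
  rows <- lapply(features, function(f) {
    fit <- fit_lme_pma(cohort, f)
    data.frame(feature = f, rho = fit$rho, p_rho = fit$p_rho,
               R2_marginal = fit$R2_marginal,
               R2_conditional = fit$R2_conditional,
               b = fit$slope, ci_lo = fit$ci[1], ci_hi = fit$ci[2],
               p_b = fit$p, model_type = fit$model_type)
  })
  do.call(rbind, rows)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation between the residuals of `x` and `y` after OLS
#' regression of each on an intercept plus `controls`; two-sided p-value
#' on n - 2 - k degrees of freedom.  Constant or collinear control
#' columns are dropped with a warning.
#'
#' @param x,y numeric vectors.
#' @param controls data.frame or matrix of control variables.
#' @return list with `rho`, `p`, `df`, and `dropped` control names.
#' @export
partial_correlation <- function(x, y, controls) {
  controls <- as.data.frame(controls)
  controls[] <- lapply(controls, as.numeric)
  keep <- vapply(controls, function(v) sd(v) > 0, TRUE)
  dropped <- names(controls)[!keep]
  controls <- controls[, keep, drop = FALSE]
  if (ncol(controls) > 0) {
    qx <- qr(cbind(1, as.matrix(controls)))
    if (qx$rank < ncol(controls) + 1) {
      full <- qr(cbind(1, as.matrix(controls)))
      indep <- full$pivot[seq_len(full$rank)] - 1L
      indep <- indep[indep > 0]
      dropped <- c(dropped, setdiff(names(controls), names(controls)[indep]))
      controls <- controls[, indep, drop = FALSE]
    }
  }
  if (length(dropped) > 0)
    warning("dropping degenerate control(s): ", paste(dropped, collapse = ", "))
  n <- length(x)
  k <- ncol(controls)
  stopifnot(n > k + 2)
  if (k == 0) {
    rx <- x - mean(x); ry <- y - mean(y)
  } else {
    X <- as.matrix(controls)
    rx <- resid(lm(x ~ X))
    ry <- resid(lm(y ~ X))
  }
  r <- cor(rx, ry)
  df <- n - 2 - k
  t <- r * sqrt(df / (1 - r^2))
  list(rho = r, p = 2 * pt(-abs(t), df), df = df, dropped = dropped)
}

#' Multiple regression of an MRI metric on an EEG feature plus covariates
#'
#' Ordinary least squares `y ~ x + GA + morphine`; reports the
#' coefficient on the EEG feature with its 95% CI and p-value, and the R^2
#' of the full model.
#'
#' @param y MRI metric values.
#' @param x EEG feature values.
#' @param covars data.frame with `ga_weeks` and `morphine`.
#' @return list with `b`, `ci` (length 2), `p`, `r2`, `coefs` (all
#'   coefficients), `n`.
#' @export
multiple_regression <- function(y, x, covars) {
  stopifnot(length(y) >= 5)
  d <- data.frame(y = y, x = x,
                  ga_weeks = as.numeric(covars$ga_weeks),
                  morphine = as.numeric(covars$morphine))
  fit <- lm(y ~ x + ga_weeks + morphine, data = d)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient regression; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  ci <- confint(fit)["x", ]
  list(b = coef(fit)[["x"]], ci = unname(ci),
       p = sm$coefficients["x", "Pr(>|t|)"], r2 = sm$r.squared,
       coefs = coef(fit), n = length(y))
}

#' Per-subject maturation-trajectory slopes
#'
#' OLS slope of the feature against PMA for every subject with at least
#' two recordings (feature units per week); single-recording subjects are
#' dropped.
#'
#' @param cohort cohort feature table.
#' @param feature feature column name.
#' @return data.frame `subject_id`, `slope`, `n_points`.
#' @export
trajectory_slopes <- function(cohort, feature) {
  d <- cohort[is.finite(cohort[[feature]]), ]
  rows <- lapply(split(d, d$subject_id), function(g) {
    if (nrow(g) < 2) return(NULL)
    data.frame(subject_id = g$subject_id[1],
               slope = coef(lm(g[[feature]] ~ g$pma_weeks))[[2]],
               n_points = nrow(g))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Structural growth per week between two scans
#'
#' @param m1,m2 metric at the first/second scan.
#' @param pma1,pma2 PMA at the first/second scan, weeks (`pma2 > pma1`).
#' @return (m2 - m1) / (pma2 - pma1), elementwise.
#' @export
growth_per_week <- function(m1, m2, pma1, pma2) {
  if (any(pma2 <= pma1)) stop("pma2 must be strictly greater than pma1")
  (m2 - m1) / (pma2 - pma1)
}

#' Adjust brain volumes for PMA at scan
#'
#' Within each scan group, replaces each volume by its residual from an
#' OLS regression on PMA-at-scan plus the group mean, so the adjusted
#' volume is uncorrelated with scan age.  Groups with fewer than 3 rows
#' are passed through with a warning.
#'
#' @param mri MRI table with `scan`, `pma_at_scan` and metric columns.
#' @param metrics metric column names to adjust (default: all numeric
#'   columns other than `pma_at_scan`).
#' @return the MRI table with adjusted metric columns.
#' @export
adjust_volumes_for_pma <- function(mri, metrics = NULL) {
  if (is.null(metrics))
    metrics <- setdiff(names(mri)[vapply(mri, is.numeric, TRUE)], "pma_at_scan")
  out <- mri
  for (g in unique(mri$scan)) {
    sel <- mri$scan == g
    if (sum(sel) < 3) {
      warning("scan group ", g, " has fewer than 3 rows; not adjusted")
      next
    }
    for (m in metrics) {
      v <- mri[[m]][sel]
      ok <- is.finite(v)
      if (sum(ok) < 3) next
      r <- resid(lm(v[ok] ~ mri$pma_at_scan[sel][ok]))
      out[[m]][sel][ok] <- r + mean(v[ok])
    }
  }
  out
}

#' Full EEG-vs-MRI association suite
#'
#' For every combination of EEG predictor and MRI metric, computes the
#' partial correlation (controlling for GA and morphine) and the multiple
#' regression coefficient.  `mode = "early"` uses each subject's first
#' recording; `mode = "slopes"` uses the per-subject maturation-trajectory
#' slope of each feature (subjects with >= 2 recordings).  No multiplicity
#' correction is applied by default; `adjust = "BH"` adds a
#' Benjamini-Hochberg column.
#'
#' @param cohort cohort feature table.
#' @param mri MRI table (one row per subject per scan).
#' @param mode `"early"` or `"slopes"`.
#' @param features EEG feature names.
#' @param metrics MRI metric column names (default: numeric columns other
#'   than `pma_at_scan`).
#' @param alpha significance level for the `significant` flag.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame, one row per (feature, metric, scan), sorted, with
#'   `rho_partial`, `p_rho`, `b`, `ci_lo`, `ci_hi`, `p_b`, `r2`, `n`,
#'   `significant`.
#' @export
run_association_suite <- function(cohort, mri, mode = c("early", "slopes"),
                                  features = feature_names(), metrics = NULL,
                                  alpha = 0.05, adjust = c("none", "BH")) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  if (is.null(mri) || nrow(mri) == 0) {
    warning("empty MRI table; no associations computed")
    return(data.frame())
  }
  if (is.null(metrics))
    metrics <- setdiff(names(mri)[vapply(mri, is.numeric, TRUE)], "pma_at_scan")
  subj_cov <- do.call(rbind, lapply(split(cohort, cohort$subject_id),
                                    function(d) d[which.min(d$epoch_index), ]))
  eeg <- if (mode == "early") {
    subj_cov[, c("subject_id", features)]
  } else {
    wide <- Reduce(function(a, b) merge(a, b, by = "subject_id"),
                   lapply(features, function(f) {
                     s <- trajectory_slopes(cohort, f)
                     setNames(s[, c("subject_id", "slope")], c("subject_id", f))
                   }))
    wide
  }
  rows <- list()
  for (sc in unique(mri$scan)) {
    msub <- mri[mri$scan == sc, ]
    j <- merge(merge(eeg, msub, by = "subject_id"),
               subj_cov[, c("subject_id", "ga_weeks", "morphine")],
               by = "subject_id")
    for (f in features) for (m in metrics) {
      ok <- is.finite(j[[f]]) & is.finite(j[[m]])
      if (sum(ok) < 6) next
      ctr <- data.frame(ga_weeks = j$ga_weeks[ok],
                        morphine = as.numeric(j$morphine[ok]))
      pc <- suppressWarnings(partial_correlation(j[[f]][ok], j[[m]][ok], ctr))
      mr <- multiple_regression(j[[m]][ok], j[[f]][ok], ctr)
      rows[[length(rows) + 1L]] <-
        data.frame(mode = mode, scan = sc, eeg_feature = f, mri_metric = m,
                   rho_partial = pc$rho, p_rho = pc$p, b = mr$b,
                   ci_lo = mr$ci[1], ci_hi = mr$ci[2], p_b = mr$p,
                   r2 = mr$r2, n = mr$n)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out <- out[order(out$scan, out$mri_metric, out$eeg_feature), ]
  rownames(out) <- NULL
  if (adjust == "BH") out$p_b_BH <- stats::p.adjust(out$p_b, "BH")
  out$significant <- out$p_b < alpha
  out
}
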