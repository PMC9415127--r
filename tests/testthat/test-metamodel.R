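test_that("standardisation z-scores continuous terms and leaves binaries alone", {
  tab <- study_table(seed = 1)
  std <- standardise_covariates(tab)
  for (term in std$scaling$term) {
    expect_equal(mean(std$data[[term]]), 0, tolerance = 1e-12)
    expect_equal(sd(std$data[[term]]), 1, tolerance = 1e-12)
  }
  expect_setequal(unique(std$data$residue_retained), c(0, 1))
  # one-hot columns against an alphabetical reference level
  expect_true(all(std$data$method_subplot %in% c(0, 1)))
  expect_false("method_isotope15N" %in% names(std$data))
})

test_that("back-transformation restores the original co-variable units", {
  tab <- study_table(seed = 1)
  std <- standardise_covariates(tab)
  back <- unstandardise(std$data, std$scaling)
  expect_equal(back$gdd, tab$gdd)
  expect_equal(back$clay, tab$clay_pct)
  expect_equal(back$duration, as.numeric(tab$duration_years))
})

test_that("a zero-variance co-variable is refused by name", {
  tab <- study_table(seed = 1)
  tab$clay_pct <- 20
  expect_error(standardise_covariates(tab), "clay")
})

test_that("with variance ratios fixed at zero the fit is weighted least squares", {
  d <- make_tiny_model_frame()
  fit <- fit_mixed(d, "x", estimation = "REML", gamma = c(0, 0))
  wls <- lm(delta_re ~ x, data = d, weights = weight)
  expect_equal(unname(fit$beta), unname(coef(wls)), tolerance = 1e-8)
  # residual variance: weighted RSS / (n - p), the REML scale
  expect_equal(fit$sigma2_resid,
               sum(d$weight * resid(wls)^2) / (nrow(d) - 2),
               tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(wls)))),
               tolerance = 1e-8)
})

test_that("the optimised REML criterion dominates an independent grid oracle", {
  d <- make_tiny_model_frame()
  fit <- fit_mixed(d, "x", estimation = "REML")
  grid <- as.matrix(expand.grid(gs = seq(0, 3, length.out = 25),
                                gy = seq(0, 3, length.out = 25)))
  oracle <- apply(grid, 1, function(g)
    oracle_criterion(d, "x", g, estimation = "REML"))
  expect_gte(fit$loglik + 1e-8, max(oracle))
  # and the criterion function itself agrees with the oracle pointwise
  probe <- fit_mixed(d, "x", estimation = "REML", gamma = c(0.4, 0.9))
  expect_equal(probe$loglik,
               as.numeric(oracle_criterion(d, "x", c(0.4, 0.9), "REML")),
               tolerance = 1e-10)
  probe_ml <- fit_mixed(d, "x", estimation = "ML", gamma = c(0.4, 0.9))
  expect_equal(probe_ml$loglik,
               as.numeric(oracle_criterion(d, "x", c(0.4, 0.9), "ML")),
               tolerance = 1e-10)
})

test_that("the fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  tab <- study_table(seed = 1)
  std <- standardise_covariates(tab)
  d <- std$data
  d$site <- factor(d$site_id)
  d$yr <- factor(d$year)
  fm <- lme4::lmer(delta_re ~ clay + method_subplot + (1 | site) + (1 | yr),
                   data = d, weights = weight, REML = TRUE)
  ours <- fit_mixed(d, c("clay", "method_subplot"), estimation = "REML")
  expect_equal(unname(ours$beta), unname(lme4::fixef(fm)), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(fm))
  expect_equal(ours$sigma2_site, vc$vcov[vc$grp == "site"], tolerance = 1e-3)
  expect_equal(ours$sigma2_year, vc$vcov[vc$grp == "yr"], tolerance = 1e-3)
  expect_equal(ours$sigma2_resid, vc$vcov[vc$grp == "Residual"],
               tolerance = 1e-3)
  expect_equal(ours$loglik, as.numeric(logLik(fm)), tolerance = 1e-5)

  fm_ml <- lme4::lmer(delta_re ~ clay + (1 | site) + (1 | yr), data = d,
                      weights = weight, REML = FALSE)
  ours_ml <- fit_mixed(d, "clay", estimation = "ML")
  expect_equal(unname(ours_ml$beta), unname(lme4::fixef(fm_ml)),
               tolerance = 1e-4)
  expect_equal(ours_ml$loglik, as.numeric(logLik(fm_ml)), tolerance = 1e-5)
})

test_that("the small-sample information criterion matches its closed form", {
  expect_equal(aicc(-50, 3, 66), 106.3871, tolerance = 1e-4)
  set.seed(31)
  for (i in 1:20) {
    l <- rnorm(1, -40, 20)
    k <- sample(2:8, 1)
    n <- sample((k + 3):80, 1)
    expect_equal(aicc(l, k, n),
                 -2 * l + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  }
  # approaches plain AIC for large n
  expect_equal(aicc(-50, 4, 1e7), -2 * -50 + 2 * 4, tolerance = 1e-4)
  expect_error(aicc(-50, 10, 11), "n_obs")
})

test_that("all-subsets selection enumerates 2^m models and ranks deterministically", {
  tab <- study_table(seed = 1)
  std <- standardise_covariates(tab)
  dr <- dredge_aicc(std, candidate_terms = c("clay", "method", "crop"))
  expect_equal(nrow(dr$table), 8)
  expect_equal(dr$table$delta_aicc[1], 0)
  expect_true(all(diff(dr$table$aicc) >= 0))
  dr0 <- dredge_aicc(std, candidate_terms = character(0))
  expect_equal(nrow(dr0$table), 1)
  expect_equal(dr0$table$terms, "")
})

test_that("selection ranking is invariant to the order of input records", {
  tab <- study_table(seed = 4)
  std1 <- standardise_covariates(tab)
  set.seed(99)
  std2 <- standardise_covariates(tab[sample(nrow(tab)), ])
  dr1 <- dredge_aicc(std1, candidate_terms = c("clay", "method", "crop",
                                               "aridity"))
  dr2 <- dredge_aicc(std2, candidate_terms = c("clay", "method", "crop",
                                               "aridity"))
  expect_equal(dr1$table$terms, dr2$table$terms)
  expect_equal(dr1$table$aicc, dr2$table$aicc, tolerance = 1e-6)
})

test_that("selection recovers a planted crop effect", {
  # legacy effects driven only by crop; 4 candidate terms keep the
  # enumeration small while testing the same selection mechanics
  hits <- 0
  n_rep <- 40
  for (rep in seq_len(n_rep)) {
    ds <- make_study_like_dataset(seed = 4000 + rep)
    tab <- build_recovery_table(ds)
    tab$delta_re <- 0.15 + 0.2 * (tab$crop == "winter_wheat") +
      rnorm(nrow(tab), 0, 0.03)
    std <- standardise_covariates(tab)
    dr <- dredge_aicc(std, candidate_terms = c("crop", "clay", "aridity",
                                               "duration"))
    if (any(vapply(dr$best_set, function(s) "crop" %in% s, logical(1)))) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("the across-study mean is weight-scale invariant and shift equivariant", {
  tab <- study_table(seed = 1)
  m1 <- mean_delta_re(tab)
  tab10 <- tab
  tab10$weight <- tab10$weight * 10
  m10 <- mean_delta_re(tab10)
  expect_equal(m10$estimate, m1$estimate, tolerance = 1e-6)

  shifted <- tab
  shifted$delta_re <- shifted$delta_re + 0.37
  m_s <- mean_delta_re(shifted)
  expect_equal(m_s$estimate, m1$estimate + 0.37, tolerance = 1e-6)
})

test_that("degenerate single-site equal-weight mean is the classical t-interval", {
  d <- data.frame(delta_re = c(0.1, 0.2, 0.3, 0.15, 0.25),
                  weight = 1, site_id = "s1",
                  year = paste0("y", 1:5), stringsAsFactors = FALSE)
  fit <- fit_mixed(d, character(0), estimation = "REML", gamma = c(0, 0))
  expect_equal(unname(fit$beta[1]), mean(d$delta_re))
  expect_equal(unname(fit$se[1]), sd(d$delta_re) / sqrt(5), tolerance = 1e-8)
})

test_that("the method contrast is zero for identical paired values and needs both methods", {
  ds <- make_tiny_dataset()
  obs <- ds$observations
  # craft a second site so the site variance is estimable
  obs2 <- obs
  obs2$site_id <- "beta"
  obs2$n_uptake <- obs2$n_uptake + 10
  obs2$n15_uptake <- obs2$n15_uptake + 2
  cov2 <- rbind(ds$covariates, transform(ds$covariates, site_id = "beta"))
  tab <- build_recovery_table(lte_dataset(rbind(obs, obs2), cov2))
  # force both methods to the same legacy effect
  tab$delta_re <- ave(tab$delta_re, paste(tab$site_id, tab$year))
  ctr <- method_contrast(tab)
  expect_equal(ctr$all$estimate, 0, tolerance = 1e-8)
  expect_error(method_contrast(tab[tab$method == "subplot", ]),
               "both methods")
})

test_that("a planted method bias is recovered by the contrast", {
  # under-recovery of the labelled method shifts the legacy-effect contrast
  # by exactly bias * r1 in expectation; here bias * r1 = 0.074
  r1 <- 0.45
  bias <- 0.074 / r1
  est <- vapply(seq_len(30), function(i) {
    cfg <- synthetic_config(n_sites = 6, delta15_bias = bias,
                            seed = 7000 + i)
    method_contrast(build_recovery_table(simulate_lte(cfg)))$all$estimate
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.074), 0.01)
})

test_that("collinearity diagnostics flag duplicated information", {
  tab <- study_table(seed = 1)
  tab$gdd <- tab$clay_pct * 3 + 5  # perfectly collinear pair
  std <- standardise_covariates(tab)
  dg <- covariate_diagnostics(std)
  expect_equal(dg$correlation, t(dg$correlation))
  expect_equal(unname(diag(dg$correlation)), rep(1, ncol(dg$correlation)))
  expect_true(any(dg$flagged$r > 0.999))
  expect_true(is.finite(dg$skewness) && is.finite(dg$excess_kurtosis))
})
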