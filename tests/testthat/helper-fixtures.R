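## Minimal single-site-year dataset with both kinds of short-term subplot.
make_tiny_dataset <- function() {
  obs <- data.frame(
    site_id = "alpha", year = 2000L, crop = "winter_wheat",
    treatment = c("LT_N", "LT_0N", "ST_0N_subplot", "ST_15N_subplot"),
    n_rate = 200,
    n15_rate = c(NA, NA, NA, 200),
    n_uptake = c(160, 60, 80, 160),
    n15_uptake = c(NA, NA, NA, 94),
    n_field_reps = 3L, n_years_pooled = 1L,
    stringsAsFactors = FALSE
  )
  cov <- data.frame(
    site_id = "alpha", gdd = 2100, temp_seasonality = 5.5, aridity = 1.0,
    crop = "winter_wheat", duration_years = 20L, avg_n_rate = 200,
    clay_pct = 25, method = "subplot", residue_retained = FALSE,
    stringsAsFactors = FALSE
  )
  lte_dataset(obs, cov)
}

## Fixed 8-observation, 2-site x 2-year model frame for mixed-model oracles.
make_tiny_model_frame <- function() {
  data.frame(
    delta_re = c(0.21, 0.30, 0.16, 0.27, 0.35, 0.12, 0.24, 0.19),
    weight = c(1, 2, 1, 3, 2, 1, 2, 1),
    site_id = rep(c("s1", "s2"), each = 4),
    year = rep(c("y1", "y1", "y2", "y2"), 2),
    x = c(-0.8, 0.3, 1.1, -0.2, 0.5, -1.0, 0.7, 0.1),
    stringsAsFactors = FALSE
  )
}

## Direct evaluation of the profiled REML/ML criterion, written independently
## of fit_mixed() (plain matrix algebra, no Cholesky shortcuts), used as the
## grid oracle.
oracle_criterion <- function(data, fixed_cols, gamma,
                             estimation = "REML", response = "delta_re") {
  y <- data[[response]]
  n <- length(y)
  X <- cbind(1, if (length(fixed_cols)) as.matrix(data[fixed_cols]))
  p <- ncol(X)
  Zs <- outer(data$site_id, unique(data$site_id), `==`) * 1
  Zy <- outer(data$year, unique(data$year), `==`) * 1
  V <- gamma[1] * Zs %*% t(Zs) + gamma[2] * Zy %*% t(Zy) +
    diag(1 / data$weight)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  q <- drop(t(r) %*% Vi %*% r)
  if (estimation == "ML") {
    s2 <- q / n
    -0.5 * (n * log(2 * pi) + n * log(s2) +
              determinant(V)$modulus + n)
  } else {
    s2 <- q / (n - p)
    -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2) +
              determinant(V)$modulus + determinant(XtViX)$modulus + (n - p))
  }
}

## The 66-record study-like recovery table, built once per test file run.
study_table <- function(seed = 1) {
  build_recovery_table(make_study_like_dataset(seed = seed))
}
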