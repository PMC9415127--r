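## Weighted linear mixed model with crossed random intercepts for site and
## year, written against the model
##
##   y = X beta + u_site + u_year + e,   u_site ~ N(0, sigma2_s I),
##   u_year ~ N(0, sigma2_y I),          e_i ~ N(0, sigma2 / w_i),
##
## where w_i is the replicate weight of record i. The likelihood is profiled
## over beta and sigma2, leaving a 2-parameter criterion in the variance
## ratios gamma = (sigma2_s, sigma2_y) / sigma2, maximised by a coarse grid
## followed by Nelder-Mead on a sqrt parameterisation (so the [0, Inf)
## boundary is reachable).

CANDIDATE_TERMS <- c("gdd", "temp_seasonality", "aridity", "crop",
                     "duration", "avg_n_rate", "clay", "method",
                     "residue_retained")

#' Standardise co-variables for the meta-model
#'
#' Continuous co-variables (growing degree days, temperature seasonality,
#' aridity, experiment duration, average N rate, clay content) are z-scored
#' (unweighted `(x - mean) / sd`) so that effect sizes are comparable across
#' co-variables; categorical co-variables (crop, method) are one-hot encoded
#' against the alphabetically first level present; the binary residue-
#' retention indicator is left as 0/1. The returned scaling table allows
#' exact back-transformation.
#'
#' @param records a `recovery_table` from [build_recovery_table()], or any
#'   data.frame with columns `delta_re`, `weight`, `site_id`, `year`, `gdd`,
#'   `temp_seasonality`, `aridity`, `crop`, `duration_years`, `avg_n_rate`,
#'   `clay_pct`, `method`, `residue_retained`.
#' @return list with elements `data` (model frame: response, weights,
#'   grouping factors and encoded co-variable columns), `terms` (named list
#'   mapping each candidate model term to its design columns), and `scaling`
#'   (data.frame of term, mean, sd for the continuous co-variables).
#' @seealso [unstandardise()]
#' @export
standardise_covariates <- function(records) {
  df <- as.data.frame(records)
  cont <- c(gdd = "gdd", temp_seasonality = "temp_seasonality",
            aridity = "aridity", duration = "duration_years",
            avg_n_rate = "avg_n_rate", clay = "clay_pct")
  out <- data.frame(
    delta_re = df$delta_re,
    weight = df$weight,
    site_id = as.character(df$site_id),
    year = as.character(df$year),
    stringsAsFactors = FALSE
  )
  if ("re_1st" %in% names(df)) out$re_1st <- df$re_1st
  if ("re_lt" %in% names(df)) out$re_lt <- df$re_lt
  terms <- list()
  scaling <- data.frame(term = character(0), mean = numeric(0),
                        sd = numeric(0), stringsAsFactors = FALSE)

  for (term in names(cont)) {
    x <- as.numeric(df[[cont[[term]]]])
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("co-variable '", term, "' has zero variance and cannot be ",
           "standardised", call. = FALSE)
    }
    m <- mean(x)
    out[[term]] <- (x - m) / s
    terms[[term]] <- term
    scaling <- rbind(scaling, data.frame(term = term, mean = m, sd = s,
                                         stringsAsFactors = FALSE))
  }

  for (term in c("crop", "method")) {
    levels_present <- sort(unique(as.character(df[[term]])))
    dummies <- levels_present[-1]  # alphabetically first level is reference
    cols <- character(0)
    for (lev in dummies) {
      col <- paste0(term, "_", lev)
      out[[col]] <- as.numeric(df[[term]] == lev)
      cols <- c(cols, col)
    }
    terms[[term]] <- cols  # empty when only one level present
  }

  out$residue_retained <- as.numeric(df$residue_retained)
  terms$residue_retained <- "residue_retained"

  list(data = out, terms = terms, scaling = scaling)
}

#' Undo co-variable standardisation
#'
#' Restores the original units of the continuous co-variable columns using
#' the scaling table returned by [standardise_covariates()].
#'
#' @param data the standardised model frame.
#' @param scaling the scaling table (`term`, `mean`, `sd`).
#' @return `data` with the continuous co-variables back on their original
#'   scales.
#' @export
unstandardise <- function(data, scaling) {
  for (i in seq_len(nrow(scaling))) {
    term <- scaling$term[i]
    data[[term]] <- data[[term]] * scaling$sd[i] + scaling$mean[i]
  }
  data
}

#' Fit the weighted crossed random-intercepts model
#'
#' Fits \eqn{y = X\beta + u_{site} + u_{year} + \varepsilon} with
#' \eqn{Var(\varepsilon_i) = \sigma^2 / w_i} by maximum likelihood or
#' restricted maximum likelihood. The criterion is profiled over the fixed
#' effects and the residual variance: with variance ratios
#' \eqn{\gamma = (\sigma^2_{site}, \sigma^2_{year})/\sigma^2} and
#' \eqn{V(\gamma) = \gamma_s Z_s Z_s' + \gamma_y Z_y Z_y' + W^{-1}}, the
#' generalised least squares solution
#' \eqn{\hat\beta = (X'V^{-1}X)^{-1} X'V^{-1} y} and a closed form for
#' \eqn{\hat\sigma^2} reduce the problem to a 2-dimensional search over
#' \eqn{\gamma \ge 0}, solved by a coarse grid followed by derivative-free
#' Nelder-Mead refinement on \eqn{\sqrt\gamma}.
#'
#' @param data model frame with columns `weight`, `site_id`, `year`, the
#'   response, and any fixed-effect columns (see
#'   [standardise_covariates()]).
#' @param fixed_cols character vector of fixed-effect column names (the
#'   intercept is always included; use `character(0)` for intercept-only).
#' @param response name of the response column (default `"delta_re"`).
#' @param estimation `"REML"` (default, for reported estimates) or `"ML"`
#'   (for model comparison).
#' @param gamma optional fixed variance ratios `c(site, year)`; when given,
#'   no optimisation is performed (e.g. `c(0, 0)` collapses the fit to
#'   weighted least squares).
#' @param reltol relative convergence tolerance of the criterion.
#' @return object of class `lte_mixfit`: fixed-effect estimates and
#'   standard errors, variance components (`sigma2_site`, `sigma2_year`,
#'   `sigma2_resid`), maximised log-criterion `loglik`, `n_obs`,
#'   `n_params` (fixed effects + 3 variance parameters), `aicc`,
#'   `converged`, and the Wald-t residual degrees of freedom
#'   `df = n_obs - n_sites`.
#' @export
fit_mixed <- function(data, fixed_cols = character(0),
                      response = "delta_re",
                      estimation = c("REML", "ML"),
                      gamma = NULL, reltol = 1e-10) {
  estimation <- match.arg(estimation)
  y <- as.numeric(data[[response]])
  w <- as.numeric(data$weight)
  if (any(is.na(w)) || any(w <= 0)) stop("weights must be > 0", call. = FALSE)
  n <- length(y)
  site <- factor(data$site_id)
  yearf <- factor(data$year)
  if (nlevels(site) < 2 && is.null(gamma)) {
    stop("need >= 2 sites to estimate a site variance component",
         call. = FALSE)
  }

  X <- cbind(`(Intercept)` = rep(1, n))
  if (length(fixed_cols)) {
    X <- cbind(X, as.matrix(data[fixed_cols]))
    colnames(X) <- c("(Intercept)", fixed_cols)
  }
  p <- ncol(X)
  if (qr(X)$rank < p) stop("fixed-effect design matrix is rank deficient",
                           call. = FALSE)

  ## incidence matrices built directly (a one-level factor is legal here,
  ## e.g. all observations from a single year)
  Zs <- outer(as.character(site), levels(site), `==`) * 1
  Zy <- outer(as.character(yearf), levels(yearf), `==`) * 1
  ZsZs <- tcrossprod(Zs)
  ZyZy <- tcrossprod(Zy)
  Winv <- diag(1 / w, n)

  crit <- function(g) {
    V <- g[1] * ZsZs + g[2] * ZyZy + Winv
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    logdetV <- 2 * sum(log(diag(ch)))
    Vi_Xy <- chol2inv(ch) %*% cbind(X, y)
    ViX <- Vi_Xy[, seq_len(p), drop = FALSE]
    Viy <- Vi_Xy[, p + 1]
    XtViX <- crossprod(X, ViX)
    beta <- tryCatch(solve(XtViX, crossprod(X, Viy)),
                     error = function(e) NULL)
    if (is.null(beta)) return(list(ll = -Inf))  # degenerate V direction
    r <- y - X %*% beta
    q <- drop(crossprod(r, Viy - ViX %*% beta))
    q <- max(q, 1e-300)
    if (estimation == "ML") {
      sig2 <- q / n
      ll <- -0.5 * (n * log(2 * pi) + n * log(sig2) + logdetV + n)
    } else {
      sig2 <- q / (n - p)
      ld2 <- determinant(XtViX, logarithm = TRUE)$modulus
      ll <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(sig2) +
                      logdetV + ld2 + (n - p))
    }
    list(ll = as.numeric(ll), beta = drop(beta), sig2 = sig2,
         XtViX = XtViX)
  }

  converged <- TRUE
  if (is.null(gamma)) {
    grid <- c(0, 0.01, 0.05, 0.2, 0.5, 1, 2, 5, 20)
    best <- c(0, 0)
    best_ll <- -Inf
    for (gs in grid) for (gy in grid) {
      ll <- crit(c(gs, gy))$ll
      if (ll > best_ll) {
        best_ll <- ll
        best <- c(gs, gy)
      }
    }
    obj <- function(phi) -crit(phi^2)$ll
    opt <- stats::optim(sqrt(best) + 1e-4, obj, method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = 2000))
    converged <- opt$convergence == 0
    gamma <- opt$par^2
    if (best_ll > -opt$value) {  # keep the grid point if NM drifted away
      gamma <- best
    }
  } else {
    if (length(gamma) != 2 || any(gamma < 0)) {
      stop("gamma must be two non-negative variance ratios", call. = FALSE)
    }
  }

  fit <- crit(gamma)
  if (!is.finite(fit$ll)) stop("mixed-model criterion is not finite",
                               call. = FALSE)
  vcov_beta <- fit$sig2 * solve(fit$XtViX)
  se <- sqrt(diag(vcov_beta))
  k <- p + 3L
  structure(list(
    beta = stats::setNames(fit$beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    vcov = vcov_beta,
    sigma2_site = gamma[1] * fit$sig2,
    sigma2_year = gamma[2] * fit$sig2,
    sigma2_resid = fit$sig2,
    gamma = gamma,
    loglik = fit$ll,
    n_obs = n,
    n_params = k,
    aicc = if (n > k + 1) aicc(fit$ll, k, n) else NA_real_,
    df = n - nlevels(site),
    estimation = estimation,
    response = response,
    fixed_cols = fixed_cols,
    converged = converged
  ), class = "lte_mixfit")
}

#' @export
print.lte_mixfit <- function(x, ...) {
  cat(sprintf("Weighted mixed model (%s), %d obs, crossed site/year intercepts\n",
              x$estimation, x$n_obs))
  coefs <- cbind(Estimate = x$beta, `Std.Error` = x$se)
  print(round(coefs, 4))
  cat(sprintf("  sigma2: site %.5f, year %.5f, residual %.5f\n",
              x$sigma2_site, x$sigma2_year, x$sigma2_resid))
  cat(sprintf("  logLik %.3f, AICc %.3f%s\n", x$loglik, x$aicc,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' \deqn{AICc = -2\,\ell + 2k + \frac{2k(k+1)}{n-k-1}}
#' with \eqn{k} the number of estimated parameters (here: fixed effects plus
#' two random-intercept variances plus the residual variance) and \eqn{n}
#' the number of observations.
#'
#' @param loglik maximised log-likelihood (or restricted log-likelihood).
#' @param n_params number of estimated parameters k.
#' @param n_obs number of observations n, must exceed `n_params + 1`.
#' @return the criterion value.
#' @examples
#' aicc(-50, 3, 66)  # 106.387
#' @export
aicc <- function(loglik, n_params, n_obs) {
  if (n_obs <= n_params + 1) {
    stop("AICc undefined: n_obs must exceed n_params + 1", call. = FALSE)
  }
  -2 * loglik + 2 * n_params + 2 * n_params * (n_params + 1) /
    (n_obs - n_params - 1)
}

#' Exhaustive AICc model selection over co-variable subsets
#'
#' Fits every subset of the candidate fixed-effect terms (all 2^9 = 512
#' models for the full nine-term candidate set; the intercept and the
#' crossed site/year random intercepts are always included), ranks them by
#' AICc and returns the set of models within 2 AICc units of the best.
#' All candidate fits use maximum likelihood so their likelihoods are
#' comparable across fixed-effect sets; refit the selected model with REML
#' for reported estimates. Ties are broken by fewer parameters, then by the
#' lexicographic term set, so the ranking is deterministic and independent
#' of input order.
#'
#' @param std output of [standardise_covariates()].
#' @param candidate_terms character vector of candidate term names, default
#'   all nine: gdd, temp_seasonality, aridity, crop, duration, avg_n_rate,
#'   clay, method, residue_retained.
#' @param delta_best models with AICc within this margin of the best form
#'   the selected set (default 2).
#' @return object of class `lte_dredge`: `table` (one row per model with
#'   term indicators, n_params, logLik, AICc and delta AICc, ranked
#'   ascending) and `best_set` (list of character vectors of term names
#'   with delta AICc <= `delta_best`).
#' @export
dredge_aicc <- function(std, candidate_terms = CANDIDATE_TERMS,
                        delta_best = 2) {
  stopifnot(all(candidate_terms %in% names(std$terms)))
  ## drop factor terms that collapsed to zero dummy columns (single level)
  usable <- candidate_terms[vapply(std$terms[candidate_terms], length,
                                   integer(1)) > 0]
  m <- length(usable)
  n_models <- 2^m
  rows <- vector("list", n_models)
  specs <- vector("list", n_models)
  for (i in seq_len(n_models) - 1L) {
    in_model <- usable[bitwAnd(i, bitwShiftL(1L, seq_len(m) - 1L)) > 0]
    cols <- unlist(std$terms[in_model], use.names = FALSE)
    fit <- tryCatch(
      fit_mixed(std$data, cols, estimation = "ML"),
      error = function(e) NULL
    )
    ok <- !is.null(fit) && fit$converged && is.finite(fit$aicc)
    rows[[i + 1L]] <- data.frame(
      model_id = i, terms = paste(sort(in_model), collapse = "+"),
      n_params = if (is.null(fit)) NA_integer_ else fit$n_params,
      loglik = if (is.null(fit)) NA_real_ else fit$loglik,
      aicc = if (ok) fit$aicc else Inf,  # failed fits rank last
      converged = ok,
      stringsAsFactors = FALSE
    )
    specs[[i + 1L]] <- sort(in_model)
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$aicc, tab$n_params, tab$terms)
  tab <- tab[ord, , drop = FALSE]
  specs <- specs[ord]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  rownames(tab) <- NULL
  best_set <- specs[is.finite(tab$delta_aicc) & tab$delta_aicc <= delta_best]
  structure(list(table = tab, best_set = best_set,
                 candidate_terms = usable, delta_best = delta_best),
            class = "lte_dredge")
}

#' @export
print.lte_dredge <- function(x, ...) {
  cat(sprintf("AICc all-subsets selection: %d candidate terms, %d models\n",
              length(x$candidate_terms), nrow(x$table)))
  cat(sprintf("  %d model(s) within %.1f AICc of the best\n",
              length(x$best_set), x$delta_best))
  print(utils::head(x$table[c("terms", "n_params", "aicc", "delta_aicc")], 5))
  invisible(x)
}

#' Weighted mean of a recovery statistic across experiments
#'
#' Estimates the across-study mean of a recovery statistic as the intercept
#' of the intercept-only weighted mixed model with crossed site and year
#' random intercepts (REML), with a Wald-t 95% confidence interval on
#' `n_obs - n_sites` degrees of freedom. The plain weighted arithmetic mean
#' `sum(w y) / sum(w)` is reported alongside, since with unbalanced designs
#' the two need not agree.
#'
#' @param records a `recovery_table` (or compatible data.frame with
#'   `weight`, `site_id`, `year` and the response column).
#' @param response which statistic to average (default `"delta_re"`).
#' @param conf confidence level (default 0.95).
#' @param use_weights set `FALSE` to refit with all weights equal (for
#'   sensitivity analysis of the weighting).
#' @return object of class `lte_mean`: `estimate`, `se`, `ci` (length 2),
#'   `df`, `weighted_mean` (the plain weighted mean), variance components
#'   and `n_obs`.
#' @export
weighted_mean_mixed <- function(records, response = "delta_re",
                                conf = 0.95, use_weights = TRUE) {
  df <- as.data.frame(records)
  df <- df[!is.na(df[[response]]), , drop = FALSE]
  data <- data.frame(
    y = df[[response]],
    weight = if (use_weights) df$weight else rep(1, nrow(df)),
    site_id = df$site_id, year = df$year,
    stringsAsFactors = FALSE
  )
  names(data)[1] <- response
  fit <- fit_mixed(data, character(0), response = response,
                   estimation = "REML")
  est <- unname(fit$beta[1])
  se <- unname(fit$se[1])
  tcrit <- stats::qt(1 - (1 - conf) / 2, df = fit$df)
  structure(list(
    estimate = est, se = se,
    ci = c(lower = est - tcrit * se, upper = est + tcrit * se),
    df = fit$df, conf = conf,
    weighted_mean = sum(data$weight * data[[response]]) / sum(data$weight),
    sigma2_site = fit$sigma2_site, sigma2_year = fit$sigma2_year,
    sigma2_resid = fit$sigma2_resid,
    n_obs = fit$n_obs, response = response, fit = fit
  ), class = "lte_mean")
}

#' Mean legacy effect across experiments
#'
#' Convenience wrapper: [weighted_mean_mixed()] on the legacy effect
#' `delta_re`.
#'
#' @inheritParams weighted_mean_mixed
#' @return see [weighted_mean_mixed()].
#' @export
mean_delta_re <- function(records, conf = 0.95, use_weights = TRUE) {
  weighted_mean_mixed(records, response = "delta_re", conf = conf,
                      use_weights = use_weights)
}

#' @export
print.lte_mean <- function(x, ...) {
  cat(sprintf(
    "Weighted mixed-model mean of %s: %.4f (%.0f%% CI %.4f to %.4f, df = %d)\n",
    x$response, x$estimate, 100 * x$conf, x$ci[1], x$ci[2], x$df))
  cat(sprintf("  plain weighted mean %.4f; n = %d\n", x$weighted_mean,
              x$n_obs))
  invisible(x)
}

#' Contrast between the 15N and subplot first-season methods
#'
#' Tests how the method used to estimate first-season recovery shifts the
#' legacy effect, by adding a method indicator to the weighted mixed model.
#' The contrast (15N minus subplot) is estimated twice: on all records that
#' used either method, and on the paired subset of site-years where both
#' methods were applied to the same plots (the most direct comparison, but
#' few records). P-values are Wald-t with `n_obs - n_sites` degrees of
#' freedom.
#'
#' An optional outlier rule (`drop_outlier = TRUE`) removes, in the paired
#' subset, the single record with the largest absolute studentised residual
#' when it exceeds 3, refits, and records what was dropped; it is off by
#' default.
#'
#' @param records a `recovery_table`.
#' @param drop_outlier apply the one-record studentised-residual rule to
#'   the paired subset (default `FALSE`).
#' @return object of class `lte_contrast` with components `all` and
#'   `paired`, each a list of `estimate` (15N - subplot), `se`, `t`, `df`,
#'   `p_value`, `n_obs`; plus `dropped` (description of any outlier
#'   removed, or `NULL`).
#' @export
method_contrast <- function(records, drop_outlier = FALSE) {
  df <- as.data.frame(records)
  df <- df[df$method %in% c("isotope15N", "subplot") & !is.na(df$delta_re), ,
           drop = FALSE]
  if (length(unique(df$method)) < 2) {
    stop("method contrast needs records from both methods", call. = FALSE)
  }

  contrast_fit <- function(d) {
    data <- data.frame(
      delta_re = d$delta_re, weight = d$weight,
      site_id = d$site_id, year = d$year,
      method_isotope15N = as.numeric(d$method == "isotope15N"),
      stringsAsFactors = FALSE
    )
    fit <- fit_mixed(data, "method_isotope15N", estimation = "REML")
    est <- unname(fit$beta["method_isotope15N"])
    se <- unname(fit$se["method_isotope15N"])
    tval <- est / se
    list(estimate = est, se = se, t = tval, df = fit$df,
         p_value = 2 * stats::pt(-abs(tval), df = fit$df),
         n_obs = fit$n_obs, fit = fit)
  }

  all_fit <- contrast_fit(df)

  key <- paste(df$site_id, df$year, sep = "\r")
  both <- names(which(tapply(df$method, key,
                             function(m) all(c("isotope15N", "subplot") %in% m))))
  paired_df <- df[key %in% both, , drop = FALSE]
  dropped <- NULL
  paired_fit <- NULL
  if (nrow(paired_df) >= 4 && length(unique(paired_df$site_id)) >= 2) {
    paired_fit <- contrast_fit(paired_df)
    if (drop_outlier) {
      fit <- paired_fit$fit
      X <- cbind(1, as.numeric(paired_df$method == "isotope15N"))
      resid <- paired_df$delta_re - drop(X %*% fit$beta)
      stud <- resid * sqrt(paired_df$weight) / sqrt(fit$sigma2_resid)
      i <- which.max(abs(stud))
      if (abs(stud[i]) > 3) {
        dropped <- sprintf("%s %s (%s), studentised residual %.2f",
                           paired_df$site_id[i], paired_df$year[i],
                           paired_df$method[i], stud[i])
        message("method_contrast: dropping outlier ", dropped)
        paired_fit <- contrast_fit(paired_df[-i, , drop = FALSE])
      }
    }
  }

  structure(list(all = all_fit, paired = paired_fit, dropped = dropped),
            class = "lte_contrast")
}

#' @export
print.lte_contrast <- function(x, ...) {
  cat("Legacy-effect contrast, 15N minus subplot method\n")
  cat(sprintf("  all records (n=%d): %.4f (SE %.4f, p = %.3g)\n",
              x$all$n_obs, x$all$estimate, x$all$se, x$all$p_value))
  if (!is.null(x$paired)) {
    cat(sprintf("  paired site-years (n=%d): %.4f (SE %.4f, p = %.3g)\n",
                x$paired$n_obs, x$paired$estimate, x$paired$se,
                x$paired$p_value))
  }
  if (!is.null(x$dropped)) cat("  outlier dropped:", x$dropped, "\n")
  invisible(x)
}

#' Co-variable collinearity and response-shape diagnostics
#'
#' Pearson correlations among the continuous co-variables of the
#' standardised design, with pairs exceeding `|r| > threshold` flagged, and
#' a skewness/excess-kurtosis summary of the response in place of density
#' plots.
#'
#' @param std output of [standardise_covariates()].
#' @param threshold absolute correlation above which a pair is flagged
#'   (default 0.8).
#' @return list with `correlation` (symmetric matrix, unit diagonal),
#'   `flagged` (data.frame of offending pairs, possibly empty), `skewness`
#'   and `excess_kurtosis` of the response.
#' @export
covariate_diagnostics <- function(std, threshold = 0.8) {
  cont <- std$scaling$term
  mat <- as.matrix(std$data[cont])
  cormat <- stats::cor(mat)
  flagged <- data.frame(var1 = character(0), var2 = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_len(ncol(cormat) - 1)) {
    for (j in seq((i + 1), ncol(cormat))) {
      if (abs(cormat[i, j]) > threshold) {
        flagged <- rbind(flagged, data.frame(
          var1 = cont[i], var2 = cont[j], r = cormat[i, j],
          stringsAsFactors = FALSE))
      }
    }
  }
  y <- std$data$delta_re
  y <- y[!is.na(y)]
  zc <- y - mean(y)
  m2 <- mean(zc^2)
  list(
    correlation = cormat,
    flagged = flagged,
    skewness = mean(zc^3) / m2^1.5,
    excess_kurtosis = mean(zc^4) / m2^2 - 3
  )
}
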