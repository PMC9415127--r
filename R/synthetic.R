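#' Configuration of the synthetic LTE generator
#'
#' Defines the generative process the test-bed simulates: every season each
#' site receives `n_rate` kg N/ha, of which a fraction `r1` is taken up by
#' the crop in the season of application and a fraction `rho` is retained in
#' the soil. Retained cohorts remineralise on an age schedule — a fraction
#' `m1` of the *applied* amount in the second season (capped at the retained
#' pool), `m2` of the *remaining pool* in the third, and `m_later` of the
#' remaining pool in each later season — and remineralised N is recovered by
#' the crop with efficiency `e_min`. Native soil N supply declines
#' exponentially from `s0` towards a floor `s_min` at rate `k_dep`. Site and
#' year random effects and plot-level measurement noise act on N uptake.
#'
#' The defaults follow multi-season isotope-tracing studies of fertiliser-N
#' fate in temperate cereal systems: first-season recovery 0.45, soil
#' retention 0.30 of the applied amount, and the 10% / 3%-of-remainder /
#' 1%-per-later-season remineralisation schedule.
#'
#' @param n_sites number of simulated sites.
#' @param years_per_site seasons of sustained application before the
#'   observation year (the observation year is the last).
#' @param n_rate annual N application (kg N/ha/yr).
#' @param r1 first-season fertiliser recovery fraction.
#' @param rho fraction of applied N retained in soil after season 1
#'   (`r1 + rho <= 1`; the remainder is lost).
#' @param m1 fraction of the applied amount remineralised in the 2nd season.
#' @param m2 fraction of the remaining retained pool remineralised in the
#'   3rd season.
#' @param m_later pool fraction remineralised in each later season.
#' @param e_min crop recovery efficiency of remineralised N (default `r1`).
#' @param s0,s_min,k_dep native soil N supply at the start (kg N/ha), its
#'   floor (kg N/ha), and the exponential depletion rate (1/yr).
#' @param sigma_site,sigma_year,sigma_obs SDs (kg N/ha) of the site effect,
#'   year effect and plot-level observation noise (the noise SD of a plot
#'   mean is `sigma_obs / sqrt(reps)`).
#' @param delta15_bias proportional under-recovery of the 15N method
#'   (added-nitrogen-interaction surrogate); 0 disables it.
#' @param reps field replicates per plot.
#' @param seed integer seed; all randomness flows from it.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 1, years_per_site = 16, n_rate = 100,
                             r1 = 0.45, rho = 0.30, m1 = 0.10, m2 = 0.03,
                             m_later = 0.01, e_min = r1,
                             s0 = 60, s_min = 35, k_dep = 0.03,
                             sigma_site = 5, sigma_year = 3, sigma_obs = 5,
                             delta15_bias = 0, reps = 3, seed = 1) {
  cfg <- list(n_sites = as.integer(n_sites),
              years_per_site = as.integer(years_per_site),
              n_rate = n_rate, r1 = r1, rho = rho, m1 = m1, m2 = m2,
              m_later = m_later, e_min = e_min, s0 = s0, s_min = s_min,
              k_dep = k_dep, sigma_site = sigma_site, sigma_year = sigma_year,
              sigma_obs = sigma_obs, delta15_bias = delta15_bias,
              reps = as.integer(reps), seed = as.integer(seed))
  problems <- character(0)
  for (f in c("r1", "rho", "m1", "m2", "m_later", "e_min")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      problems <- c(problems, paste0(f, " must be in [0, 1]"))
    }
  }
  if (cfg$r1 + cfg$rho > 1 + 1e-12) {
    problems <- c(problems, "r1 + rho must not exceed 1")
  }
  for (f in c("sigma_site", "sigma_year", "sigma_obs")) {
    if (cfg[[f]] < 0) problems <- c(problems, paste0(f, " must be >= 0"))
  }
  if (cfg$n_sites < 1 || cfg$years_per_site < 1 || cfg$reps < 1) {
    problems <- c(problems,
                  "n_sites, years_per_site and reps must be >= 1")
  }
  if (cfg$n_rate <= 0) problems <- c(problems, "n_rate must be > 0")
  if (cfg$delta15_bias < 0 || cfg$delta15_bias > 1) {
    problems <- c(problems, "delta15_bias must be in [0, 1]")
  }
  if (length(problems)) {
    stop("invalid synthetic config:\n",
         paste0("  - ", problems, collapse = "\n"), call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

## Per-cohort remineralised flux by cohort age. With annual application at a
## fixed rate, every cohort follows the same age trajectory:
##   age 1: m1 * applied, capped at the retained pool rho * applied
##   age 2: m2 * remaining pool
##   age>=3: m_later * remaining pool
## Returns the fluxes f(1..max_age) and remaining pools after each release.
cohort_schedule <- function(cfg, max_age) {
  if (max_age < 1) return(list(flux = numeric(0), pool = numeric(0)))
  flux <- numeric(max_age)
  pool <- numeric(max_age)
  p <- cfg$rho * cfg$n_rate
  for (a in seq_len(max_age)) {
    f <- if (a == 1) {
      min(cfg$m1 * cfg$n_rate, p)
    } else if (a == 2) {
      cfg$m2 * p
    } else {
      cfg$m_later * p
    }
    p <- p - f
    flux[a] <- f
    pool[a] <- p
  }
  list(flux = flux, pool = pool)
}

#' Remineralised fertiliser-N flux in a given season
#'
#' Deterministic soil-to-crop-available N flux at season `t` of sustained
#' annual application, summed over all fertiliser cohorts applied in seasons
#' 1 to t-1, each releasing according to its age (see
#' [synthetic_config()]). At `t = 1` there are no aged cohorts and the flux
#' is zero; as `t` grows the flux approaches `rho * n_rate` per year times
#' the fraction of each pool eventually released.
#'
#' @param cfg a [synthetic_config()].
#' @param t season index (1-based), `t >= 1`.
#' @return flux in kg N/ha.
#' @examples
#' cfg <- synthetic_config()
#' legacy_flux(cfg, 2)  # one cohort at age 1: 0.10 * 100 = 10
#' @export
legacy_flux <- function(cfg, t) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (t < 1) stop("t must be >= 1", call. = FALSE)
  if (t == 1) return(0)
  sched <- cohort_schedule(cfg, t - 1)
  sum(sched$flux)
}

#' Noise-free legacy effect implied by the generator
#'
#' The true legacy effect at season `t`: the remineralised flux captured by
#' the crop with efficiency `e_min`, as a fraction of the annual N rate,
#' \eqn{e_{min} \cdot flux(t) / N_{rate}}. Monotone non-decreasing in `t`
#' and bounded above by `e_min * rho` (full eventual release of every
#' cohort).
#'
#' @inheritParams legacy_flux
#' @return the true legacy effect (fraction of the annual N rate).
#' @export
expected_delta_re <- function(cfg, t) {
  cfg$e_min * legacy_flux(cfg, t) / cfg$n_rate
}

## Native soil N supply in season t (declines to a floor).
native_supply <- function(cfg, t) {
  cfg$s_min + (cfg$s0 - cfg$s_min) * exp(-cfg$k_dep * (t - 1))
}

#' Simulate one LTE observation set
#'
#' For each site, emits the four plot observations of the observation year
#' `T = years_per_site`: the long-term fertilised plot, its never-fertilised
#' control, a withheld-N subplot, and a 15N-labelled subplot. Mean uptakes
#' follow the generative model (native supply + first-season recovery +
#' remineralised-N capture + site/year effects), each plot mean perturbed by
#' `Normal(0, sigma_obs / sqrt(reps))` noise; labelled uptake is
#' `r1 * n_rate * (1 - delta15_bias)` plus noise. With all noise SDs at
#' zero, the recovery pipeline reproduces `r1` by both first-season methods
#' and [expected_delta_re()] exactly. Reproducible: the same config (and
#' seed) yields an identical dataset.
#'
#' @param cfg a [synthetic_config()].
#' @return an [lte_dataset()]. Uptakes are kept at full precision; they are
#'   reduced to the 6-significant-digit interchange resolution only when
#'   written with [write_dataset()].
#' @export
simulate_lte <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  rng <- local_rng(cfg$seed)
  on.exit(rng())

  tt <- cfg$years_per_site
  flux_capture <- cfg$e_min * legacy_flux(cfg, tt)
  s_t <- native_supply(cfg, tt)
  noise_sd <- cfg$sigma_obs / sqrt(cfg$reps)

  obs <- list()
  cov <- list()
  for (i in seq_len(cfg$n_sites)) {
    site <- sprintf("sim%02d", i)
    b_site <- stats::rnorm(1, 0, cfg$sigma_site)
    b_year <- stats::rnorm(1, 0, cfg$sigma_year)
    base <- s_t + b_site + b_year
    year <- 2000L + tt

    mean_lt0 <- base
    mean_ltn <- base + cfg$r1 * cfg$n_rate + flux_capture
    mean_st0 <- base + flux_capture
    mean_u15 <- cfg$r1 * cfg$n_rate * (1 - cfg$delta15_bias)

    noisy <- function(mu) {
      max(mu + stats::rnorm(1, 0, noise_sd), 0)
    }
    row <- function(treatment, n_uptake, n15_rate = NA_real_,
                    n15_uptake = NA_real_) {
      data.frame(site_id = site, year = year, crop = "winter_wheat",
                 treatment = treatment, n_rate = cfg$n_rate,
                 n15_rate = n15_rate, n_uptake = n_uptake,
                 n15_uptake = n15_uptake, n_field_reps = cfg$reps,
                 n_years_pooled = 1L, stringsAsFactors = FALSE)
    }
    obs[[length(obs) + 1L]] <- rbind(
      row("LT_N", noisy(mean_ltn)),
      row("LT_0N", noisy(mean_lt0)),
      row("ST_0N_subplot", noisy(mean_st0)),
      row("ST_15N_subplot", noisy(mean_ltn), n15_rate = cfg$n_rate,
          n15_uptake = noisy(mean_u15))
    )
    cov[[length(cov) + 1L]] <- data.frame(
      site_id = site,
      gdd = signif(stats::runif(1, 1400, 2600), 6),
      temp_seasonality = signif(stats::runif(1, 4.5, 8.5), 6),
      aridity = signif(stats::runif(1, 0.7, 1.3), 6),
      crop = "winter_wheat",
      duration_years = tt,
      avg_n_rate = cfg$n_rate,
      clay_pct = signif(stats::runif(1, 15, 28), 6),
      method = "isotope15N",
      residue_retained = FALSE,
      stringsAsFactors = FALSE
    )
  }
  lte_dataset(do.call(rbind, obs), do.call(rbind, cov))
}

## Seeds the RNG for a reproducible block and returns a restorer for the
## caller's RNG state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

## Fixed design of the study-like fixture: 9 heterogeneous sites, 66 analysis
## records. Sites RO, IC, IS offer both first-season methods (each of their
## site-years yields two records); the rest offer one. Crops, durations, N
## rates and clay contents span the ranges reported for temperate cereal
## LTEs (durations 5-141 yr, N rates 34-269 kg N/ha, clay 15-28%).
STUDY_DESIGN <- data.frame(
  site_id  = c("BB", "RO", "OK", "MO", "SA", "IC", "IS", "KI", "HF"),
  crop     = c("winter_wheat", "winter_wheat", "winter_wheat", "maize",
               "maize", "maize", "maize", "winter_barley", "spring_barley"),
  methods  = c("isotope15N", "both", "isotope15N", "isotope15N",
               "isotope15N", "both", "both", "isotope15N", "subplot"),
  n_years  = c(9L, 3L, 8L, 8L, 7L, 3L, 2L, 9L, 9L),
  start_yr = c(1980L, 1992L, 1989L, 1994L, 1977L, 2013L, 2014L, 1991L, 1970L),
  n_rate   = c(192, 150, 90, 200, 269, 180, 160, 120, 34),
  duration = c(140L, 16L, 21L, 12L, 5L, 16L, 16L, 9L, 120L),
  clay     = c(28, 27, 20, 24, 15, 20, 15, 15, 22),
  residue  = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
  gdd      = c(2050, 2000, 2500, 2450, 2600, 2300, 2350, 1900, 2050),
  seasonal = c(5.2, 5.4, 8.9, 9.4, 8.6, 10.2, 10.0, 6.1, 5.2),
  aridity  = c(1.05, 1.00, 0.72, 0.95, 1.10, 0.98, 0.92, 1.15, 1.05),
  re1_base = c(0.40, 0.48, 0.36, 0.50, 0.42, 0.52, 0.47, 0.44, 0.38),
  native   = c(48, 45, 36, 55, 42, 60, 52, 40, 35),
  reps     = c(3L, 3L, 2L, 4L, 2L, 4L, 4L, 3L, 3L),
  stringsAsFactors = FALSE
)

#' Study-like synthetic fixture: 9 sites, 66 analysis records
#'
#' Generates a heterogeneous multi-experiment dataset emulating the
#' structure of a temperate-cereal LTE compilation: nine sites with
#' differing crops, durations (5-140 yr), N rates (34-269 kg N/ha/yr), clay
#' contents and climates; three sites offer both first-season methods (so
#' their site-years each yield two analysis records), giving exactly 66
#' records. Record-level legacy effects are drawn as
#' `0.244 + site effect + year effect + noise` with site SD 0.10, year SD
#' 0.05 and record SD `0.08 / sqrt(weight)`, so the designed true mean
#' legacy effect is 0.244 of the annual N rate; first-season recoveries
#' scatter around site-specific bases whose record-weighted average is
#' about 0.43.
#'
#' @param seed integer seed.
#' @param delta15_bias optional proportional under-recovery of the 15N
#'   method (default 0: the two methods differ only by noise).
#' @return an [lte_dataset()] which [build_recovery_table()] turns into 66
#'   records across 9 sites.
#' @export
make_study_like_dataset <- function(seed = 1, delta15_bias = 0) {
  rng <- local_rng(seed)
  on.exit(rng())
  design <- STUDY_DESIGN

  true_mean <- 0.244
  sigma_site <- 0.10
  sigma_year <- 0.05
  sigma_rec <- 0.08
  re1_year_sd <- 0.03

  u_site <- stats::rnorm(nrow(design), 0, sigma_site)
  all_years <- sort(unique(unlist(
    Map(function(s, k) seq(s, length.out = k), design$start_yr,
        design$n_years))))
  u_year <- stats::setNames(stats::rnorm(length(all_years), 0, sigma_year),
                            all_years)

  obs <- list()
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    w <- d$reps  # n_years_pooled = 1 throughout
    for (yr in seq(d$start_yr, length.out = d$n_years)) {
      re1 <- d$re1_base + stats::rnorm(1, 0, re1_year_sd)
      delta <- true_mean + u_site[i] + u_year[[as.character(yr)]] +
        stats::rnorm(1, 0, sigma_rec / sqrt(w))
      u0n_lt <- d$native + stats::rnorm(1, 0, 3)

      has_sub <- d$methods %in% c("subplot", "both")
      has_iso <- d$methods %in% c("isotope15N", "both")
      ## the KI-like experiment alternates winter wheat and winter barley
      ## in its rotation, so crop varies within that site
      crop_yr <- if (d$site_id == "KI" && yr %% 2 == 0) "winter_wheat" else
        d$crop

      ## primary method defines RE^LT and the fertilised-plot uptake
      re_lt_true <- re1 + delta
      u_ltn <- u0n_lt + re_lt_true * d$n_rate
      rows <- list(
        study_row(d, yr, crop_yr, "LT_N", u_ltn),
        study_row(d, yr, crop_yr, "LT_0N", u0n_lt)
      )
      if (has_sub) {
        rows[[length(rows) + 1L]] <-
          study_row(d, yr, crop_yr, "ST_0N_subplot", u_ltn - re1 * d$n_rate)
      }
      if (has_iso) {
        ## the 15N estimate of first-season recovery differs from the
        ## subplot estimate by method noise and any systematic bias
        re1_iso <- (re1 + stats::rnorm(1, 0, 0.03 * has_sub)) *
          (1 - delta15_bias)
        rows[[length(rows) + 1L]] <-
          study_row(d, yr, crop_yr, "ST_15N_subplot", u_ltn,
                    n15_rate = d$n_rate, n15_uptake = re1_iso * d$n_rate)
      }
      obs[[length(obs) + 1L]] <- do.call(rbind, rows)
    }
  }

  cov <- data.frame(
    site_id = design$site_id,
    gdd = design$gdd,
    temp_seasonality = design$seasonal,
    aridity = design$aridity,
    crop = design$crop,
    duration_years = design$duration,
    avg_n_rate = design$n_rate,
    clay_pct = design$clay,
    method = ifelse(design$methods == "both", "subplot", design$methods),
    residue_retained = design$residue,
    stringsAsFactors = FALSE
  )
  lte_dataset(do.call(rbind, obs), cov)
}

study_row <- function(d, yr, crop, treatment, n_uptake, n15_rate = NA_real_,
                      n15_uptake = NA_real_) {
  data.frame(
    site_id = d$site_id, year = as.integer(yr), crop = crop,
    treatment = treatment, n_rate = d$n_rate, n15_rate = n15_rate,
    n_uptake = signif(max(n_uptake, 0), 6),
    n15_uptake = if (is.na(n15_uptake)) NA_real_ else
      signif(max(n15_uptake, 0), 6),
    n_field_reps = d$reps, n_years_pooled = 1L,
    stringsAsFactors = FALSE
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("Synthetic LTE config: %d site(s) x %d season(s), %g kg N/ha/yr\n",
              x$n_sites, x$years_per_site, x$n_rate))
  cat(sprintf("  r1 %.2f, rho %.2f, schedule m1 %.2f / m2 %.2f / later %.2f, e_min %.2f\n",
              x$r1, x$rho, x$m1, x$m2, x$m_later, x$e_min))
  cat(sprintf("  native supply %g -> %g kg N/ha (k = %g/yr)\n",
              x$s0, x$s_min, x$k_dep))
  cat(sprintf("  SDs site %g / year %g / obs %g kg N/ha; 15N bias %g; seed %d\n",
              x$sigma_site, x$sigma_year, x$sigma_obs, x$delta15_bias,
              x$seed))
  invisible(x)
}
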