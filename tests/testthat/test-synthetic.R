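test_that("generator configuration invariants are enforced", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(r1 = 0.8, rho = 0.4), "r1 \\+ rho")
  expect_error(synthetic_config(m1 = 1.2), "m1")
  expect_error(synthetic_config(sigma_obs = -1), "sigma_obs")
  expect_error(synthetic_config(n_rate = 0), "n_rate")
  expect_error(synthetic_config(delta15_bias = 2), "delta15_bias")
})

test_that("remineralised flux follows the cohort-age schedule", {
  cfg <- synthetic_config()  # r1 0.45, rho 0.30, n_rate 100
  expect_equal(legacy_flux(cfg, 1), 0)   # no aged cohorts yet
  expect_equal(legacy_flux(cfg, 2), 10)  # one cohort at age 1: 0.10 x 100
  expect_error(legacy_flux(cfg, 0), "t must be")

  # independent year-by-year forward accumulation over all cohorts
  forward <- function(cfg, t) {
    pools <- numeric(0)  # retained pool per cohort, updated each season
    flux_t <- 0
    for (season in seq_len(t)) {
      released <- 0
      if (length(pools)) {
        age <- season - seq_along(pools)
        for (j in seq_along(pools)) {
          f <- if (age[j] == 1) min(cfg$m1 * cfg$n_rate, pools[j])
          else if (age[j] == 2) cfg$m2 * pools[j]
          else cfg$m_later * pools[j]
          pools[j] <- pools[j] - f
          released <- released + f
        }
      }
      if (season == t) flux_t <- released
      pools <- c(pools, cfg$rho * cfg$n_rate)  # this season's new cohort
    }
    flux_t
  }
  for (t in c(2, 3, 5, 16, 40)) {
    expect_equal(legacy_flux(cfg, t), forward(cfg, t), tolerance = 1e-12)
  }
  expect_equal(legacy_flux(cfg, 16) / cfg$n_rate, 0.13, tolerance = 0.01)
})

test_that("cohort N is conserved: cumulative release never exceeds retention", {
  cfg <- synthetic_config(m1 = 0.29, rho = 0.30)  # m1 close to the pool cap
  for (t in c(2, 10, 60, 200)) {
    expect_lte(legacy_flux(cfg, t), (t - 1) * cfg$rho * cfg$n_rate + 1e-9)
  }
  # a single cohort's lifetime release approaches but never passes its pool
  sched_flux <- vapply(2:300, function(t) legacy_flux(cfg, t) -
                         legacy_flux(cfg, t - 1), numeric(1))
  expect_true(all(diff(vapply(2:300, function(t) legacy_flux(cfg, t),
                              numeric(1))) > -1e-12))
})

test_that("the noise-free legacy effect is monotone, bounded and conserves N", {
  cfg <- synthetic_config()
  expect_equal(expected_delta_re(cfg, 1), 0)
  vals <- vapply(1:200, function(t) expected_delta_re(cfg, t), numeric(1))
  expect_true(all(diff(vals) >= -1e-12))          # monotone in t
  expect_true(all(vals <= cfg$e_min * cfg$rho + 1e-12))
  # asymptotically every pool mineralises: limit e_min * rho
  expect_equal(expected_delta_re(cfg, 2000), cfg$e_min * cfg$rho,
               tolerance = 1e-6)
  # monotone in rho, zero when rho = 0
  lo <- synthetic_config(rho = 0.1)
  expect_lte(expected_delta_re(lo, 16), expected_delta_re(cfg, 16))
  none <- synthetic_config(rho = 0)
  expect_equal(expected_delta_re(none, 16), 0)
})

test_that("noise-free simulation reproduces the generator truth exactly", {
  cfg <- synthetic_config(sigma_site = 0, sigma_year = 0, sigma_obs = 0)
  tab <- build_recovery_table(simulate_lte(cfg))
  expect_equal(tab$re_1st[tab$method == "subplot"], cfg$r1,
               tolerance = 1e-12)
  expect_equal(tab$re_1st[tab$method == "isotope15N"], cfg$r1,
               tolerance = 1e-12)
  truth <- expected_delta_re(cfg, cfg$years_per_site)
  expect_equal(tab$delta_re, rep(truth, 2), tolerance = 1e-12)
})

test_that("a 15N under-recovery bias moves the method contrast by bias x r1", {
  cfg <- synthetic_config(sigma_site = 0, sigma_year = 0, sigma_obs = 0,
                          delta15_bias = 0.1)
  tab <- build_recovery_table(simulate_lte(cfg))
  d_iso <- tab$delta_re[tab$method == "isotope15N"]
  d_sub <- tab$delta_re[tab$method == "subplot"]
  expect_equal(d_iso - d_sub, cfg$delta15_bias * cfg$r1, tolerance = 1e-12)
})

test_that("simulation is reproducible and leaves the caller's RNG alone", {
  cfg <- synthetic_config(n_sites = 3, seed = 9)
  d1 <- simulate_lte(cfg)
  set.seed(123)
  ref <- rnorm(1)
  set.seed(123)
  d2 <- simulate_lte(cfg)
  expect_identical(d1, d2)
  expect_identical(rnorm(1), ref)  # RNG state restored around simulation
})

test_that("the pipeline legacy effect is an unbiased estimate of the truth", {
  cfg0 <- synthetic_config()
  truth <- expected_delta_re(cfg0, cfg0$years_per_site)
  est <- vapply(seq_len(500), function(i) {
    cfg <- synthetic_config(seed = 10000 + i)
    tab <- build_recovery_table(simulate_lte(cfg))
    mean(tab$delta_re[tab$method == "subplot"])
  }, numeric(1))
  expect_lt(abs(mean(est) - truth), 0.005)
})

test_that("the study-like fixture has the designed shape", {
  ds <- make_study_like_dataset(seed = 5)
  tab <- build_recovery_table(ds)
  expect_equal(nrow(tab), 66)
  expect_equal(length(unique(tab$site_id)), 9)
  expect_setequal(unique(tab$method), c("isotope15N", "subplot"))
  expect_true(all(tab$n_rate >= 34 & tab$n_rate <= 269))
  expect_true(all(tab$re_1st > 0.2 & tab$re_1st < 0.7))
  # paired site-years contribute one record per method
  key <- paste(tab$site_id, tab$year)
  expect_equal(sum(table(key) == 2), 8)
  expect_equal(max(table(key)), 2)
  # the fixture is seed-reproducible
  expect_identical(make_study_like_dataset(seed = 5), ds)
})
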