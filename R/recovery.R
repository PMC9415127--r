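#' Long-term apparent N recovery
#'
#' Fraction of the annually applied fertiliser N recovered in aboveground
#' crop biomass after many years of sustained application, taking the
#' never-fertilised long-term control as reference:
#' \deqn{RE^{LT} = (U^{N,LT} - U^{0N,LT}) / N_{rate}.}
#' It includes uptake of fertiliser N applied in earlier seasons that was
#' retained in the soil and remineralised, so values above 1 are legal and
#' observed in practice (the increment in uptake can exceed one year's
#' application); negative values can arise from noise and are retained.
#'
#' @param u_n_lt annual N uptake on the long-term fertilised plot (kg N/ha).
#' @param u_0n_lt annual N uptake on the long-term unfertilised control
#'   (kg N/ha).
#' @param n_rate annual N application rate on the fertilised plot (kg N/ha).
#' @return recovery as a fraction of `n_rate` (dimensionless).
#' @examples
#' re_lt(160, 60, 200)  # 0.50
#' @export
re_lt <- function(u_n_lt, u_0n_lt, n_rate) {
  check_rate(n_rate, "n_rate")
  (u_n_lt - u_0n_lt) / n_rate
}

#' First-season N recovery by the withheld-N subplot method
#'
#' Estimates the fraction of this season's fertiliser N taken up this season
#' by comparing the long-term fertilised plot with a subplot inside it on
#' which N was withheld for the observation year:
#' \deqn{RE^{1st} = (U^{N,LT} - U^{0N,ST}) / N_{rate}.}
#'
#' @param u_n_lt annual N uptake on the long-term fertilised plot (kg N/ha).
#' @param u_0n_st N uptake on the short-term withheld-N subplot (kg N/ha).
#' @inheritParams re_lt
#' @return recovery as a fraction of `n_rate`.
#' @examples
#' re_1st_subplot(160, 80, 200)  # 0.40
#' @export
re_1st_subplot <- function(u_n_lt, u_0n_st, n_rate) {
  check_rate(n_rate, "n_rate")
  (u_n_lt - u_0n_st) / n_rate
}

#' First-season N recovery by 15N labelling
#'
#' Fraction of isotope-labelled fertiliser N recovered in aboveground biomass
#' in the year of application: labelled uptake divided by labelled amount
#' applied. Assumes 14N and 15N undergo the same transformations; added
#' nitrogen interactions (pool substitution, priming) can bias this method
#' downwards relative to the subplot method.
#'
#' @param u15_uptake labelled N uptake (kg 15N/ha).
#' @param n15_rate labelled N applied (kg 15N/ha).
#' @return recovery as a fraction of `n15_rate`.
#' @examples
#' re_1st_15n(47, 100)  # 0.47
#' @export
re_1st_15n <- function(u15_uptake, n15_rate) {
  check_rate(n15_rate, "n15_rate")
  u15_uptake / n15_rate
}

#' Delta recovery: the legacy effect
#'
#' \deqn{\Delta RE = RE^{LT} - RE^{1st},} the additional recovery of
#' fertiliser N beyond the season of application, expressed as a fraction of
#' the annual N rate. Negative values (long-term recovery below first-season
#' recovery) are legal and retained.
#'
#' @param re_lt_val long-term recovery (fraction).
#' @param re_1st_val first-season recovery (fraction).
#' @return the legacy effect as a fraction of the annual N rate.
#' @examples
#' delta_re(0.66, 0.44)  # 0.22
#' @export
delta_re <- function(re_lt_val, re_1st_val) {
  re_lt_val - re_1st_val
}

#' Delta recovery computed directly from withheld-N uptakes
#'
#' Substituting the definitions of long-term and subplot first-season
#' recovery into the legacy-effect difference cancels the fertilised-plot
#' uptake:
#' \deqn{\Delta RE = (U^{0N,ST} - U^{0N,LT}) / N_{rate},}
#' i.e. the extra N taken up on a previously fertilised plot in a season
#' without N, compared with the never-fertilised control, per unit of the
#' historical annual rate. For any consistent inputs this equals the
#' two-step route through the recovery fractions exactly.
#'
#' @param u_0n_st N uptake on the withheld-N subplot (kg N/ha).
#' @param u_0n_lt N uptake on the long-term unfertilised control (kg N/ha).
#' @param n_rate the historical annual N rate of the fertilised plot
#'   (kg N/ha).
#' @return the legacy effect as a fraction of the annual N rate.
#' @examples
#' # a withheld-N season: 29 kg extra uptake on a plot historically given
#' # 192 kg N/ha
#' delta_re_withheld(89, 60, 192)  # 0.151
#' @export
delta_re_withheld <- function(u_0n_st, u_0n_lt, n_rate) {
  check_rate(n_rate, "n_rate")
  (u_0n_st - u_0n_lt) / n_rate
}

#' Legacy effect rescaled to the N not recovered in the first season
#'
#' Expresses the legacy effect as a fraction of the N that was *not* taken up
#' in the season of application, \eqn{\Delta RE / (1 - RE^{1st})}, rather than
#' of the N rate. Undefined when first-season recovery reaches 1.
#'
#' @param delta legacy effect (fraction of N rate).
#' @param re_1st_val first-season recovery (fraction), must be < 1.
#' @return rescaled legacy effect (dimensionless fraction).
#' @export
delta_re_scaled <- function(delta, re_1st_val) {
  if (any(re_1st_val >= 1)) {
    stop("delta_re_scaled is undefined for re_1st >= 1", call. = FALSE)
  }
  delta / (1 - re_1st_val)
}

#' Relative increase in crop N uptake from soil
#'
#' Compares the legacy effect with the soil-derived N uptake of the
#' unfertilised control:
#' \deqn{100 \cdot \Delta RE \cdot N_{rate} / U^{0N} \ (\%),}
#' the percentage by which N uptake from soil is higher on the long-term
#' fertilised plot than on the control. Used to contrast the (large) relative
#' increase in soil N *supply* with the (small) relative increase in total
#' soil N *stock*.
#'
#' @param delta legacy effect (fraction of N rate).
#' @param n_rate annual N rate (kg N/ha).
#' @param u_0n N uptake on the unfertilised control (kg N/ha), must be > 0.
#' @return percentage increase in soil N uptake.
#' @examples
#' relative_soil_n_uptake_increase(0.151, 192, 60)  # 48.3
#' @export
relative_soil_n_uptake_increase <- function(delta, n_rate, u_0n) {
  if (any(u_0n <= 0)) stop("u_0n must be > 0", call. = FALSE)
  delta * n_rate / u_0n * 100
}

check_rate <- function(x, name) {
  if (any(is.na(x)) || any(x <= 0)) {
    stop(name, " must be > 0", call. = FALSE)
  }
  invisible(x)
}

#' Assemble the recovery analysis table from an LTE dataset
#'
#' Builds one analysis record per (site, year, first-season method): each
#' record carries first-season recovery, long-term recovery, the legacy
#' effect `delta_re`, the replicate weight
#' `n_years_pooled * n_field_reps`, and the site co-variables. A site-year
#' offering both a withheld-N subplot and a 15N subplot yields two records
#' (one per method) sharing the same long-term recovery. Records with
#' negative `delta_re` or long-term recovery above 1 are retained and
#' flagged, not dropped.
#'
#' Experiments whose design permits only a direct legacy-effect estimate
#' (no separable first-season and long-term recoveries) enter through
#' `direct`, a data.frame of externally computed values with columns
#' `site_id`, `year`, `crop`, `delta_re`, `weight`; these records get
#' method `"direct_delta"` and `NA` recovery parts.
#'
#' The site co-variables are joined by `site_id`; `duration_years` is taken
#' to describe the site's first sampling year, so records sampled in later
#' years of the same experiment get correspondingly longer durations.
#'
#' @param ds an [lte_dataset()].
#' @param direct optional data.frame of direct legacy-effect records (see
#'   Details).
#' @return data.frame of class `recovery_table`, one row per analysis
#'   record, with columns `site_id`, `year`, `crop`, `method`, `n_rate`,
#'   `re_1st`, `re_lt`, `delta_re`, `delta_re_scaled`, `weight`, `flag`,
#'   and the co-variable columns joined by `site_id`.
#' @export
build_recovery_table <- function(ds, direct = NULL) {
  stopifnot(inherits(ds, "lte_dataset"))
  obs <- ds$observations
  key <- paste(obs$site_id, obs$year, sep = "\r")
  records <- list()

  for (k in unique(key[obs$treatment == "LT_N"])) {
    rows <- obs[key == k, , drop = FALSE]
    ltn <- rows[rows$treatment == "LT_N", , drop = FALSE]
    lt0 <- rows[rows$treatment == "LT_0N", , drop = FALSE]
    relt <- re_lt(ltn$n_uptake, lt0$n_uptake, ltn$n_rate)
    weight <- ltn$n_years_pooled * ltn$n_field_reps

    emit <- function(method, re1) {
      d <- delta_re(relt, re1)
      data.frame(
        site_id = ltn$site_id, year = ltn$year, crop = ltn$crop,
        method = method, n_rate = ltn$n_rate,
        re_1st = re1, re_lt = relt, delta_re = d,
        delta_re_scaled = if (re1 < 1) delta_re_scaled(d, re1) else NA_real_,
        weight = weight,
        flag = flag_record(relt, d),
        stringsAsFactors = FALSE
      )
    }

    st0 <- rows[rows$treatment == "ST_0N_subplot", , drop = FALSE]
    if (nrow(st0)) {
      records[[length(records) + 1L]] <-
        emit("subplot", re_1st_subplot(ltn$n_uptake, st0$n_uptake, ltn$n_rate))
    }
    st15 <- rows[rows$treatment == "ST_15N_subplot", , drop = FALSE]
    if (nrow(st15)) {
      records[[length(records) + 1L]] <-
        emit("isotope15N", re_1st_15n(st15$n15_uptake, st15$n15_rate))
    }
  }

  if (!is.null(direct) && nrow(direct)) {
    need <- c("site_id", "year", "crop", "delta_re", "weight")
    missing <- setdiff(need, names(direct))
    if (length(missing)) {
      stop("direct records missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    nr <- if ("n_rate" %in% names(direct)) direct$n_rate else NA_real_
    records[[length(records) + 1L]] <- data.frame(
      site_id = as.character(direct$site_id), year = as.integer(direct$year),
      crop = as.character(direct$crop), method = "direct_delta",
      n_rate = nr, re_1st = NA_real_, re_lt = NA_real_,
      delta_re = direct$delta_re, delta_re_scaled = NA_real_,
      weight = direct$weight, flag = "", stringsAsFactors = FALSE
    )
  }

  if (!length(records)) {
    stop("dataset contains no complete site-year pairing with a short-term ",
         "subplot", call. = FALSE)
  }
  tab <- do.call(rbind, records)
  rownames(tab) <- NULL

  cov <- ds$covariates
  idx <- match(tab$site_id, cov$site_id)
  if (anyNA(idx)) {
    stop("no covariates for site(s): ",
         paste(unique(tab$site_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  covcols <- setdiff(COV_COLUMNS, c("site_id", "crop", "method"))
  tab <- cbind(tab, cov[idx, covcols, drop = FALSE])
  rownames(tab) <- NULL
  ## duration_years in the covariate table refers to the site's first
  ## sampling year; records sampled later in the same experiment are
  ## correspondingly older
  first_year <- stats::ave(tab$year, tab$site_id, FUN = min)
  tab$duration_years <- tab$duration_years + (tab$year - first_year)
  class(tab) <- c("recovery_table", "data.frame")
  tab
}

flag_record <- function(relt, d) {
  flags <- character(0)
  if (!is.na(relt) && relt > 1) flags <- c(flags, "re_lt>1")
  if (!is.na(d) && d < 0) flags <- c(flags, "delta_re<0")
  paste(flags, collapse = ";")
}

#' @export
print.recovery_table <- function(x, ...) {
  cat(sprintf(
    "Recovery table: %d records, %d sites (%d by 15N, %d by subplot, %d direct)\n",
    nrow(x), length(unique(x$site_id)),
    sum(x$method == "isotope15N"), sum(x$method == "subplot"),
    sum(x$method == "direct_delta")))
  ok <- !is.na(x$delta_re)
  cat(sprintf("  delta_re: mean %.3f, range [%.3f, %.3f], %d/%d positive\n",
              mean(x$delta_re[ok]), min(x$delta_re[ok]), max(x$delta_re[ok]),
              sum(x$delta_re[ok] > 0), sum(ok)))
  invisible(x)
}

#' Write a recovery table to CSV
#'
#' @param tab a `recovery_table` from [build_recovery_table()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_recovery_table <- function(tab, path) {
  write_csv6(as.data.frame(tab), path)
  invisible(path)
}
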