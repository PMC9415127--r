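#' @keywords internal
"_PACKAGE"

## Column orders are part of the interchange contract: files written by
## write_dataset() are byte-stable given identical data.
OBS_COLUMNS <- c(
  "site_id", "year", "crop", "treatment", "n_rate", "n15_rate",
  "n_uptake", "n15_uptake", "n_field_reps", "n_years_pooled"
)

COV_COLUMNS <- c(
  "site_id", "gdd", "temp_seasonality", "aridity", "crop",
  "duration_years", "avg_n_rate", "clay_pct", "method", "residue_retained"
)

CROP_LEVELS <- c("winter_wheat", "spring_barley", "winter_barley", "maize",
                 "rotation")

TREATMENT_LEVELS <- c("LT_N", "LT_0N", "ST_0N_subplot", "ST_15N_subplot")

METHOD_LEVELS <- c("isotope15N", "subplot", "direct_delta")

#' Construct an LTE dataset
#'
#' Bundles plot observations from one or more long-term experiments (LTEs)
#' with their per-site co-variables and validates the experimental-design
#' invariants the recovery calculations rely on: every long-term fertilised
#' (`LT_N`) record must have a same-site, same-year long-term control
#' (`LT_0N`) partner, and every superimposed short-term subplot (`ST_0N_subplot`
#' or `ST_15N_subplot`) must sit inside such a complete long-term pairing,
#' because first-season and long-term recovery must refer to the same year of
#' observation.
#'
#' @param observations data.frame with one row per plot observation; required
#'   columns `site_id`, `year`, `crop`, `treatment`, `n_rate`, `n15_rate`,
#'   `n_uptake`, `n15_uptake`, `n_field_reps`, `n_years_pooled`. N rates and
#'   uptakes are in kg N/ha. `n15_rate`/`n15_uptake` are `NA` except on
#'   `ST_15N_subplot` rows. Control rows (`LT_0N`, `ST_0N_subplot`) carry the
#'   `n_rate` of their paired fertilised plot for bookkeeping but received no
#'   N in the observation year.
#' @param covariates data.frame keyed by `site_id` with columns `gdd`
#'   (growing degree days, degC day), `temp_seasonality` (degC),
#'   `aridity` (precipitation / potential evapotranspiration), `crop`,
#'   `duration_years`, `avg_n_rate` (kg N/ha/yr), `clay_pct`, `method`
#'   (the site's primary first-season recovery method), `residue_retained`
#'   (logical).
#' @return An object of class `lte_dataset`: a list with elements
#'   `observations` and `covariates`, both validated data.frames.
#' @seealso [read_dataset()], [write_dataset()], [build_recovery_table()]
#' @examples
#' obs <- data.frame(
#'   site_id = "site1", year = 2000L, crop = "winter_wheat",
#'   treatment = c("LT_N", "LT_0N", "ST_0N_subplot"),
#'   n_rate = 192, n15_rate = NA_real_,
#'   n_uptake = c(160, 55, 84), n15_uptake = NA_real_,
#'   n_field_reps = 3L, n_years_pooled = 1L
#' )
#' cov <- data.frame(
#'   site_id = "site1", gdd = 2200, temp_seasonality = 5.4, aridity = 1.05,
#'   crop = "winter_wheat", duration_years = 140, avg_n_rate = 192,
#'   clay_pct = 28, method = "subplot", residue_retained = FALSE
#' )
#' ds <- lte_dataset(obs, cov)
#' ds
#' @export
lte_dataset <- function(observations, covariates) {
  observations <- as.data.frame(observations, stringsAsFactors = FALSE)
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)

  missing_obs <- setdiff(OBS_COLUMNS, names(observations))
  if (length(missing_obs)) {
    stop("observations is missing column(s): ",
         paste(missing_obs, collapse = ", "), call. = FALSE)
  }
  missing_cov <- setdiff(COV_COLUMNS, names(covariates))
  if (length(missing_cov)) {
    stop("covariates is missing column(s): ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }

  observations <- observations[OBS_COLUMNS]
  covariates <- covariates[COV_COLUMNS]

  observations$site_id <- as.character(observations$site_id)
  observations$year <- as.integer(observations$year)
  observations$crop <- as.character(observations$crop)
  observations$treatment <- as.character(observations$treatment)
  for (col in c("n_rate", "n15_rate", "n_uptake", "n15_uptake")) {
    observations[[col]] <- as.numeric(observations[[col]])
  }
  observations$n_field_reps <- as.integer(observations$n_field_reps)
  observations$n_years_pooled <- as.integer(observations$n_years_pooled)

  covariates$site_id <- as.character(covariates$site_id)
  covariates$residue_retained <- as.logical(covariates$residue_retained)

  problems <- c(
    validate_observations(observations),
    validate_covariates(covariates),
    validate_pairings(observations)
  )
  if (length(problems)) {
    stop("invalid LTE dataset:\n", paste0("  - ", problems, collapse = "\n"),
         call. = FALSE)
  }

  rownames(observations) <- NULL
  rownames(covariates) <- NULL
  structure(list(observations = observations, covariates = covariates),
            class = "lte_dataset")
}

## Collects ALL violations rather than stopping at the first, so one pass over
## an input file reports every bad row.
validate_observations <- function(obs) {
  problems <- character(0)
  rowlab <- function(i) sprintf("observation row %d (%s, %s, %s)", i,
                                obs$site_id[i], obs$year[i], obs$treatment[i])
  for (i in seq_len(nrow(obs))) {
    if (is.na(obs$site_id[i]) || !nzchar(obs$site_id[i])) {
      problems <- c(problems, paste0(rowlab(i), ": empty site_id"))
    }
    if (is.na(obs$year[i])) {
      problems <- c(problems, paste0(rowlab(i), ": missing year"))
    }
    if (!obs$crop[i] %in% CROP_LEVELS) {
      problems <- c(problems, paste0(rowlab(i), ": unknown crop '",
                                     obs$crop[i], "'"))
    }
    if (!obs$treatment[i] %in% TREATMENT_LEVELS) {
      problems <- c(problems, paste0(rowlab(i), ": unknown treatment '",
                                     obs$treatment[i], "'"))
      next
    }
    if (is.na(obs$n_rate[i]) || obs$n_rate[i] < 0) {
      problems <- c(problems, paste0(rowlab(i), ": n_rate must be >= 0"))
    }
    if (is.na(obs$n_uptake[i]) || obs$n_uptake[i] < 0) {
      problems <- c(problems, paste0(rowlab(i), ": n_uptake must be >= 0"))
    }
    if (obs$treatment[i] == "ST_15N_subplot") {
      if (is.na(obs$n15_rate[i]) || obs$n15_rate[i] <= 0) {
        problems <- c(problems,
                      paste0(rowlab(i), ": ST_15N_subplot needs n15_rate > 0"))
      }
      ## n15_uptake > n15_rate is NOT rejected: measurement noise can push
      ## labelled uptake above the applied amount. Negative uptake is.
      if (is.na(obs$n15_uptake[i]) || obs$n15_uptake[i] < 0) {
        problems <- c(problems,
                      paste0(rowlab(i), ": n15_uptake must be >= 0"))
      }
    } else {
      if (!is.na(obs$n15_rate[i]) || !is.na(obs$n15_uptake[i])) {
        problems <- c(problems,
                      paste0(rowlab(i),
                             ": n15 fields only allowed on ST_15N_subplot"))
      }
    }
    if (is.na(obs$n_field_reps[i]) || obs$n_field_reps[i] < 1) {
      problems <- c(problems, paste0(rowlab(i), ": n_field_reps must be >= 1"))
    }
    if (is.na(obs$n_years_pooled[i]) || obs$n_years_pooled[i] < 1) {
      problems <- c(problems,
                    paste0(rowlab(i), ": n_years_pooled must be >= 1"))
    }
  }
  key <- paste(obs$site_id, obs$year, obs$treatment, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    problems <- c(problems,
                  sprintf("duplicate (site_id, year, treatment): %s",
                          paste(unique(gsub("\r", "/", key[dup])),
                                collapse = "; ")))
  }
  problems
}

validate_covariates <- function(cov) {
  problems <- character(0)
  rowlab <- function(i) sprintf("covariate row %d (%s)", i, cov$site_id[i])
  for (i in seq_len(nrow(cov))) {
    if (!is.na(cov$aridity[i]) && cov$aridity[i] <= 0) {
      problems <- c(problems, paste0(rowlab(i), ": aridity must be > 0"))
    }
    if (!is.na(cov$clay_pct[i]) &&
        (cov$clay_pct[i] < 0 || cov$clay_pct[i] > 100)) {
      problems <- c(problems, paste0(rowlab(i), ": clay_pct outside [0, 100]"))
    }
    if (!is.na(cov$duration_years[i]) && cov$duration_years[i] < 1) {
      problems <- c(problems, paste0(rowlab(i), ": duration_years must be >= 1"))
    }
    if (!cov$crop[i] %in% CROP_LEVELS) {
      problems <- c(problems, paste0(rowlab(i), ": unknown crop '",
                                     cov$crop[i], "'"))
    }
    if (!cov$method[i] %in% METHOD_LEVELS) {
      problems <- c(problems, paste0(rowlab(i), ": unknown method '",
                                     cov$method[i], "'"))
    }
  }
  if (anyDuplicated(cov$site_id)) {
    problems <- c(problems, "duplicate site_id in covariates")
  }
  problems
}

## Design invariants: a fertilised long-term plot needs its never-fertilised
## control in the same year, and any superimposed subplot needs both.
validate_pairings <- function(obs) {
  problems <- character(0)
  key <- function(trt) paste(obs$site_id[obs$treatment == trt],
                             obs$year[obs$treatment == trt])
  ltn <- key("LT_N")
  lt0 <- key("LT_0N")
  for (k in setdiff(ltn, lt0)) {
    problems <- c(problems,
                  sprintf("LT_N record without LT_0N partner: %s", k))
  }
  for (trt in c("ST_0N_subplot", "ST_15N_subplot")) {
    st <- key(trt)
    for (k in setdiff(st, intersect(ltn, lt0))) {
      problems <- c(problems,
                    sprintf("%s record without complete LT_N/LT_0N pairing: %s",
                            trt, k))
    }
  }
  problems
}

#' @export
print.lte_dataset <- function(x, ...) {
  obs <- x$observations
  n_pairs <- length(intersect(
    paste(obs$site_id[obs$treatment == "LT_N"], obs$year[obs$treatment == "LT_N"]),
    paste(obs$site_id[obs$treatment == "LT_0N"], obs$year[obs$treatment == "LT_0N"])
  ))
  cat("LTE dataset\n")
  cat(sprintf("  %d plot observations, %d sites, %d site-year pairings\n",
              nrow(obs), length(unique(obs$site_id)), n_pairs))
  cat(sprintf("  treatments: %s\n",
              paste(sort(unique(obs$treatment)), collapse = ", ")))
  cat(sprintf("  years %d-%d, N rates %.0f-%.0f kg N/ha\n",
              min(obs$year), max(obs$year),
              min(obs$n_rate), max(obs$n_rate)))
  invisible(x)
}

#' Read an LTE dataset from CSV files
#'
#' Reads the long-format plot-observation table and the per-site co-variable
#' table, optionally renaming columns from a user schema, and validates the
#' result (see [lte_dataset()]). All validation failures are reported at
#' once, with row numbers.
#'
#' @param obs_path path to the observations CSV (one row per plot observation).
#' @param cov_path path to the covariates CSV (one row per site).
#' @param schema optional named character vector mapping this package's
#'   column names to the names used in the files, e.g.
#'   `c(site_id = "Trial", n_uptake = "Nupt_kg_ha")`.
#' @return An [lte_dataset()].
#' @export
read_dataset <- function(obs_path, cov_path, schema = NULL) {
  if (!file.exists(obs_path)) stop("file not found: ", obs_path, call. = FALSE)
  if (!file.exists(cov_path)) stop("file not found: ", cov_path, call. = FALSE)
  obs <- utils::read.csv(obs_path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  cov <- utils::read.csv(cov_path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    obs <- apply_schema(obs, schema)
    cov <- apply_schema(cov, schema)
  }
  lte_dataset(obs, cov)
}

apply_schema <- function(df, schema) {
  for (ours in names(schema)) {
    theirs <- schema[[ours]]
    if (theirs %in% names(df)) names(df)[names(df) == theirs] <- ours
  }
  df
}

#' Write an LTE dataset to CSV files
#'
#' Writes the two interchange files with a fixed column order, '.' decimal
#' separator, UTF-8 encoding and numerics formatted at 6 significant digits,
#' so that identical datasets produce byte-identical files and
#' `read_dataset()` of the output reproduces the input exactly.
#'
#' @param ds an [lte_dataset()].
#' @param obs_path,cov_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_dataset <- function(ds, obs_path, cov_path) {
  stopifnot(inherits(ds, "lte_dataset"))
  write_csv6(ds$observations, obs_path)
  write_csv6(ds$covariates, cov_path)
  invisible(c(obs_path, cov_path))
}

## Deterministic CSV writer: 6 significant digits, no scientific notation for
## the magnitudes that occur here, empty string for NA.
write_csv6 <- function(df, path) {
  out <- df
  for (col in names(out)) {
    x <- out[[col]]
    if (is.double(x)) {
      out[[col]] <- ifelse(is.na(x), "",
                           trimws(formatC(signif(x, 6), format = "fg",
                                          digits = 6)))
    } else if (is.logical(x)) {
      out[[col]] <- ifelse(is.na(x), "", ifelse(x, "TRUE", "FALSE"))
    } else {
      out[[col]] <- ifelse(is.na(x), "", as.character(x))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  if (nrow(out)) {
    lines <- do.call(paste, c(unname(as.list(out)), list(sep = ",")))
    writeLines(lines, con)
  }
}
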