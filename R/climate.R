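#' Growing degree days
#'
#' Accumulated temperature sum of daily mean temperature above a base
#' temperature over one year:
#' \deqn{GDD = \sum_d \max(T_d - T_{base}, 0).}
#' The base temperature defaults to 0 degC, the common convention for
#' small-grain cereals; it is configuration, not ground truth.
#'
#' @param daily_mean_temp numeric vector of daily mean temperatures (degC),
#'   typically length 365/366.
#' @param base_temp base temperature (degC), default 0.
#' @return degree days (degC day).
#' @examples
#' growing_degree_days(c(10, 5, -2))  # 15
#' @export
growing_degree_days <- function(daily_mean_temp, base_temp = 0) {
  if (!length(daily_mean_temp)) {
    stop("daily temperature series is empty", call. = FALSE)
  }
  if (anyNA(daily_mean_temp)) {
    stop("daily temperature series contains NA", call. = FALSE)
  }
  sum(pmax(daily_mean_temp - base_temp, 0))
}

#' Aridity index
#'
#' Annual total precipitation divided by annual total potential
#' evapotranspiration (both mm). Values below 1 indicate that potential
#' evaporative demand exceeds rainfall.
#'
#' @param annual_precip annual precipitation (mm).
#' @param annual_pet annual potential evapotranspiration (mm), must be > 0.
#' @return dimensionless index.
#' @examples
#' aridity_index(600, 800)  # 0.75
#' @export
aridity_index <- function(annual_precip, annual_pet) {
  if (any(is.na(annual_pet)) || any(annual_pet <= 0)) {
    stop("annual_pet must be > 0", call. = FALSE)
  }
  annual_precip / annual_pet
}

#' Temperature seasonality
#'
#' Standard deviation of the twelve monthly mean temperatures (sample SD,
#' divisor n - 1). Zero for a perfectly even climate, large for continental
#' climates.
#'
#' @param monthly_mean_temp numeric vector of exactly 12 monthly mean
#'   temperatures (degC).
#' @return seasonality (degC).
#' @export
temperature_seasonality <- function(monthly_mean_temp) {
  if (length(monthly_mean_temp) != 12 || anyNA(monthly_mean_temp)) {
    stop("monthly_mean_temp must be 12 non-missing values", call. = FALSE)
  }
  stats::sd(monthly_mean_temp)
}

#' Climate co-variables from a daily weather series
#'
#' Computes the three climate-zone descriptors used as model co-variables
#' (growing degree days, temperature seasonality, aridity index) from a
#' daily weather table. Multi-year tables are handled by computing each
#' index per calendar year and averaging across years.
#'
#' @param weather data.frame with columns `date` (Date or parseable
#'   character), `daily_mean_temp` (degC), `precip` (mm/day), `pet`
#'   (mm/day).
#' @param base_temp base temperature for degree days (degC).
#' @return named list with `gdd`, `temp_seasonality`, `aridity`.
#' @export
climate_indices <- function(weather, base_temp = 0) {
  need <- c("date", "daily_mean_temp", "precip", "pet")
  missing <- setdiff(need, names(weather))
  if (length(missing)) {
    stop("weather is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  date <- as.Date(weather$date)
  yr <- as.integer(format(date, "%Y"))
  mo <- as.integer(format(date, "%m"))
  per_year <- lapply(split(seq_along(yr), yr), function(i) {
    monthly <- tapply(weather$daily_mean_temp[i], mo[i], mean)
    if (length(monthly) != 12) {
      stop("each weather year must cover all 12 months", call. = FALSE)
    }
    list(
      gdd = growing_degree_days(weather$daily_mean_temp[i], base_temp),
      temp_seasonality = temperature_seasonality(as.numeric(monthly)),
      aridity = aridity_index(sum(weather$precip[i]), sum(weather$pet[i]))
    )
  })
  list(
    gdd = mean(vapply(per_year, `[[`, numeric(1), "gdd")),
    temp_seasonality = mean(vapply(per_year, `[[`, numeric(1),
                                   "temp_seasonality")),
    aridity = mean(vapply(per_year, `[[`, numeric(1), "aridity"))
  )
}
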