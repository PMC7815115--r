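#' Thornthwaite monthly potential evapotranspiration
#'
#' Classical Thornthwaite (1948) monthly PET with the day-length correction.
#' Months with mean temperature at or below 0 degC get PET = 0; the annual heat
#' index is accumulated over the warm months only.
#'
#' @param monthly_mean_temps numeric(12), mean air temperature per calendar
#'   month, degC (January first)
#' @param latitude degrees north; must satisfy `abs(latitude) <= 66.5`
#'   (the day-length formula breaks poleward of the polar circles)
#' @return numeric(12), potential evapotranspiration, mm per month
#' @examples
#' thornthwaite_pet(c(-16, -12, -3, 7, 15, 20, 23, 21, 14, 6, -4, -13), 44)
#' @export
thornthwaite_pet <- function(monthly_mean_temps, latitude) {
  if (length(monthly_mean_temps) != 12L) {
    stop("thornthwaite_pet: need exactly 12 monthly mean temperatures")
  }
  if (abs(latitude) > 66.5) {
    stop("thornthwaite_pet: |latitude| must be <= 66.5 degrees")
  }
  tw <- pmax(monthly_mean_temps, 0)
  heat_index <- sum((tw / 5)^1.514)
  if (heat_index <= 0) return(rep(0, 12))
  a <- 6.75e-7 * heat_index^3 - 7.71e-5 * heat_index^2 +
    1.792e-2 * heat_index + 0.49239
  pet <- ifelse(tw > 0, 16 * (10 * tw / heat_index)^a, 0)
  # day-length / month-length correction
  mid <- c(15, 46, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)
  ndays <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  decl <- 0.409 * sin(2 * pi * (284 + mid) / 365)
  phi <- latitude * pi / 180
  x <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
  daylen <- 24 / pi * acos(x)
  pet * (daylen / 12) * (ndays / 30)
}

#' Abiotic decomposition factor (DEFAC)
#'
#' The common climate scalar multiplying all pool decay rates:
#' `defac = f_T * f_W` with a capped Q10 temperature response
#' `f_T = min(1, q10^((tavg - t_ref)/10))` and a moisture response given by
#' the precipitation/PET ratio, bounded to `[0.1, 1]` (floor 0.1 also applies
#' when PET is zero, i.e. frozen months retain a trickle of decomposition).
#'
#' @param tavg monthly mean air temperature, degC
#' @param precip monthly precipitation, mm
#' @param pet monthly potential evapotranspiration, mm (>= 0)
#' @param params a [model_params()]
#' @return decomposition scalar in `[0, 1]` (vectorised over months)
#' @examples
#' abiotic_factor(20, 25, 100, model_params())  # 0.5 * 0.25 = 0.125
#' @export
abiotic_factor <- function(tavg, precip, pet, params = model_params()) {
  if (any(pet < 0)) stop("abiotic_factor: pet must be >= 0")
  f_t <- pmin(1, params$q10^((tavg - params$t_ref) / 10))
  f_w <- ifelse(pet > 0, pmin(1, pmax(0.1, precip / pet)), 0.1)
  f_t * f_w
}

#' Monthly plant production
#'
#' Potential production `prdx` scaled by a parabolic temperature response
#' `g_T = max(0, 1 - ((tavg - topt)/twidth)^2)` and the same moisture ratio as
#' [abiotic_factor()]. Zero outside the growing season.
#'
#' @param tavg monthly mean temperature, degC (`(tmin+tmax)/2`)
#' @param precip,pet monthly precipitation and PET, mm
#' @param params a [model_params()]
#' @param in_growing_season logical
#' @param topt,twidth optimum and width of the temperature response, degC
#' @param prdx_mult extra multiplier on `prdx` (calibration / fertiliser boost)
#' @return fixed carbon, g C m-2 month-1
#' @export
monthly_production <- function(tavg, precip, pet, params = model_params(),
                               in_growing_season = TRUE,
                               topt = 25, twidth = 15, prdx_mult = 1) {
  if (!in_growing_season) return(0)
  g_t <- pmax(0, 1 - ((tavg - topt) / twidth)^2)
  f_w <- ifelse(pet > 0, pmin(1, pmax(0.1, precip / pet)), 0.1)
  params$prdx * prdx_mult * g_t * f_w
}

#' Long-term mean monthly climate from a weather record
#'
#' Collapses a monthly weather series to 12 monthly normals (mean temperature
#' and precipitation), optionally over a reference window of years.
#'
#' @param weather data frame with columns `year, month, tmin_c, tmax_c,
#'   precip_mm`
#' @param years optional vector of years to average over (intersected with the
#'   record; defaults to the whole record)
#' @return list with `tavg` (numeric(12), degC) and `precip` (numeric(12), mm)
#' @export
climate_normals <- function(weather, years = NULL) {
  w <- validate_weather_frame(weather)
  if (!is.null(years)) {
    keep <- w$year %in% years
    if (any(keep)) w <- w[keep, ]
  }
  tavg <- (w$tmin_c + w$tmax_c) / 2
  list(tavg = as.numeric(tapply(tavg, w$month, mean)),
       precip = as.numeric(tapply(w$precip_mm, w$month, mean)))
}

# shared structural checks on a weather frame
validate_weather_frame <- function(weather) {
  need <- c("year", "month", "tmin_c", "tmax_c", "precip_mm")
  miss <- setdiff(need, names(weather))
  if (length(miss)) {
    stop("weather frame missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(weather$tmax_c < weather$tmin_c)) {
    stop("weather frame: tmax_c < tmin_c in some rows")
  }
  if (any(weather$precip_mm < 0)) stop("weather frame: negative precipitation")
  weather[order(weather$year, weather$month), , drop = FALSE]
}

# split a weather frame into complete calendar years (list of 12-row frames)
weather_years <- function(weather) {
  w <- validate_weather_frame(weather)
  yrs <- split(w, w$year)
  complete <- vapply(yrs, function(d) identical(sort(d$month), 1:12), TRUE)
  if (!any(complete)) stop("weather record contains no complete year")
  yrs[complete]
}
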