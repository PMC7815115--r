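# Five-pool monthly turnover core.
#
# Flow network (fractions of decayed carbon):
#   structural -> 30% respired; lignin share of the remainder to slow,
#                 the rest to active
#   metabolic  -> 55% respired; remainder to active
#   active     -> F_CO2 = 0.85 - 0.68*(silt+clay) respired; of the remainder,
#                 0.003 + 0.032*clay to passive, the rest to slow
#   slow       -> 55% respired; of the remainder, 0.003 + 0.009*clay to
#                 passive, the rest to active
#   passive    -> 55% respired; remainder to active
#
# Monthly decay uses the exact within-month exponential
#   D_i = C_i * (1 - exp(-k_i * defac * m_i / 12))
# so even the fast metabolic pool (k = 14.8 yr-1) cannot overshoot. m_i is the
# texture multiplier (active pool only: 1 - 0.75*(silt+clay)) times the
# cultivation multiplier (litter + active pools, in cultivated months only).
# All fractions are state-independent, so one month is an affine map of the
# pool vector -- a fact the spin-up exploits (see affine_year_map).

active_resp_frac <- function(site) 0.85 - 0.68 * (site$silt + site$clay)

texture_mult <- function(site) 1 - 0.75 * (site$silt + site$clay)

# Core monthly update. `residue_met`/`residue_str` are this month's litter
# inputs (g C m-2) already split; `fire_fraction` removes that share of both
# litter pools (combustion) before decay.
step_month_core <- function(state, defac, site, params,
                            residue_met = 0, residue_str = 0,
                            cultivated = FALSE, fire_fraction = 0) {
  s <- unclass(state)
  burned <- 0
  if (fire_fraction > 0) {
    burned <- fire_fraction * (s[["structural"]] + s[["metabolic"]])
    s[["structural"]] <- s[["structural"]] * (1 - fire_fraction)
    s[["metabolic"]] <- s[["metabolic"]] * (1 - fire_fraction)
  }
  cult <- if (cultivated) params$cultivation_mult else 1
  mult <- c(cult, cult, texture_mult(site) * cult, 1, 1)
  frac <- 1 - exp(-params$k * defac * mult / 12)
  d <- s * frac

  f_a <- active_resp_frac(site)
  to_pas_a <- 0.003 + 0.032 * site$clay  # of non-respired active decay
  to_pas_s <- 0.003 + 0.009 * site$clay  # of non-respired slow decay
  rf <- params$resp_frac

  resp <- rf[["structural"]] * d[["structural"]] +
    rf[["metabolic"]] * d[["metabolic"]] +
    f_a * d[["active"]] +
    rf[["slow"]] * d[["slow"]] +
    rf[["passive"]] * d[["passive"]]

  rem_str <- (1 - rf[["structural"]]) * d[["structural"]]
  rem_met <- (1 - rf[["metabolic"]]) * d[["metabolic"]]
  rem_act <- (1 - f_a) * d[["active"]]
  rem_slo <- (1 - rf[["slow"]]) * d[["slow"]]
  rem_pas <- (1 - rf[["passive"]]) * d[["passive"]]

  inflow <- c(
    structural = 0,
    metabolic = 0,
    active = rem_str * (1 - params$lignin_frac) + rem_met +
      rem_slo * (1 - to_pas_s) + rem_pas,
    slow = rem_str * params$lignin_frac + rem_act * (1 - to_pas_a),
    passive = rem_act * to_pas_a + rem_slo * to_pas_s
  )

  new <- s - d + inflow
  new[["structural"]] <- new[["structural"]] + residue_str
  new[["metabolic"]] <- new[["metabolic"]] + residue_met
  if (any(new < -1e-9)) {
    stop("step_month: negative pool after update (broken flow table)")
  }
  new[new < 0] <- 0
  flux <- c(residue_input = residue_met + residue_str,
            heterotrophic_respiration = resp,
            combustion_loss = burned,
            net_pool_change = sum(new) - sum(unclass(state)))
  list(state = as_pool_state(new), flux = flux)
}

#' Advance the pool state by one month
#'
#' Applies one month of decomposition and transfer through the five-pool flow
#' network under the supplied forcing, then adds the month's residue inputs.
#' Management events are passed in `events`: residue already produced by the
#' caller's crop/grassland logic, a cultivation flag, and a litter combustion
#' fraction for fire months.
#'
#' @param state a [pool_state()]
#' @param forcing list with `tmin`, `tmax`, `precip`, `pet` for the month
#' @param site a [site_params()]
#' @param params a [model_params()]
#' @param events list with any of `residue_metabolic`, `residue_structural`
#'   (g C m-2 entering litter this month), `cultivated` (logical),
#'   `fire_fraction` (fraction of litter combusted)
#' @return list with `state` (the new [pool_state()]) and `flux` (named vector:
#'   `residue_input`, `heterotrophic_respiration`, `combustion_loss`,
#'   `net_pool_change`; mass balance
#'   `net = input - respiration - combustion` holds to float precision)
#' @examples
#' s <- pool_state(active = 100)
#' step_month(s, list(tmin = 15, tmax = 25, precip = 80, pet = 80),
#'            site_params(0.4, 0.4, 0.2, 1.2, latitude = 44))
#' @export
step_month <- function(state, forcing, site, params = model_params(),
                       events = list()) {
  tavg <- (forcing$tmin + forcing$tmax) / 2
  defac <- abiotic_factor(tavg, forcing$precip, forcing$pet, params)
  step_month_core(state, defac, site, params,
                  residue_met = events$residue_metabolic %||% 0,
                  residue_str = events$residue_structural %||% 0,
                  cultivated = isTRUE(events$cultivated),
                  fire_fraction = events$fire_fraction %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Precompute the 12 state-independent monthly drivers for one simulated year:
# defac, residue inputs (from production, harvest, amendment), cultivation and
# fire flags. Everything here depends only on forcing and schedule, never on
# the pool state, which is what makes the year map affine.
month_drivers <- function(tavg12, precip12, pet12, schedule, params,
                          fire_this_year = FALSE, prdx_mult = 1) {
  defac <- abiotic_factor(tavg12, precip12, pet12, params)
  res_met <- res_str <- numeric(12)
  eff_mult <- prdx_mult * if (isTRUE(schedule$mineral_fertilizer)) 1.1 else 1
  gs <- schedule$growing_season
  harvest_month <- if (length(gs)) max(gs) else NA_integer_
  standing_ag <- standing_bg <- 0
  litter <- numeric(12)
  for (m in 1:12) {
    if (m %in% gs) {
      p <- monthly_production(tavg12[m], precip12[m], pet12[m], params,
                              in_growing_season = TRUE,
                              topt = schedule$topt, twidth = schedule$twidth,
                              prdx_mult = eff_mult)
      ag <- params$aboveground_frac * p
      bg <- (1 - params$aboveground_frac) * p
      if (identical(schedule$vegetation, "c3_grass")) {
        # grassland: continuous litterfall; grazing removes part of the
        # aboveground increment before it reaches the litter layer
        litter[m] <- litter[m] + ag * (1 - schedule$grazing_offtake) + bg
      } else {
        standing_ag <- standing_ag + ag
        standing_bg <- standing_bg + bg
      }
    }
    if (!is.na(harvest_month) && m == harvest_month &&
        !identical(schedule$vegetation, "c3_grass")) {
      # harvest: grain and surplus straw exported, a fixed share of the
      # aboveground biomass returned as residue, roots returned in full
      litter[m] <- litter[m] +
        schedule$residue_return_fraction * standing_ag + standing_bg
      standing_ag <- standing_bg <- 0
    }
    litter[m] <- litter[m] + schedule$organic_amendment / 12
  }
  res_met <- litter * params$metabolic_split
  res_str <- litter * (1 - params$metabolic_split)
  fire <- numeric(12)
  if (fire_this_year && !is.null(schedule$fire_interval_years)) {
    fire[schedule$fire_month] <- schedule$fire_combusted_fraction
  }
  list(defac = defac, residue_met = res_met, residue_str = res_str,
       cultivated = 1:12 %in% schedule$cultivated_months, fire = fire)
}

# run 12 months of step_month_core under precomputed drivers
year_step <- function(state, drivers, site, params) {
  flux <- c(residue_input = 0, heterotrophic_respiration = 0,
            combustion_loss = 0, net_pool_change = 0)
  for (m in 1:12) {
    out <- step_month_core(state, drivers$defac[m], site, params,
                           residue_met = drivers$residue_met[m],
                           residue_str = drivers$residue_str[m],
                           cultivated = drivers$cultivated[m],
                           fire_fraction = drivers$fire[m])
    state <- out$state
    flux <- flux + out$flux
  }
  list(state = state, flux = flux)
}

# Probe the exact affine one-year map state' = A %*% state + b implied by
# year_step under fixed drivers. Valid because every flow fraction is
# state-independent.
affine_year_map <- function(drivers, site, params) {
  zero <- as_pool_state(numeric(5))
  b <- unclass(year_step(zero, drivers, site, params)$state)
  A <- matrix(0, 5, 5, dimnames = list(POOLS, POOLS))
  for (i in 1:5) {
    e <- numeric(5)
    e[i] <- 1
    A[, i] <- unclass(year_step(as_pool_state(e), drivers, site,
                                params)$state) - b
  }
  list(A = A, b = b)
}

# compose affine maps: apply `first`, then `second`
affine_compose <- function(second, first) {
  list(A = second$A %*% first$A,
       b = as.numeric(second$A %*% first$b) + second$b)
}

# n-fold self-composition by repeated squaring
affine_power <- function(map, n) {
  acc <- NULL
  sq <- map
  while (n > 0) {
    if (n %% 2 == 1) acc <- if (is.null(acc)) sq else affine_compose(sq, acc)
    n <- n %/% 2
    if (n > 0) sq <- affine_compose(sq, sq)
  }
  if (is.null(acc)) list(A = diag(5), b = numeric(5)) else acc
}

affine_apply <- function(map, state) {
  as_pool_state(as.numeric(map$A %*% unclass(state)) + map$b)
}

#' Run the turnover model over a span of years
#'
#' Applies [step_month()] sequentially, computing PET per weather year from its
#' monthly mean temperatures, generating residue inputs from the management
#' schedule, and recording the December pool state each year. If the weather
#' record is shorter than the requested span it is recycled cyclically (with
#' one warning).
#'
#' @param initial starting [pool_state()]
#' @param site a [site_params()]
#' @param weather data frame (`year, month, tmin_c, tmax_c, precip_mm`)
#' @param schedule a [management_schedule()]
#' @param params a [model_params()]
#' @param years number of years to simulate
#' @param prdx_mult multiplier on `params$prdx` (calibration hook)
#' @param start_year calendar label of the first simulated year (cosmetic)
#' @return list of class `soc_trajectory`: `annual` (data frame with `year`,
#'   pool columns, `total_c` g C m-2, `socc` g kg-1, `socd` Mg C ha-1),
#'   `final_state`, and `flux` (summed fluxes, g C m-2)
#' @export
run_simulation <- function(initial, site, weather, schedule,
                           params = model_params(), years,
                           prdx_mult = 1, start_year = NULL) {
  if (years < 1) stop("run_simulation: years must be >= 1")
  yrs <- weather_years(weather)
  ny <- length(yrs)
  if (ny < years) {
    warning(sprintf(
      "weather record (%d complete years) shorter than simulation (%d years); recycling cyclically",
      ny, years))
  }
  if (is.null(start_year)) start_year <- as.integer(names(yrs)[1])
  state <- as_pool_state(unclass(initial))
  ann <- matrix(NA_real_, years, 5, dimnames = list(NULL, POOLS))
  totals <- numeric(years)
  flux <- c(residue_input = 0, heterotrophic_respiration = 0,
            combustion_loss = 0, net_pool_change = 0)
  fire_iv <- schedule$fire_interval_years
  for (y in seq_len(years)) {
    w <- yrs[[(y - 1) %% ny + 1]]
    tavg12 <- (w$tmin_c + w$tmax_c) / 2
    pet12 <- thornthwaite_pet(tavg12, site$latitude)
    drivers <- month_drivers(tavg12, w$precip_mm, pet12, schedule, params,
                             fire_this_year = !is.null(fire_iv) &&
                               y %% fire_iv == 0,
                             prdx_mult = prdx_mult)
    out <- year_step(state, drivers, site, params)
    state <- out$state
    flux <- flux + out$flux
    ann[y, ] <- unclass(state)
    totals[y] <- sum(unclass(state))
  }
  socc <- totals / (site$bulk_density * site$depth_cm * 10)
  annual <- data.frame(year = start_year + seq_len(years) - 1, ann,
                       total_c = totals, socc = socc, socd = totals * 0.01)
  structure(list(annual = annual, final_state = state, flux = flux,
                 site = site),
            class = "soc_trajectory")
}

#' @export
print.soc_trajectory <- function(x, ...) {
  n <- nrow(x$annual)
  cat(sprintf("<soc_trajectory> %d years (%d-%d)\n", n,
              x$annual$year[1], x$annual$year[n]))
  cat(sprintf("  SOCD %.2f -> %.2f Mg C ha-1 (SOCC %.3f -> %.3f g kg-1)\n",
              x$annual$socd[1], x$annual$socd[n],
              x$annual$socc[1], x$annual$socc[n]))
  invisible(x)
}

#' Soil organic carbon content of a pool state
#'
#' Converts total pool carbon (g C m-2) to a concentration (g C per kg soil)
#' over the accounted layer: `SOCC = total / (BD * depth_cm * 10)` (the layer
#' holds `BD * depth_cm * 10` kg of soil per m2). Algebraically consistent
#' with the density formula [socd_from_socc()], so that
#' SOCD (Mg C ha-1) = total (g C m-2) * 0.01.
#'
#' @param state a [pool_state()]
#' @param site a [site_params()]
#' @return SOCC, g kg-1
#' @export
state_socc <- function(state, site) {
  total_carbon(state) / (site$bulk_density * site$depth_cm * 10)
}

#' Analytic equilibrium of the annualised flow network
#'
#' Under fixed monthly forcing the one-year update of the pool vector is an
#' affine map `c' = A c + b`; its fixed point `(I - A)^{-1} b` is the
#' equilibrium the model approaches under that forcing. Residue input is
#' supplied as a mean annual total, split over the twelve months and routed
#' through the standard metabolic/structural split.
#'
#' @param site a [site_params()]
#' @param mean_forcing list with `tavg` and `precip`, each numeric(12)
#' @param mean_annual_input mean annual residue input, g C m-2 yr-1 (>= 0)
#' @param params a [model_params()]
#' @return equilibrium [pool_state()]
#' @export
steady_state <- function(site, mean_forcing, mean_annual_input,
                         params = model_params()) {
  if (mean_annual_input < 0) stop("steady_state: input must be >= 0")
  pet12 <- thornthwaite_pet(mean_forcing$tavg, site$latitude)
  defac <- abiotic_factor(mean_forcing$tavg, mean_forcing$precip, pet12,
                          params)
  if (all(defac <= 0) && mean_annual_input > 0) {
    stop("steady_state: no finite equilibrium (zero decomposition with nonzero input)")
  }
  monthly <- mean_annual_input / 12
  drivers <- list(defac = defac,
                  residue_met = rep(monthly * params$metabolic_split, 12),
                  residue_str = rep(monthly * (1 - params$metabolic_split), 12),
                  cultivated = rep(FALSE, 12), fire = numeric(12))
  map <- affine_year_map(drivers, site, params)
  eye_minus_a <- diag(5) - map$A
  if (abs(det(eye_minus_a)) < 1e-14) {
    stop("steady_state: no finite equilibrium (singular annual map)")
  }
  eq <- solve(eye_minus_a, map$b)
  if (any(eq < -1e-8)) stop("steady_state: negative equilibrium pool")
  eq[eq < 0] <- 0
  as_pool_state(as.numeric(eq))
}
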