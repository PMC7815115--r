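# Seeded generators for a synthetic dry-farmland region: a polygon attribute
# database, station weather with a temperate continental monsoon structure,
# and a black-soil monitoring-site fixture with known truth, so every stage of
# the pipeline is testable without external data.

SOIL_GROUPS <- c("aeolian sandy soil", "black soil", "chernozem",
                 "dark brown forest soil", "meadow soil", "planosol")

#' Reference attributes of the six dry-farmland soil groups
#'
#' Group-level centroids (texture %, bulk density g cm-3, soil organic matter
#' g kg-1, pH) for the six soil groups the regional analysis covers. These are
#' the attribute centres the polygon generator jitters around. SOM converts to
#' SOC content via the van Bemmelen factor 0.58.
#'
#' @return data frame with columns `soil_group, sand, silt, clay,
#'   bulk_density, som, ph` (texture as fractions)
#' @export
soil_group_reference <- function() {
  ref <- data.frame(
    soil_group = SOIL_GROUPS,
    sand = c(78.36, 38.69, 34.49, 47.10, 33.39, 20.29),
    silt = c(9.72, 43.08, 40.64, 31.90, 46.55, 57.39),
    clay = c(11.92, 18.23, 24.87, 21.01, 20.07, 22.33),
    bulk_density = c(1.46, 1.16, 1.30, 1.07, 1.30, 1.38),
    som = c(9.50, 40.00, 32.90, 41.30, 33.55, 38.10),
    ph = c(8.10, 7.20, 7.80, 5.85, 5.70, 5.05))
  s <- ref$sand + ref$silt + ref$clay
  ref$sand <- ref$sand / s
  ref$silt <- ref$silt / s
  ref$clay <- ref$clay / s
  ref
}

#' Van Bemmelen conversion from soil organic matter to organic carbon
#' @param som soil organic matter, g kg-1
#' @return SOC content, g kg-1 (`som * 0.58`)
#' @export
som_to_socc <- function(som) som * 0.58

#' Configuration for the synthetic-region generators
#'
#' Defaults describe a Jilin-like temperate continental monsoon dry-farmland
#' region: annual mean temperature 2-6 degC, annual precipitation 400-600 mm
#' concentrated (65%) in June-August, and polygon attributes drawn around the
#' [soil_group_reference()] centroids with truncated-normal jitter.
#'
#' @param n_polygons,n_stations counts (>= 1)
#' @param seed integer RNG seed
#' @param bbox region bounding box, degrees:
#'   `c(lon_min, lon_max, lat_min, lat_max)`
#' @param group_weights mixture weights over the six soil groups (sum to 1)
#' @param annual_t_range annual mean temperature range, degC
#' @param annual_p_range annual precipitation range, mm
#' @param t_amplitude seasonal temperature amplitude, degC (July peak)
#' @param t_noise_sd interannual monthly temperature noise, degC
#' @param summer_precip_frac June-August share of annual precipitation
#' @param precip_gamma_shape shape of the multiplicative gamma noise on
#'   monthly precipitation (mean 1; cv = 1/sqrt(shape))
#' @param years calendar years the weather record spans
#' @param texture_cv,bd_cv,som_cv jitter coefficients of variation
#' @param som_floor minimum SOM after jitter, g kg-1
#' @param area_median_ha,area_sdlog lognormal polygon-area parameters
#' @param gradient make western polygons sandier (west-east texture gradient)
#' @return list of class `generator_config`
#' @export
generator_config <- function(n_polygons = 100, n_stations = 28, seed = 1,
                             bbox = c(lon_min = 121.6, lon_max = 131.3,
                                      lat_min = 40.8, lat_max = 46.3),
                             group_weights = c("aeolian sandy soil" = 0.10,
                                               "black soil" = 0.20,
                                               "chernozem" = 0.25,
                                               "dark brown forest soil" = 0.15,
                                               "meadow soil" = 0.25,
                                               "planosol" = 0.05),
                             annual_t_range = c(2, 6),
                             annual_p_range = c(400, 600),
                             t_amplitude = 19, t_noise_sd = 1.5,
                             summer_precip_frac = 0.65,
                             precip_gamma_shape = 25,
                             years = 1955:2015,
                             texture_cv = 0.10, bd_cv = 0.05, som_cv = 0.20,
                             som_floor = 2, area_median_ha = 4000,
                             area_sdlog = 1, gradient = TRUE) {
  if (n_polygons < 1 || n_stations < 1) {
    stop("generator_config: n_polygons and n_stations must be >= 1")
  }
  if (abs(sum(group_weights) - 1) > 1e-6 || any(group_weights < 0)) {
    stop("generator_config: group_weights must be non-negative and sum to 1")
  }
  if (!all(names(group_weights) %in% SOIL_GROUPS)) {
    stop("generator_config: unknown soil group in group_weights")
  }
  structure(as.list(environment()), class = "generator_config")
}

# normal draw truncated below; used for attribute jitter
rtrunc_norm <- function(n, mean, cv, floor = .Machine$double.eps) {
  pmax(floor, stats::rnorm(n, mean, cv * mean))
}

#' Generate a synthetic soil polygon database
#'
#' Each polygon draws a soil group from the configured mixture; its attributes
#' are the group centroid of [soil_group_reference()] plus truncated-normal
#' jitter (texture renormalised to sum 1), its initial SOC content is
#' SOM x 0.58, its area is lognormal, and its centroid is uniform in the
#' bounding box with (optionally) sandier polygons placed further west.
#' Deterministic given the config seed.
#'
#' @param config a [generator_config()]
#' @return data frame with columns `id, area_ha, soil_group, sand, silt, clay,
#'   bulk_density, ph, initial_socc, lon, lat`
#' @export
generate_polygon_db <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  ref <- soil_group_reference()
  with_seed(config$seed, {
    n <- config$n_polygons
    groups <- sample(names(config$group_weights), n, replace = TRUE,
                     prob = config$group_weights)
    idx <- match(groups, ref$soil_group)
    sand <- rtrunc_norm(n, ref$sand[idx], config$texture_cv)
    silt <- rtrunc_norm(n, ref$silt[idx], config$texture_cv)
    clay <- rtrunc_norm(n, ref$clay[idx], config$texture_cv)
    s <- sand + silt + clay
    sand <- sand / s; silt <- silt / s; clay <- clay / s
    bd <- pmin(1.99, pmax(0.51,
                          rtrunc_norm(n, ref$bulk_density[idx], config$bd_cv)))
    som <- rtrunc_norm(n, ref$som[idx], config$som_cv,
                       floor = config$som_floor)
    area <- stats::rlnorm(n, log(config$area_median_ha), config$area_sdlog)
    lat <- stats::runif(n, config$bbox[["lat_min"]], config$bbox[["lat_max"]])
    lon <- stats::runif(n, config$bbox[["lon_min"]], config$bbox[["lon_max"]])
    if (isTRUE(config$gradient)) {
      # sandier polygons sit further west, with noise so the marginal
      # longitude distribution stays uniform
      ord <- order(-sand + stats::rnorm(n, 0, stats::sd(sand)))
      lon <- sort(lon)[order(ord)]
    }
    data.frame(id = sprintf("P%04d", seq_len(n)), area_ha = area,
               soil_group = groups, sand = sand, silt = silt, clay = clay,
               bulk_density = bd, ph = ref$ph[idx],
               initial_socc = som_to_socc(som), lon = lon, lat = lat)
  })
}

# fixed monthly precipitation weight vector with the configured summer share
monthly_precip_weights <- function(summer_frac) {
  rest <- c(0.010, 0.010, 0.020, 0.050, 0.090, NA, NA, NA,
            0.095, 0.055, 0.040, 0.030)
  rest_total <- sum(rest, na.rm = TRUE)
  rest[!is.na(rest)] <- rest[!is.na(rest)] * (1 - summer_frac) / rest_total
  rest[6:8] <- summer_frac * c(0.31, 0.38, 0.31)
  rest / sum(rest)
}

#' Generate synthetic station weather records
#'
#' Per station: monthly mean temperature is a July-peaked sinusoid around an
#' annual mean drawn from the configured range, plus interannual noise;
#' tmin/tmax bracket the mean by half a diurnal-range draw; annual
#' precipitation is drawn from the configured range and allocated by a
#' monsoon-shaped monthly weight vector with multiplicative gamma noise.
#' Deterministic given the config seed.
#'
#' @param config a [generator_config()]
#' @return list of station records, each a list with `id, lon, lat, weather`
#'   (weather: `station_id, year, month, tmin_c, tmax_c, precip_mm`)
#' @export
generate_weather <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  w_month <- monthly_precip_weights(config$summer_precip_frac)
  with_seed(config$seed + 1L, {
    lapply(seq_len(config$n_stations), function(i) {
      id <- sprintf("S%03d", i)
      lon <- stats::runif(1, config$bbox[["lon_min"]], config$bbox[["lon_max"]])
      lat <- stats::runif(1, config$bbox[["lat_min"]], config$bbox[["lat_max"]])
      t_mean <- stats::runif(1, config$annual_t_range[1],
                             config$annual_t_range[2])
      diurnal <- stats::runif(1, 8, 12)
      p_annual <- stats::runif(1, config$annual_p_range[1],
                               config$annual_p_range[2])
      ny <- length(config$years)
      month <- rep(1:12, ny)
      year <- rep(config$years, each = 12)
      tmean <- t_mean + config$t_amplitude * cos(2 * pi * (month - 7) / 12) +
        stats::rnorm(12 * ny, 0, config$t_noise_sd)
      noise <- stats::rgamma(12 * ny, shape = config$precip_gamma_shape,
                             rate = config$precip_gamma_shape)
      precip <- p_annual * w_month[month] * noise
      list(id = id, lon = lon, lat = lat,
           weather = data.frame(station_id = id, year = year, month = month,
                                tmin_c = tmean - diurnal / 2,
                                tmax_c = tmean + diurnal / 2,
                                precip_mm = precip))
    })
  })
}

#' Yushu-like black-soil monitoring-site fixture
#'
#' A corn monitoring site on black soil with the canonical attributes of a
#' long-term plot in central Jilin: pH 5.0, bulk density 1.00 g cm-3, texture
#' 45.0/34.5/18.7 (renormalised to fractions), initial carbon 2413 g C m-2
#' (SOCC 12.065 g kg-1) and a 1988-2007 observation window. The site is
#' spun up and calibrated to the initial SOC, then run forward under a known
#' productivity multiplier; the "observed" series is that truth trajectory
#' with multiplicative Gaussian observation noise. Because the truth is known
#' exactly, validation statistics and calibration recovery can be tested
#' against it.
#'
#' The default truth multiplier (`productivity_trend = 3.5`, relative to the
#' calibrated maintenance productivity) emulates a plot under intensifying
#' management -- the era in which maize yields (and with them stover and root
#' inputs) more than doubled -- whose SOC gain over the 20 observed years is
#' large relative to the 5% observation noise. That gives the series the
#' signal-to-noise structure a high-class monitoring validation shows
#' (correlation between measurements and a faithful model >= 0.8).
#'
#' @param seed integer RNG seed (weather + observation noise)
#' @param noise_sd multiplicative observation noise sd (default 0.05)
#' @param productivity_trend truth productivity multiplier relative to the
#'   calibrated maintenance value (values < 1 emulate a degrading plot)
#' @param years observation years (default 1988:2007)
#' @return list with `site` (polygon-style record), `weather`, `truth` (data
#'   frame `year, socd`), `observed` (numeric SOCD series), `initial_state`,
#'   `multiplier_calibrated`, `multiplier_truth`
#' @export
generate_monitoring_site <- function(seed = 1, noise_sd = 0.05,
                                     productivity_trend = 3.5,
                                     years = 1988:2007) {
  tex <- normalize_texture(45.0, 34.5, 18.7)
  site_rec <- list(id = "YS", area_ha = 1,
                   soil_group = "black soil",
                   sand = tex[["sand"]], silt = tex[["silt"]],
                   clay = tex[["clay"]],
                   bulk_density = 1.00, ph = 5.0,
                   initial_socc = 2413 / (1.00 * 20 * 10),
                   lon = 126.05, lat = 44.83)
  cfg <- generator_config(n_polygons = 1, n_stations = 1, seed = seed,
                          years = 1955:2015)
  station <- generate_weather(cfg)[[1]]
  station$lon <- site_rec$lon
  station$lat <- site_rec$lat
  station$weather$station_id <- "YS-station"
  init <- initialize_polygon(site_rec, station$weather,
                             climate_years = 1955:1980)
  m_truth <- init$multiplier * productivity_trend
  obs_weather <- station$weather[station$weather$year %in% years, ]
  sim <- run_simulation(init$state, init$site, obs_weather,
                        default_cropping_schedule(),
                        years = length(years), prdx_mult = m_truth,
                        start_year = years[1])
  truth <- data.frame(year = sim$annual$year, socd = sim$annual$socd)
  observed <- with_seed(seed + 2L, {
    truth$socd * (1 + stats::rnorm(nrow(truth), 0, noise_sd))
  })
  list(site = site_rec, weather = station$weather, truth = truth,
       observed = observed, initial_state = init$state,
       multiplier_calibrated = init$multiplier, multiplier_truth = m_truth)
}
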