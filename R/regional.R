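# Polygon-scale regional driver: nearest-station climate assignment,
# independent per-polygon simulation, and regional / soil-group aggregation.

#' Nearest weather station to a polygon centroid
#'
#' Great-circle (haversine) distance on WGS84 longitude/latitude; ties are
#' broken by the lexicographically lowest station id.
#'
#' @param centroid `c(lon, lat)` in degrees
#' @param stations list of station records (each with `id, lon, lat`)
#' @return the chosen station id (character)
#' @export
nearest_station <- function(centroid, stations) {
  if (!length(stations)) stop("nearest_station: empty station list")
  ids <- vapply(stations, `[[`, "", "id")
  locs <- cbind(vapply(stations, `[[`, 0, "lon"),
                vapply(stations, `[[`, 0, "lat"))
  d <- geosphere::distHaversine(matrix(centroid, 1), locs)
  # ids break ties; distances within float jitter of the minimum count as tied
  tied <- d <= min(d) * (1 + 1e-9) + 1e-9
  min(ids[tied])
}

#' Run the regional simulation
#'
#' Assigns each polygon its nearest weather station, initialises it through
#' the calibrated three-stage spin-up (unless pre-initialised states are
#' supplied), and simulates it independently from `start` to `end`, reporting
#' December-state SOC density per year. Aggregates to yearly regional stocks
#' and per-polygon density change. Polygons are independent: permuting their
#' order leaves every aggregate bit-identical. A polygon whose spin-up or run
#' fails is reported by id and excluded from the aggregates, never silently
#' dropped; the run errors only if every polygon fails.
#'
#' @param polygons polygon data frame (see [read_polygons()] for the dialect)
#' @param stations list of station records (e.g. from [generate_weather()])
#' @param params a [model_params()]
#' @param schedule the simulation-period [management_schedule()]
#' @param start,end first and last simulated calendar year
#' @param stage_plans spin-up [stage_plan()]s used for initialisation
#' @param initial_states optional named list (by polygon id) of
#'   pre-initialised results from [initialize_polygon()]
#' @param climate_years reference years for the spin-up climate normals
#' @return object of class `regional_result`: `socd` (polygons x years matrix,
#'   Mg C ha-1), `years`, `socs` (Tg per year), `delta_socd` (per polygon),
#'   `polygons` (id, area, group of the successful polygons), `station_id`
#'   assignment, `multipliers`, `failures` (named list of error messages)
#' @export
run_region <- function(polygons, stations, params = model_params(),
                       schedule = default_cropping_schedule(),
                       start = 1985, end = 2015,
                       stage_plans = default_stage_plans(),
                       initial_states = NULL,
                       climate_years = 1955:1980) {
  if (start >= end) stop("run_region: start must be < end")
  n_years <- end - start + 1
  station_ids <- vapply(seq_len(nrow(polygons)), function(i) {
    nearest_station(c(polygons$lon[i], polygons$lat[i]), stations)
  }, "")
  weather_by_id <- stats::setNames(lapply(stations, `[[`, "weather"),
                                   vapply(stations, `[[`, "", "id"))
  ids <- as.character(polygons$id)
  socd <- matrix(NA_real_, nrow(polygons), n_years,
                 dimnames = list(ids, start:end))
  mult <- stats::setNames(rep(NA_real_, nrow(polygons)), ids)
  failures <- list()
  for (i in seq_len(nrow(polygons))) {
    poly <- as.list(polygons[i, ])
    res <- tryCatch({
      w <- weather_by_id[[station_ids[i]]]
      init <- if (!is.null(initial_states) && ids[i] %in% names(initial_states))
        initial_states[[ids[i]]]
      else
        initialize_polygon(poly, w, params, stage_plans,
                           climate_years = climate_years)
      w_run <- w[w$year >= start & w$year <= end, ]
      sim <- suppressWarnings(
        run_simulation(init$state, init$site, w_run, schedule, params,
                       years = n_years, prdx_mult = init$multiplier,
                       start_year = start))
      list(socd = sim$annual$socd, multiplier = init$multiplier)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[ids[i]]] <- conditionMessage(res)
    } else {
      socd[i, ] <- res$socd
      mult[i] <- res$multiplier
    }
  }
  ok <- !is.na(socd[, 1])
  if (!any(ok)) {
    stop("run_region: all polygons failed; first error: ", failures[[1]])
  }
  if (length(failures)) {
    message(sprintf("run_region: %d of %d polygons failed and were excluded: %s",
                    length(failures), nrow(polygons),
                    paste(names(failures), collapse = ", ")))
  }
  socd_ok <- socd[ok, , drop = FALSE]
  area_ok <- polygons$area_ha[ok]
  socs <- apply(socd_ok, 2, socs_total, area = area_ok)
  structure(list(
    socd = socd_ok, years = start:end, socs = socs,
    delta_socd = socd_ok[, n_years] - socd_ok[, 1],
    polygons = data.frame(id = ids[ok], area_ha = area_ok,
                          soil_group = polygons$soil_group[ok]),
    station_id = stats::setNames(station_ids, ids),
    multipliers = mult[ok], failures = failures),
    class = "regional_result")
}

#' @export
print.regional_result <- function(x, ...) {
  n <- length(x$years)
  aw <- function(v) sum(v * x$polygons$area_ha) / sum(x$polygons$area_ha)
  cat(sprintf("<regional_result> %d polygons, %d-%d\n",
              nrow(x$socd), x$years[1], x$years[n]))
  cat(sprintf("  area-weighted SOCD %.2f -> %.2f Mg C ha-1\n",
              aw(x$socd[, 1]), aw(x$socd[, n])))
  cat(sprintf("  SOCS %.2f -> %.2f Tg\n", x$socs[1], x$socs[n]))
  if (length(x$failures)) {
    cat(sprintf("  %d failed polygon(s): %s\n", length(x$failures),
                paste(names(x$failures), collapse = ", ")))
  }
  invisible(x)
}

#' Area-weighted mean SOC density change of a regional result
#' @param result a `regional_result`
#' @return Mg C ha-1
#' @export
mean_delta_socd <- function(result) {
  sum(result$delta_socd * result$polygons$area_ha) /
    sum(result$polygons$area_ha)
}

#' Per-soil-group summary of a regional result
#'
#' Area-weighted group mean SOC density for the first and last year, mean
#' density change, group stock change in Tg, and the group ranking by initial
#' density.
#'
#' @param result a `regional_result` from [run_region()]
#' @return data frame (one row per group, ordered by initial SOCD, highest
#'   first): `soil_group, n, area_ha, socd_start, socd_end, delta_socd,
#'   socs_change_tg, rank`
#' @export
soil_group_summary <- function(result) {
  groups <- result$polygons$soil_group
  if (!all(groups %in% SOIL_GROUPS)) {
    stop("soil_group_summary: unknown soil group label: ",
         paste(setdiff(groups, SOIL_GROUPS), collapse = ", "))
  }
  n_years <- length(result$years)
  rows <- lapply(split(seq_along(groups), groups), function(ix) {
    a <- result$polygons$area_ha[ix]
    s0 <- result$socd[ix, 1]
    s1 <- result$socd[ix, n_years]
    data.frame(soil_group = groups[ix[1]], n = length(ix), area_ha = sum(a),
               socd_start = sum(s0 * a) / sum(a),
               socd_end = sum(s1 * a) / sum(a),
               delta_socd = sum((s1 - s0) * a) / sum(a),
               socs_change_tg = socs_total(s1, a) - socs_total(s0, a))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$socd_start), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
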