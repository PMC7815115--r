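# Readers and writers for the pipeline's plain-text dialects:
# polygon attribute CSV, long-format station weather CSV, GeoJSON point
# FeatureCollections, and the YAML run configuration.

POLYGON_COLUMNS <- c("id", "area_ha", "soil_group", "sand", "silt", "clay",
                     "bulk_density", "ph", "initial_socc", "lon", "lat")

#' Read a soil polygon attribute table
#'
#' CSV with columns `id, area_ha, soil_group, sand, silt, clay, bulk_density,
#' ph, initial_socc, lon, lat`. Row-level problems (texture not summing to 1
#' within 1e-3, non-positive area or SOC, unknown soil group) are collected
#' and reported with their line numbers; with `strict = TRUE` the first
#' problem aborts immediately.
#'
#' @param path CSV file path
#' @param strict abort on the first row error instead of collecting all
#' @return polygon data frame
#' @export
read_polygons <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("read_polygons: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(POLYGON_COLUMNS, names(df))
  if (length(miss)) {
    stop("read_polygons: missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  errs <- character()
  note <- function(row, msg) {
    line <- sprintf("line %d (id %s): %s", row + 1L, df$id[row], msg)
    if (strict) stop("read_polygons: ", line) else errs <<- c(errs, line)
  }
  for (i in seq_len(nrow(df))) {
    tex <- df$sand[i] + df$silt[i] + df$clay[i]
    if (abs(tex - 1) > 1e-3) {
      note(i, sprintf("sand+silt+clay = %.4f, not 1 within 1e-3", tex))
    }
    if (!is.na(df$area_ha[i]) && df$area_ha[i] <= 0) note(i, "area_ha <= 0")
    if (!is.na(df$initial_socc[i]) && df$initial_socc[i] <= 0) {
      note(i, "initial_socc <= 0")
    }
    if (!df$soil_group[i] %in% SOIL_GROUPS) {
      note(i, paste0("unknown soil group '", df$soil_group[i], "'"))
    }
  }
  if (length(errs)) {
    stop("read_polygons: invalid rows:\n  ", paste(errs, collapse = "\n  "))
  }
  df[, POLYGON_COLUMNS]
}

fmt_num <- function(x, digits) {
  if (is.numeric(x)) trimws(formatC(x, digits = digits, format = "g")) else x
}

#' Write a soil polygon attribute table
#' @param polygons polygon data frame
#' @param path output CSV path
#' @param digits significant digits to serialise (default 15, which
#'   round-trips doubles to ~1e-15 relative)
#' @return `path`, invisibly
#' @export
write_polygons <- function(polygons, path, digits = 15) {
  out <- polygons[, POLYGON_COLUMNS]
  out[] <- lapply(out, fmt_num, digits = digits)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read long-format station weather
#'
#' CSV with columns `station_id, year, month, tmin_c, tmax_c, precip_mm` and
#' (optionally) constant `lon, lat` per station; station coordinates may
#' instead come from a separate stations table (`station_id, lon, lat`).
#' Every station must be monthly-complete over its span: any missing
#' (station, year, month) cell is an error listing the gaps, and any row with
#' `tmax_c < tmin_c` is a row error.
#'
#' @param path weather CSV path
#' @param stations_path optional stations CSV path with coordinates
#' @return list of station records (`id, lon, lat, weather`)
#' @export
read_weather <- function(path, stations_path = NULL) {
  if (!file.exists(path)) stop("read_weather: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "year", "month", "tmin_c", "tmax_c", "precip_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("read_weather: missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  bad <- which(df$tmax_c < df$tmin_c)
  if (length(bad)) {
    stop("read_weather: tmax_c < tmin_c at line(s) ",
         paste(bad + 1L, collapse = ", "))
  }
  coords <- NULL
  if (!is.null(stations_path)) {
    coords <- utils::read.csv(stations_path, stringsAsFactors = FALSE)
  }
  gaps <- character()
  recs <- lapply(split(df, df$station_id), function(w) {
    id <- w$station_id[1]
    span <- min(w$year):max(w$year)
    want <- paste(rep(span, each = 12), rep(1:12, length(span)))
    have <- paste(w$year, w$month)
    missing_cells <- setdiff(want, have)
    if (length(missing_cells)) {
      gaps <<- c(gaps, paste0(id, ": ",
                              paste(gsub(" ", "-", missing_cells),
                                    collapse = ", ")))
    }
    lon <- if ("lon" %in% names(w)) w$lon[1] else
      coords$lon[match(id, coords$station_id)]
    lat <- if ("lat" %in% names(w)) w$lat[1] else
      coords$lat[match(id, coords$station_id)]
    list(id = id, lon = lon, lat = lat,
         weather = w[order(w$year, w$month),
                     c("station_id", "year", "month", "tmin_c", "tmax_c",
                       "precip_mm")])
  })
  if (length(gaps)) {
    stop("read_weather: missing (station, year-month) cells:\n  ",
         paste(gaps, collapse = "\n  "))
  }
  unname(recs)
}

#' Write station weather records to long-format CSV
#' @param stations list of station records (`id, lon, lat, weather`)
#' @param path output CSV path
#' @param digits significant digits (default 15)
#' @return `path`, invisibly
#' @export
write_weather <- function(stations, path, digits = 15) {
  rows <- lapply(stations, function(s) {
    w <- s$weather
    w$lon <- s$lon
    w$lat <- s$lat
    w
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[] <- lapply(out, fmt_num, digits = digits)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write polygons as a GeoJSON point FeatureCollection
#'
#' RFC 7946 FeatureCollection of Point features (the polygon centroids) with
#' the attribute columns as properties.
#'
#' @param polygons polygon data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_polygons_geojson <- function(polygons, path) {
  features <- lapply(seq_len(nrow(polygons)), function(i) {
    p <- as.list(polygons[i, setdiff(POLYGON_COLUMNS, c("lon", "lat"))])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(polygons$lon[i], polygons$lat[i])),
         properties = p)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from a GeoJSON point FeatureCollection
#' @param path GeoJSON path (as written by [write_polygons_geojson()])
#' @return polygon data frame
#' @export
read_polygons_geojson <- function(path) {
  if (!file.exists(path)) stop("read_polygons_geojson: no such file: ", path)
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("read_polygons_geojson: not a FeatureCollection")
  }
  rows <- lapply(gj$features, function(f) {
    props <- f$properties
    props$lon <- f$geometry$coordinates[[1]]
    props$lat <- f$geometry$coordinates[[2]]
    as.data.frame(props, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df[, POLYGON_COLUMNS]
}

#' Read a run configuration file
#'
#' YAML with optional sections `paths` (polygons, weather, output_dir),
#' `years` (start, end), `model` (overrides for [model_params()] scalars),
#' `schedule` (overrides for [default_cropping_schedule()]), and `seed`.
#'
#' @param path YAML file path
#' @return named list of configuration values
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: no such file: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$years)) {
    if (cfg$years$start >= cfg$years$end) {
      stop("read_run_config: years.start must be < years.end")
    }
  }
  cfg
}
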