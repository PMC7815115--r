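# SOC accounting formulas and validation statistics.

#' SOC density from SOC content
#'
#' `SOCD (Mg C ha-1) = SOCC (g kg-1) * BD (g cm-3) * H (cm) * 0.1`
#' for the accounted layer (default 0-20 cm).
#'
#' @param socc SOC content, g kg-1 (> 0)
#' @param bd bulk density, g cm-3 (> 0)
#' @param h_cm layer thickness, cm (default 20)
#' @return SOC density, Mg C ha-1 (vectorised)
#' @examples
#' socd_from_socc(10, 1.3)  # 26
#' @export
socd_from_socc <- function(socc, bd, h_cm = 20) {
  if (any(socc <= 0) || any(bd <= 0) || any(h_cm <= 0)) {
    stop("socd_from_socc: all inputs must be > 0")
  }
  socc * bd * h_cm * 0.1
}

#' Inverse of [socd_from_socc()]
#' @param socd SOC density, Mg C ha-1
#' @param bd bulk density, g cm-3
#' @param h_cm layer thickness, cm
#' @return SOC content, g kg-1
#' @export
socc_from_socd <- function(socd, bd, h_cm = 20) {
  if (any(socd <= 0) || any(bd <= 0) || any(h_cm <= 0)) {
    stop("socc_from_socd: all inputs must be > 0")
  }
  socd / (bd * h_cm * 0.1)
}

#' Regional SOC stock
#'
#' `SOCS (Tg) = sum_i SOCD_i * S_i / 1e6` over polygons, with SOCD in
#' Mg C ha-1 and area S in ha.
#'
#' @param socd per-polygon SOC density, Mg C ha-1
#' @param area per-polygon area, ha (> 0)
#' @return total stock, Tg (1 Tg = 1e12 g)
#' @export
socs_total <- function(socd, area) {
  if (length(socd) != length(area)) {
    stop("socs_total: socd and area must have equal length")
  }
  if (length(area) && any(area <= 0)) stop("socs_total: areas must be > 0")
  sum(socd * area) / 1e6
}

#' Change in SOC density over the simulation period
#' @param socd_start,socd_end SOC density at the start and end year, Mg C ha-1
#' @return `socd_end - socd_start`, Mg C ha-1 (vectorised)
#' @export
delta_socd <- function(socd_start, socd_end) socd_end - socd_start

#' Pearson correlation between observed and simulated series
#'
#' Sample correlation coefficient plus the verbal interpretation class used
#' for monitoring-site validation: "high" for r >= 0.8, "moderate" for
#' `[0.5, 0.8)`, "low" for `[0.3, 0.5)`, "extremely weak" below 0.3.
#'
#' @param observed,simulated paired numeric series (length >= 2, non-constant)
#' @return list with `r`, `n`, `class`
#' @export
pearson_r <- function(observed, simulated) {
  if (length(observed) != length(simulated)) {
    stop("pearson_r: series must have equal length")
  }
  n <- length(observed)
  if (n < 2) stop("pearson_r: need at least 2 pairs")
  if (stats::sd(observed) == 0 || stats::sd(simulated) == 0) {
    stop("pearson_r: constant series (zero denominator)")
  }
  r <- stats::cor(observed, simulated)
  cls <- if (r >= 0.8) "high" else if (r >= 0.5) "moderate" else
    if (r >= 0.3) "low" else "extremely weak"
  list(r = r, n = n, class = cls)
}

#' Modelling efficiency (Nash-Sutcliffe-type index)
#'
#' `variant = "standard"` (default) is the usual Nash-Sutcliffe form
#' `1 - sum((P-O)^2) / sum((O-Obar)^2)`: 1 means a perfect fit, 0 means the
#' model is no better than the observed mean, negative means worse.
#' `variant = "as_printed"` uses `sum((P-Obar)^2)` in the denominator, a
#' non-standard form sometimes seen in the applied literature; it is provided
#' so both conventions can be reported side by side.
#'
#' @param observed,simulated paired numeric series (length >= 2)
#' @param variant `"standard"` or `"as_printed"`
#' @return modelling efficiency (<= 1 for the standard variant)
#' @export
modeling_efficiency <- function(observed, simulated,
                                variant = c("standard", "as_printed")) {
  variant <- match.arg(variant)
  if (length(observed) != length(simulated)) {
    stop("modeling_efficiency: series must have equal length")
  }
  if (length(observed) < 2) stop("modeling_efficiency: need at least 2 pairs")
  obar <- mean(observed)
  denom <- if (variant == "standard") sum((observed - obar)^2) else
    sum((simulated - obar)^2)
  if (denom == 0) stop("modeling_efficiency: zero denominator")
  1 - sum((simulated - observed)^2) / denom
}

#' Descriptive statistics of a SOC density set
#'
#' The summary reported for a regional polygon set: n, minimum, maximum, mean,
#' range, sample (n-1) standard deviation and variance.
#'
#' @param values numeric vector (length >= 2)
#' @return data frame with one row:
#'   `n, min, max, mean, range, sd, variance`
#' @export
descriptive_stats <- function(values) {
  if (length(values) < 2) {
    stop("descriptive_stats: need at least 2 values for sd/variance")
  }
  data.frame(n = length(values), min = min(values), max = max(values),
             mean = mean(values), range = max(values) - min(values),
             sd = stats::sd(values), variance = stats::var(values))
}

DELTA_BREAKS <- c(-Inf, -10, -5, 0, 5, Inf)
DELTA_LABELS <- c("(-Inf,-10)", "[-10,-5)", "[-5,0)", "[0,5)", "[5,Inf)")

#' Classify a SOC density change into reporting bins
#'
#' Half-open bins, closed on the left:
#' `(-Inf,-10), [-10,-5), [-5,0), [0,5), [5,Inf)` Mg C ha-1.
#' Zero falls on the gain side (`[0,5)`).
#'
#' @param delta SOC density change, Mg C ha-1 (finite; vectorised)
#' @return factor of bin labels
#' @export
classify_delta <- function(delta) {
  if (any(!is.finite(delta))) stop("classify_delta: delta must be finite")
  cut(delta, breaks = DELTA_BREAKS, labels = DELTA_LABELS, right = FALSE)
}

#' Monitoring-site validation report
#'
#' Bundles the validation statistics for one observed/simulated pair of SOC
#' density series: Pearson r with its verbal class, both modelling-efficiency
#' variants and n.
#'
#' @param observed,simulated paired numeric series
#' @return list of class `validation_report`
#' @export
validation_report <- function(observed, simulated) {
  r <- pearson_r(observed, simulated)
  structure(list(
    n = r$n, r = r$r, correlation_class = r$class,
    me = modeling_efficiency(observed, simulated, "standard"),
    me_as_printed = modeling_efficiency(observed, simulated, "as_printed")),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  n  = %d\n  r  = %.4f (%s correlation)\n", x$n, x$r,
              x$correlation_class))
  cat(sprintf("  ME = %.4f (standard; as-printed variant %.4f)\n",
              x$me, x$me_as_printed))
  invisible(x)
}

#' Write a validation report to JSON (and optional plain text)
#' @param report a [validation_report()]
#' @param path output JSON path
#' @param text_path optional plain-text path
#' @return `path`, invisibly
#' @export
write_validation_report <- function(report, path, text_path = NULL) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  if (!is.null(text_path)) {
    con <- file(text_path, "w")
    on.exit(close(con))
    writeLines(utils::capture.output(print(report)), con)
  }
  invisible(path)
}
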