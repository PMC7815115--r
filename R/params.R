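#' Carbon pool state
#'
#' The model tracks five carbon pools (g C m-2) in the 0-20 cm layer:
#' two litter pools (structural, metabolic) receiving plant residue, and the
#' three soil organic matter pools of CENTURY-family models -- active (microbial
#' biomass and labile products, turnover of years), slow (physically protected,
#' turnover of decades) and passive (chemically stabilised, turnover of
#' centuries to millennia; often called "inert", though it does decay slowly).
#'
#' @param structural structural litter, g C m-2
#' @param metabolic metabolic litter, g C m-2
#' @param active active SOM pool, g C m-2
#' @param slow slow SOM pool, g C m-2
#' @param passive passive SOM pool, g C m-2
#' @return A named numeric vector of class `pool_state`.
#' @examples
#' pool_state(active = 100)
#' @export
pool_state <- function(structural = 0, metabolic = 0, active = 0,
                       slow = 0, passive = 0) {
  x <- c(structural = structural, metabolic = metabolic, active = active,
         slow = slow, passive = passive)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("pool_state: all pools must be finite and >= 0")
  }
  class(x) <- c("pool_state", "numeric")
  x
}

POOLS <- c("structural", "metabolic", "active", "slow", "passive")

as_pool_state <- function(x) {
  stopifnot(is.numeric(x), length(x) == 5L)
  names(x) <- POOLS
  class(x) <- c("pool_state", "numeric")
  x
}

#' Total carbon of a pool state
#' @param state a [pool_state()]
#' @return total carbon, g C m-2
#' @export
total_carbon <- function(state) sum(unclass(state))

#' @export
print.pool_state <- function(x, ...) {
  cat("<pool_state>  (g C m-2)\n")
  print(round(unclass(x), 3))
  cat("total:", format(sum(x), digits = 6), "\n")
  invisible(x)
}

#' Site (soil and location) parameters
#'
#' Static properties of one simulation unit: texture as mass fractions of the
#' fine-earth (must sum to 1), bulk density, pH, latitude (used by the
#' Thornthwaite evapotranspiration routine) and the accounted soil depth.
#'
#' @param sand,silt,clay texture fractions in `[0, 1]`, summing to 1 (+-1e-6)
#' @param bulk_density g cm-3, in (0.5, 2.0)
#' @param ph soil pH (carried as an attribute; not used by the carbon flows)
#' @param latitude degrees north
#' @param depth_cm accounted layer thickness, cm (default 20, i.e. 0-20 cm)
#' @return A list of class `site_params`.
#' @examples
#' site_params(0.39, 0.43, 0.18, bulk_density = 1.16, ph = 7.2, latitude = 44)
#' @export
site_params <- function(sand, silt, clay, bulk_density, ph = 7,
                        latitude = 44, depth_cm = 20) {
  tex <- c(sand, silt, clay)
  if (any(tex < 0) || any(tex > 1)) {
    stop("site_params: texture fractions must lie in [0, 1]")
  }
  if (abs(sum(tex) - 1) > 1e-6) {
    stop(sprintf("site_params: sand+silt+clay = %.6f, must equal 1 (+-1e-6)",
                 sum(tex)))
  }
  if (bulk_density <= 0.5 || bulk_density >= 2.0) {
    stop("site_params: bulk_density must lie in (0.5, 2.0) g cm-3")
  }
  if (depth_cm <= 0) stop("site_params: depth_cm must be > 0")
  structure(list(sand = sand, silt = silt, clay = clay,
                 bulk_density = bulk_density, ph = ph,
                 latitude = latitude, depth_cm = depth_cm),
            class = "site_params")
}

#' Normalise a texture triple to sum to one
#'
#' Laboratory texture rows frequently sum to slightly less than 100%;
#' this rescales the triple so [site_params()] accepts it.
#'
#' @param sand,silt,clay raw fractions (any positive scale)
#' @return named numeric vector `c(sand, silt, clay)` summing to 1
#' @export
normalize_texture <- function(sand, silt, clay) {
  s <- sand + silt + clay
  if (s <= 0) stop("normalize_texture: texture sum must be positive")
  c(sand = sand / s, silt = silt / s, clay = clay / s)
}

#' Turnover model parameters
#'
#' Rate constants and partition fractions of the five-pool turnover network,
#' the climate-response parameters, and the plant-production parameters.
#' Defaults are the canonical CENTURY-family values; every one is overridable.
#'
#' * `k`: base (potential) decay rates, yr-1, per pool.
#' * `resp_frac`: fraction of decayed carbon respired as CO2, per pool
#'   (the active pool's respired fraction is texture-dependent,
#'   0.85 - 0.68 (silt+clay), and set at run time).
#' * `metabolic_split`: fraction of incoming residue routed to metabolic litter.
#' * `lignin_frac`: lignin fraction of structural litter; the lignin share of
#'   decayed structural carbon is routed to the slow pool.
#' * `q10`, `t_ref`: temperature response of decomposition,
#'   `min(1, q10^((T - t_ref)/10))`.
#' * `cultivation_mult`: decay multiplier applied to litter and active pools in
#'   months flagged as cultivated.
#' * `prdx`: potential monthly production, g C m-2 month-1, before climate
#'   limitation; the single calibration knob of the spin-up.
#' * `aboveground_frac`: fraction of production allocated aboveground.
#' * `grain_frac`: grain share of aboveground biomass (exported at harvest).
#' * `residue_return_fraction`: aboveground share returned to the soil at
#'   harvest (default 0.15; the remainder of the non-grain straw is removed).
#'
#' @param k named numeric vector of base decay rates (yr-1)
#' @param resp_frac respired fractions for structural, metabolic, slow, passive
#' @param metabolic_split,lignin_frac residue partitioning fractions
#' @param q10,t_ref decomposition temperature response
#' @param cultivation_mult tillage decay multiplier
#' @param prdx potential monthly production scalar (g C m-2 month-1)
#' @param aboveground_frac,grain_frac,residue_return_fraction allocation
#'   and harvest fractions
#' @return A list of class `model_params`.
#' @examples
#' p <- model_params(prdx = 120)
#' p$k[["active"]]
#' @export
model_params <- function(k = c(structural = 3.9, metabolic = 14.8,
                               active = 7.3, slow = 0.2, passive = 0.0045),
                         resp_frac = c(structural = 0.30, metabolic = 0.55,
                                       slow = 0.55, passive = 0.55),
                         metabolic_split = 0.55,
                         lignin_frac = 0.20,
                         q10 = 2, t_ref = 30,
                         cultivation_mult = 1.2,
                         prdx = 150,
                         aboveground_frac = 0.5,
                         grain_frac = 0.45,
                         residue_return_fraction = 0.15) {
  if (any(k <= 0)) stop("model_params: all decay rates must be > 0")
  if (any(c(resp_frac, metabolic_split, lignin_frac, aboveground_frac,
            grain_frac, residue_return_fraction) < 0) ||
      any(c(resp_frac, metabolic_split, lignin_frac, aboveground_frac,
            grain_frac, residue_return_fraction) > 1)) {
    stop("model_params: all fractions must lie in [0, 1]")
  }
  if (q10 <= 0 || prdx < 0) stop("model_params: q10 must be > 0 and prdx >= 0")
  structure(list(k = k[POOLS], resp_frac = resp_frac,
                 metabolic_split = metabolic_split, lignin_frac = lignin_frac,
                 q10 = q10, t_ref = t_ref, cultivation_mult = cultivation_mult,
                 prdx = prdx, aboveground_frac = aboveground_frac,
                 grain_frac = grain_frac,
                 residue_return_fraction = residue_return_fraction),
            class = "model_params")
}

# run a block with a locally-seeded RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
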