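# Shared fixtures built in code, plus independent oracles used across files.

# a loamy reference site
test_site <- function(sand = 0.40, silt = 0.40, clay = 0.20, bd = 1.2,
                      lat = 44) {
  site_params(sand, silt, clay, bulk_density = bd, ph = 6.5, latitude = lat)
}

# one synthetic station record, small and fixed
test_station <- function(seed = 7, years = 1955:2015) {
  generate_weather(generator_config(n_polygons = 1, n_stations = 1,
                                    seed = seed, years = years))[[1]]
}

# constant warm, wet weather frame: defac = 1 in every month
warm_weather <- function() {
  data.frame(year = 1, month = 1:12, tmin_c = 30, tmax_c = 30,
             precip_mm = 500)
}

warm_climate <- function() list(tavg = rep(30, 12), precip = rep(500, 12))

# independent Pearson-r oracle: the definition written out directly
pearson_oracle <- function(o, p) {
  sum((o - mean(o)) * (p - mean(p))) /
    sqrt(sum((o - mean(o))^2) * sum((p - mean(p))^2))
}

# total carbon budget closure of a trajectory, relative to the pool total
mass_balance_error <- function(sim, initial) {
  change <- total_carbon(sim$final_state) - total_carbon(initial)
  expected <- sim$flux[["residue_input"]] -
    sim$flux[["heterotrophic_respiration"]] -
    sim$flux[["combustion_loss"]]
  abs(change - expected) / max(total_carbon(sim$final_state), 1)
}
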