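station <- test_station()
climate <- climate_normals(station$weather, 1955:1980)

test_that("zero production spins up to zero pools", {
  site <- test_site()
  eq <- equilibrium_stage(site, climate, params = model_params(prdx = 0),
                          years = 500, warn_convergence = FALSE)
  expect_equal(total_carbon(eq), 0)
  expect_error(equilibrium_stage(site, climate, years = 0), ">= 1")
})

test_that("analytic and month-by-month equilibrium stages agree", {
  site <- test_site()
  fast <- equilibrium_stage(site, climate, years = 100,
                            warn_convergence = FALSE)
  slow <- equilibrium_stage(site, climate, years = 100, fast = FALSE)
  expect_equal(unclass(fast), unclass(slow), tolerance = 5e-3)
  expect_lt(abs(total_carbon(fast) / total_carbon(slow) - 1), 1e-9)
})

test_that("fire can only lower the grassland equilibrium", {
  site <- test_site()
  with_fire <- equilibrium_stage(site, climate, grassland_schedule(),
                                 years = 1000, warn_convergence = FALSE)
  no_fire <- equilibrium_stage(site, climate,
                               grassland_schedule(fire_interval_years = NULL),
                               years = 1000, warn_convergence = FALSE)
  expect_lte(total_carbon(with_fire), total_carbon(no_fire))
})

test_that("stage plans validate their duration", {
  expect_error(stage_plan("x", 0, cropping_schedule()), ">= 1")
})

test_that("an equilibrium state is a fixed point of its own stage", {
  site <- test_site()
  eq <- equilibrium_stage(site, climate, years = 6000,
                          warn_convergence = FALSE)
  again <- historical_stage(eq, stage_plan("same", 50, grassland_schedule()),
                            site, station$weather,
                            climate_years = 1955:1980)
  expect_lt(abs(total_carbon(again) / total_carbon(eq) - 1), 0.01)
})

test_that("cultivation after grassland equilibrium loses carbon", {
  site <- test_site()
  eq <- equilibrium_stage(site, climate, years = 3000,
                          warn_convergence = FALSE)
  cropped <- historical_stage(
    eq, stage_plan("historical", 80, cropping_schedule(organic_amendment = 15)),
    site, station$weather, climate_years = 1955:1980)
  expect_lt(total_carbon(cropped), total_carbon(eq))
})

test_that("running stages back-to-back equals one longer stage", {
  site <- test_site()
  sched <- cropping_schedule(organic_amendment = 15)
  start <- pool_state(structural = 100, metabolic = 50, active = 300,
                      slow = 3000, passive = 1500)
  one <- historical_stage(start, stage_plan("a", 80, sched), site,
                          station$weather)
  two <- historical_stage(
    historical_stage(start, stage_plan("b1", 40, sched), site,
                     station$weather),
    stage_plan("b2", 40, sched), site, station$weather)
  expect_equal(unclass(one), unclass(two), tolerance = 1e-9)
})

test_that("calibration is self-consistent at multiplier one", {
  site <- test_site()
  plans <- default_stage_plans()
  target <- state_socc(spinup_state(site, plans, station$weather,
                                    model_params(), 1, 1955:1980), site)
  cal <- calibrate_prdx(site, plans, station$weather, target_socc = target,
                        climate_years = 1955:1980)
  expect_equal(cal$multiplier, 1, tolerance = 0.02)
  expect_equal(cal$achieved_socc, target, tolerance = 0.01)
})

test_that("calibration recovers a known multiplier within 2%", {
  site <- test_site()
  plans <- default_stage_plans()
  target <- state_socc(spinup_state(site, plans, station$weather,
                                    model_params(), 1.7, 1955:1980), site)
  cal <- calibrate_prdx(site, plans, station$weather, target_socc = target,
                        climate_years = 1955:1980)
  expect_equal(cal$multiplier, 1.7, tolerance = 0.02)
})

test_that("final initialized SOC increases with the multiplier", {
  site <- test_site()
  plans <- default_stage_plans()
  soccs <- sapply(c(0.1, 0.5, 1, 2, 5, 10), function(m) {
    state_socc(spinup_state(site, plans, station$weather, model_params(), m,
                            1955:1980), site)
  })
  expect_true(all(diff(soccs) > 0))
})

test_that("an unreachable target fails loudly with the achievable range", {
  site <- test_site()
  plans <- default_stage_plans()
  hi <- state_socc(spinup_state(site, plans, station$weather, model_params(),
                                10, 1955:1980), site)
  expect_error(
    calibrate_prdx(site, plans, station$weather, target_socc = hi * 10,
                   climate_years = 1955:1980),
    "achievable range")
  expect_error(
    calibrate_prdx(site, plans, station$weather, target_socc = -1),
    "> 0")
})

test_that("polygon initialization hits the attributed initial SOC", {
  ref <- soil_group_reference()
  bs <- as.list(ref[ref$soil_group == "black soil", ])
  poly <- list(id = "T1", area_ha = 100, sand = bs$sand, silt = bs$silt,
               clay = bs$clay, bulk_density = bs$bulk_density, ph = bs$ph,
               lat = 44, initial_socc = som_to_socc(40.0))
  init <- initialize_polygon(poly, station$weather,
                             climate_years = 1955:1980)
  expect_equal(init$achieved_socc, 23.2, tolerance = 0.01)
  expect_equal(state_socc(init$state, init$site), init$achieved_socc)

  sandy <- as.list(ref[ref$soil_group == "aeolian sandy soil", ])
  poly2 <- list(id = "T2", area_ha = 100, sand = sandy$sand,
                silt = sandy$silt, clay = sandy$clay,
                bulk_density = sandy$bulk_density, ph = sandy$ph, lat = 44,
                initial_socc = som_to_socc(9.50))
  init2 <- initialize_polygon(poly2, station$weather,
                              climate_years = 1955:1980)
  expect_lt(state_socc(init2$state, init2$site),
            state_socc(init$state, init$site))
})

test_that("degenerate polygons are rejected with their id attached", {
  poly <- list(id = "BAD", area_ha = 0, sand = 0.4, silt = 0.4, clay = 0.2,
               bulk_density = 1.2, ph = 6.5, lat = 44, initial_socc = 20)
  expect_error(initialize_polygon(poly, station$weather), "area")
  poly$area_ha <- 10
  poly$initial_socc <- 0
  expect_error(initialize_polygon(poly, station$weather), "initial_socc")
})
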