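test_that("pool state validates non-negativity and totals", {
  s <- pool_state(active = 100, slow = 50)
  expect_equal(total_carbon(s), 150)
  expect_error(pool_state(active = -1), ">= 0")
})

test_that("a month with zero pools and zero input does nothing", {
  site <- test_site()
  out <- step_month(pool_state(), list(tmin = 10, tmax = 20, precip = 50,
                                       pet = 60), site)
  expect_equal(total_carbon(out$state), 0)
  expect_equal(unname(out$flux), rep(0, 4))
})

test_that("with zero decomposition, residue accumulates in litter untouched", {
  site <- test_site()
  p <- model_params()
  out <- step_month_core(pool_state(active = 80, slow = 40), defac = 0,
                         site = site, params = p,
                         residue_met = 5.5, residue_str = 4.5)
  expect_equal(out$state[["active"]], 80)
  expect_equal(out$state[["slow"]], 40)
  expect_equal(out$state[["metabolic"]], 5.5)
  expect_equal(out$state[["structural"]], 4.5)
  expect_equal(out$flux[["heterotrophic_respiration"]], 0)
})

test_that("single-pool decay matches the flow-table arithmetic", {
  # active pool only: silt+clay = 0.5 gives texture multiplier 0.625 and a
  # respired fraction 0.85 - 0.68*0.5 = 0.51; forcing chosen so defac = 0.5
  site <- site_params(0.5, 0.313, 0.187, bulk_density = 1.0, latitude = 44)
  expect_equal(1 - 0.75 * (site$silt + site$clay), 0.625)
  out <- step_month(pool_state(active = 100),
                    list(tmin = 20, tmax = 20, precip = 120, pet = 100),
                    site)
  decay_expected <- 100 * (1 - exp(-7.3 * 0.5 * 0.625 / 12))  # = 17.3127
  expect_equal(decay_expected, 17.3127, tolerance = 1e-4)
  expect_equal(100 - out$state[["active"]], decay_expected, tolerance = 1e-10)
  expect_equal(out$flux[["heterotrophic_respiration"]],
               decay_expected * 0.51, tolerance = 1e-10)
  # non-respired decay is partitioned between slow and passive
  to_passive <- decay_expected * 0.49 * (0.003 + 0.032 * site$clay)
  expect_equal(out$state[["passive"]], to_passive, tolerance = 1e-10)
  expect_equal(out$state[["slow"]],
               decay_expected * 0.49 - to_passive, tolerance = 1e-10)
})

test_that("cultivation accelerates litter and active decay only", {
  site <- test_site()
  f <- list(tmin = 15, tmax = 25, precip = 100, pet = 80)
  decayed <- function(pool, cultivated) {
    s <- pool_state()
    s[[pool]] <- 50
    50 - step_month(as_pool_state(unclass(s)), f, site,
                    events = list(cultivated = cultivated))$state[[pool]]
  }
  for (pool in c("structural", "metabolic", "active")) {
    expect_gt(decayed(pool, TRUE), decayed(pool, FALSE))
  }
  for (pool in c("slow", "passive")) {
    expect_equal(decayed(pool, TRUE), decayed(pool, FALSE), tolerance = 1e-12)
  }
})

test_that("mass balance closes to 1e-9 relative on randomized runs", {
  set.seed(421)
  station <- test_station()
  for (i in 1:5) {
    sand <- runif(1, 0.2, 0.7)
    clay <- runif(1, 0.1, 0.3) * (1 - sand) / 0.4
    site <- site_params(sand, 1 - sand - clay, clay,
                        bulk_density = runif(1, 0.9, 1.5), latitude = 44)
    sched <- if (i %% 2) grassland_schedule() else
      cropping_schedule(organic_amendment = runif(1, 0, 40))
    init <- pool_state(structural = runif(1, 0, 200),
                       metabolic = runif(1, 0, 100),
                       active = runif(1, 50, 300), slow = runif(1, 500, 3000),
                       passive = runif(1, 300, 2000))
    sim <- run_simulation(init, site, station$weather, sched,
                          years = 8, prdx_mult = runif(1, 0.3, 2))
    expect_lt(mass_balance_error(sim, init), 1e-9)
    expect_true(all(as.matrix(sim$annual[, POOLS]) >= 0))
  }
})

test_that("SOCC conversion matches the density bookkeeping", {
  site <- site_params(0.45, 0.35, 0.20, bulk_density = 1.0, latitude = 44)
  expect_equal(state_socc(pool_state(slow = 2413), site), 12.065)
  # SOCD consistency: g C m-2 times 0.01 equals SOCC*BD*H*0.1
  expect_equal(socd_from_socc(12.065, 1.0, 20), 2413 * 0.01)
})

test_that("with zero production total carbon never increases", {
  site <- test_site()
  station <- test_station()
  init <- pool_state(structural = 100, metabolic = 50, active = 200,
                     slow = 2000, passive = 1000)
  sim <- run_simulation(init, site, station$weather,
                        cropping_schedule(), model_params(prdx = 0),
                        years = 15)
  expect_true(all(diff(sim$annual$total_c) <= 1e-9))
})

test_that("a short weather record recycles with a warning", {
  site <- test_site()
  expect_warning(
    run_simulation(pool_state(active = 100), site, warm_weather(),
                   cropping_schedule(), years = 3),
    "recycling")
})

test_that("steady state is a fixed point of the simulated dynamics", {
  site <- test_site()
  input <- 250
  eq <- steady_state(site, warm_climate(), input)
  # feed the same constant input through the simulator via an amendment-only
  # schedule (prdx = 0) and confirm the trajectory stays flat
  sched <- cropping_schedule(organic_amendment = input,
                             cultivated_months = integer())
  sim <- suppressWarnings(
    run_simulation(eq, site, warm_weather(), sched, model_params(prdx = 0),
                   years = 50))
  rel <- abs(sim$annual$total_c / total_carbon(eq) - 1)
  expect_lt(max(rel), 1e-3)
})

test_that("steady state matches a long from-zero run under fast forcing", {
  # warm, wet forcing keeps even the passive pool's e-folding time ~220
  # years, so 3000 years from zero converges to the fixed point
  site <- test_site()
  eq <- steady_state(site, warm_climate(), 250)
  sched <- cropping_schedule(organic_amendment = 250,
                             cultivated_months = integer())
  long <- equilibrium_stage(site, warm_climate(), sched,
                            model_params(prdx = 0), years = 3000)
  expect_lt(abs(total_carbon(long) / total_carbon(eq) - 1), 1e-3)
})

test_that("steady state handles degenerate inputs", {
  site <- test_site()
  expect_equal(total_carbon(steady_state(site, warm_climate(), 0)), 0)
  expect_error(steady_state(site, warm_climate(), -1), ">= 0")
})

test_that("a slow near-isolated pool equilibrates to input over rate", {
  # with all residue routed to metabolic litter and a small rate constant,
  # the discrete equilibrium approaches the continuous closed form I/k
  site <- test_site()
  p <- model_params(k = c(structural = 3.9, metabolic = 0.2, active = 7.3,
                          slow = 0.2, passive = 0.0045), metabolic_split = 1)
  eq <- steady_state(site, warm_climate(), 10, p)
  expect_equal(eq[["metabolic"]], 10 / 0.2, tolerance = 0.01)
})

test_that("final carbon is non-decreasing in silt+clay", {
  # texture slows active decay and reduces active respiration, so for
  # identical forcing and inputs more silt+clay retains more carbon
  station <- test_station()
  finals <- sapply(seq(0.20, 0.80, by = 0.15), function(sc) {
    site <- site_params(1 - sc, sc * 0.65, sc * 0.35, bulk_density = 1.2,
                        latitude = 44)
    sim <- run_simulation(pool_state(), site, station$weather,
                          cropping_schedule(organic_amendment = 200),
                          model_params(prdx = 0), years = 20)
    sim$annual$total_c[20]
  })
  expect_true(all(diff(finals) > 0))
})

test_that("returning more residue never loses carbon", {
  site <- test_site()
  station <- test_station()
  run_rrf <- function(rrf) {
    sim <- run_simulation(pool_state(slow = 2000), site, station$weather,
                          cropping_schedule(residue_return_fraction = rrf),
                          years = 20)
    sim$annual$total_c[20]
  }
  expect_gte(run_rrf(0.30), run_rrf(0.15))
})
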