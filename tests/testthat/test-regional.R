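make_stations <- function(records) {
  lapply(records, function(r) {
    st <- test_station(seed = r$seed)
    st$id <- r$id
    st$lon <- r$lon
    st$lat <- r$lat
    st$weather$station_id <- r$id
    st
  })
}

test_that("nearest station minimizes haversine distance with id tie-break", {
  stns <- list(list(id = "S2", lon = 125.0, lat = 44.0),
               list(id = "S1", lon = 126.0, lat = 46.0))
  expect_equal(nearest_station(c(125.0, 44.0), stns), "S2")
  # (126, 44) is ~80 km from (125, 44) but ~222 km from (126, 46)
  expect_equal(nearest_station(c(126.0, 44.0), stns), "S2")
  # equidistant stations resolve to the lexicographically lowest id
  twin <- list(list(id = "B", lon = 125.0, lat = 44.0),
               list(id = "A", lon = 127.0, lat = 44.0))
  expect_equal(nearest_station(c(126.0, 44.0), twin), "A")
  expect_error(nearest_station(c(126, 44), list()), "empty")
})

small_region <- function(n = 6, seed = 101) {
  cfg <- generator_config(n_polygons = n, n_stations = 2, seed = seed)
  list(polygons = generate_polygon_db(cfg), stations = generate_weather(cfg))
}

test_that("every polygon is assigned exactly one station", {
  reg <- small_region()
  res <- run_region(reg$polygons, reg$stations, start = 1985, end = 1990)
  expect_equal(length(res$station_id), nrow(reg$polygons))
  expect_true(all(res$station_id %in%
                    vapply(reg$stations, `[[`, "", "id")))
})

test_that("regional aggregates are invariant to polygon order", {
  reg <- small_region()
  res1 <- run_region(reg$polygons, reg$stations, start = 1985, end = 1990)
  res2 <- run_region(reg$polygons[rev(seq_len(nrow(reg$polygons))), ],
                     reg$stations, start = 1985, end = 1990)
  expect_identical(res1$socs, res2$socs)
  expect_identical(res1$socd[order(rownames(res1$socd)), ],
                   res2$socd[order(rownames(res2$socd)), ])
  # determinism: repeating the identical call is bit-identical
  res3 <- run_region(reg$polygons, reg$stations, start = 1985, end = 1990)
  expect_identical(res1$socd, res3$socd)
})

test_that("yearly stocks equal the stock formula applied to that year", {
  reg <- small_region()
  res <- run_region(reg$polygons, reg$stations, start = 1985, end = 1990)
  for (j in seq_along(res$years)) {
    expect_equal(res$socs[[j]],
                 socs_total(res$socd[, j], res$polygons$area_ha))
  }
  expect_equal(res$delta_socd,
               res$socd[, ncol(res$socd)] - res$socd[, 1])
})

test_that("failed polygons are excluded and reported, never silent", {
  reg <- small_region()
  reg$polygons$initial_socc[2] <- 5000  # unreachable calibration target
  expect_message(
    res <- run_region(reg$polygons, reg$stations, start = 1985, end = 1990),
    "1 of 6 polygons failed")
  expect_equal(nrow(res$socd), 5)
  expect_named(res$failures, reg$polygons$id[2])
  expect_match(res$failures[[1]], "achievable range")
})

test_that("run_region validates its year span", {
  reg <- small_region()
  expect_error(run_region(reg$polygons, reg$stations, start = 2015,
                          end = 1985), "start")
})

test_that("group summaries are area-weighted and sum to the regional stock", {
  reg <- small_region(n = 12, seed = 7)
  res <- run_region(reg$polygons, reg$stations, start = 1985, end = 1990)
  g <- soil_group_summary(res)
  expect_equal(sum(g$n), nrow(res$socd))
  ny <- length(res$years)
  expect_equal(sum(g$socs_change_tg), res$socs[[ny]] - res$socs[[1]],
               tolerance = 1e-9)
  # hand-check one group's area weighting
  grp <- g$soil_group[1]
  ix <- which(res$polygons$soil_group == grp)
  a <- res$polygons$area_ha[ix]
  expect_equal(g$socd_start[1], sum(res$socd[ix, 1] * a) / sum(a))
  expect_equal(g$rank, seq_len(nrow(g)))
  expect_true(all(diff(g$socd_start) <= 0))
})

test_that("group summary rejects unknown labels", {
  reg <- small_region()
  res <- run_region(reg$polygons, reg$stations, start = 1985, end = 1990)
  res$polygons$soil_group[1] <- "peat soil"
  expect_error(soil_group_summary(res), "peat soil")
})

test_that("two equal-area groups average to the regional mean", {
  res <- structure(list(
    socd = matrix(c(20, 40, 21, 41), 2,
                  dimnames = list(c("a", "b"), c("1985", "1986"))),
    years = 1985:1986, socs = c(socs_total(c(20, 40), c(100, 100)),
                                socs_total(c(21, 41), c(100, 100))),
    delta_socd = c(a = 1, b = 1),
    polygons = data.frame(id = c("a", "b"), area_ha = c(100, 100),
                          soil_group = c("black soil", "meadow soil")),
    failures = list()), class = "regional_result")
  g <- soil_group_summary(res)
  expect_equal(sort(g$socd_start), c(20, 40))
  expect_equal(mean(g$socd_start), 30)
  expect_equal(mean_delta_socd(res), 1)
})
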