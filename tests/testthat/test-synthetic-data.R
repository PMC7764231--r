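test_that("degenerate config yields an exactly constant series", {
  out <- generateStationSeries(flatConfig())
  expect_true(all(pm25(out$series) == 50))
})

test_that("the firework spike places the national-mean maximum at 02:00 on New Year's Day", {
  cfg <- simulationConfig(nStations = 8L, startDate = "2013-01-01",
                          endDate = "2013-12-31",
                          newYearDates = "2013-02-10", spikePeak = 250,
                          seed = 4L)
  out <- generateStationSeries(cfg)
  nat <- nationalHourlyMean(out$series)
  peak <- nat[which.max(nat$mean), ]
  expect_equal(as.Date(peak$timestamp, tz = "UTC"), as.Date("2013-02-10"))
  expect_equal(as.integer(format(peak$timestamp, "%H", tz = "UTC")), 2L)
})

test_that("generation is seed-deterministic and seed-sensitive", {
  cfg <- simulationConfig(nStations = 4L, startDate = "2013-01-01",
                          endDate = "2013-02-28",
                          newYearDates = "2013-02-10", seed = 9L)
  a <- generateStationSeries(cfg)
  b <- generateStationSeries(cfg)
  expect_identical(pm25(a$series), pm25(b$series))
  expect_identical(stationInfo(a$series), stationInfo(b$series))
  cfg2 <- simulationConfig(nStations = 4L, startDate = "2013-01-01",
                           endDate = "2013-02-28",
                           newYearDates = "2013-02-10", seed = 10L)
  c <- generateStationSeries(cfg2)
  expect_false(identical(pm25(a$series), pm25(c$series)))
})

test_that("concentrations are non-negative and holiday reduction lowers the celebration mean", {
  cfg <- simulationConfig(nStations = 6L, startDate = "2013-01-06",
                          endDate = "2013-03-31",
                          newYearDates = "2013-02-10", spikePeak = 0,
                          holidayReduction = 0.15, seed = 21L)
  out <- generateStationSeries(cfg)
  v <- pm25(out$series)
  expect_true(all(v >= 0))
  d <- as.Date(timestamps(out$series), tz = "UTC")
  win <- seq(as.Date("2013-02-09"), as.Date("2013-02-25"), by = "day")
  pre <- seq(as.Date("2013-01-23"), as.Date("2013-02-08"), by = "day")
  post <- seq(as.Date("2013-02-26"), as.Date("2013-03-14"), by = "day")
  expect_lt(mean(v[, d %in% win]),
            mean(v[, d %in% c(pre, post)]))
})

test_that("invalid configs are rejected", {
  expect_error(simulationConfig(nStations = 0), "nStations")
  expect_error(simulationConfig(spikeHours = c(0, 25)), "spikeHours")
  expect_error(simulationConfig(ar1 = 1), "ar1")
  expect_error(simulationConfig(newYearDates = "2020-02-10"), "inside")
})

test_that("cloud masking follows the configured missingness probability", {
  mkGrids <- function(p) {
    cfg <- simulationConfig(nStations = 2L, lonRange = c(110, 115),
                            latRange = c(28, 33),
                            startDate = "2013-02-01", endDate = "2013-02-10",
                            newYearDates = "2013-02-10",
                            cloudMissingProb = p, seed = 31L)
    sim <- generateStationSeries(cfg)
    generateGrids(cfg, sim$truth,
                  dates = seq(as.Date("2013-02-01"), as.Date("2013-02-05"),
                              by = "day"))
  }
  allMiss <- mkGrids(1)
  expect_true(all(vapply(allMiss, function(g)
    all(is.na(gridValues(g$terra))) && all(is.na(gridValues(g$aqua))),
    logical(1))))
  half <- mkGrids(0.5)
  vals <- unlist(lapply(half, function(g)
    c(is.na(gridValues(g$terra)), is.na(gridValues(g$aqua)))))
  n <- length(vals)
  expect_gte(n, 10000L)
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(mean(vals) - 0.5), 3 * se)
})

test_that("noise-free grids reproduce true PM2.5 exactly under the ground-truth mapping", {
  cfg <- simulationConfig(nStations = 2L, noiseSd = 0, cloudMissingProb = 0,
                          startDate = "2013-01-01", endDate = "2013-12-31",
                          newYearDates = "2013-02-10", seed = 5L)
  sim <- generateStationSeries(cfg)
  days <- as.Date(c("2013-01-15", "2013-06-15", "2013-10-15"))
  grids <- generateGrids(cfg, sim$truth, dates = days)
  tm <- sim$truth@trueMapping
  for (g in grids) {
    aod <- mergeDailyAOD(g$terra, g$aqua)
    lon <- gridLon(aod); lat <- gridLat(aod)
    pmhat <- tm(rep(lon, each = length(lat)), rep(lat, times = length(lon)),
                as.integer(format(g$date, "%j")),
                as.vector(gridValues(aod)), as.vector(gridValues(g$rh)),
                as.vector(gridValues(g$temp)), as.vector(gridValues(g$ws)),
                as.vector(gridValues(g$sp)), as.vector(gridValues(g$hpbl)))
    expect_equal(pmhat, as.vector(gridValues(g$pm25)), tolerance = 1e-12)
  }
})
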