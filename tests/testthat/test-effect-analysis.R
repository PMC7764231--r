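test_that("the national hourly mean averages reporting stations only", {
  ts <- hourly <- seq(as.POSIXct("2013-02-01 00:00:00", tz = "UTC"),
                      by = "hour", length.out = 48)
  v <- rbind(rep(10, 48), rep(30, 48))
  s <- StationSeries(c("A", "B"), c(110, 111), c(30, 31), ts, v)
  nat <- nationalHourlyMean(s)
  expect_true(all(nat$mean == 20))
  ## one station is the identity
  s1 <- StationSeries("A", 110, 30, ts, v[1, , drop = FALSE])
  expect_equal(nationalHourlyMean(s1)$mean, v[1, ])
  ## hour with only one reporter uses that reporter; empty hour is NA
  v2 <- v; v2[1, 5] <- NA; v2[, 7] <- NA
  s2 <- StationSeries(c("A", "B"), c(110, 111), c(30, 31), ts, v2)
  nat2 <- nationalHourlyMean(s2)
  expect_equal(nat2$mean[5], 30)
  expect_true(is.na(nat2$mean[7]))
  ## brute-force loop oracle on a random fixture
  set.seed(3)
  v3 <- matrix(runif(5 * 48, 10, 90), 5, 48)
  v3[sample(length(v3), 40)] <- NA
  s3 <- StationSeries(paste0("S", 1:5), 110 + 1:5, 30 + 1:5 / 10, ts, v3)
  nat3 <- nationalHourlyMean(s3)
  for (j in seq_len(48)) {
    col <- v3[, j]
    want <- if (all(is.na(col))) NA_real_ else mean(col[!is.na(col)])
    expect_equal(nat3$mean[j], want)
  }
})

test_that("daily maxima pick the earliest tied hour and match a scan oracle", {
  cs <- makeCitySeries("2013-02-01", "2013-02-03", value = 50)
  nat <- data.frame(timestamp = cs$times, mean = cs$values)
  dm <- dailyMaxSeries(nat)
  expect_equal(dm$max_hour, c(0L, 0L, 0L))    # constant day -> hour 0
  cs <- setAt(cs, "2013-02-02", 14, 90)
  nat$mean <- cs$values
  dm <- dailyMaxSeries(nat)
  expect_equal(dm$max_value[2], 90)
  expect_equal(dm$max_hour[2], 14L)
  ## random series against a brute-force scan
  set.seed(11)
  nat$mean <- runif(nrow(nat), 20, 80)
  dm <- dailyMaxSeries(nat)
  d <- as.Date(nat$timestamp, tz = "UTC")
  for (i in seq_len(nrow(dm))) {
    vals <- nat$mean[d == dm$date[i]]
    expect_equal(dm$max_value[i], max(vals))
    expect_equal(dm$max_hour[i], which.max(vals) - 1L)
  }
})

test_that("the synthetic spike drives the New Year daily maximum to 02:00", {
  cfg <- simulationConfig(nStations = 6L, startDate = "2013-01-15",
                          endDate = "2013-03-15",
                          newYearDates = "2013-02-10", spikePeak = 250,
                          seed = 23L)
  s <- generateStationSeries(cfg)$series
  dm <- dailyMaxSeries(nationalHourlyMean(s))
  expect_equal(dm$max_hour[dm$date == as.Date("2013-02-10")], 2L)
})

test_that("peakRatio follows its definition and is scale-invariant", {
  dm <- data.frame(date = as.Date("2013-02-09") + 0:2,
                   max_value = c(100, 220, 120),
                   max_hour = c(9L, 2L, 9L))
  expect_equal(peakRatio(dm, "2013-02-10"), 200)
  dmEq <- dm; dmEq$max_value <- c(70, 70, 70)
  expect_equal(peakRatio(dmEq, "2013-02-10"), 100)
  dmScaled <- dm; dmScaled$max_value <- dm$max_value * 3.7
  expect_equal(peakRatio(dmScaled, "2013-02-10"),
               peakRatio(dm, "2013-02-10"))
  dmNA <- dm; dmNA$max_value[3] <- NA
  expect_error(peakRatio(dmNA, "2013-02-10"), "missing")
})

test_that("a calibrated spike reproduces the ~209% peak-to-baseline regime", {
  ## flat noiseless series at 50; a spike of 54.5 at 02:00 makes the New
  ## Year daily maximum 104.5 = 209% of the 50 flanking level, by
  ## construction.
  cfg <- flatConfig(spikePeak = 54.5, seed = 3L)
  s <- generateStationSeries(cfg)$series
  dm <- dailyMaxSeries(nationalHourlyMean(s))
  expect_equal(peakRatio(dm, "2013-02-10"), 209, tolerance = 1e-10)
})

test_that("the three classification rules fire on their constructed examples", {
  div <- division2013()
  ## rule 1: single 300 at 02:00 of New Year's Day in a flat series
  cs <- makeCitySeries("2013-01-20", "2013-03-20", 50)
  cs1 <- setAt(cs, "2013-02-10", 2, 300)
  lab1 <- classifyResponse(cs1$values, cs1$times, div, city = "A")
  expect_identical(responseCategory(lab1), "significant")
  ## rule 2: celebration max on an evening, but New Year's Day has the
  ## strictly largest 00:00-04:00 increase and increase rate
  cs2 <- setAt(cs, "2013-02-14", 20, 400)     # evening max, outside window
  cs2 <- setAt(cs2, "2013-02-10", 4, 80)      # increase 30, rate 0.6
  lab2 <- classifyResponse(cs2$values, cs2$times, div, city = "B")
  expect_identical(responseCategory(lab2), "obvious")
  ## rule 3: constant series
  lab3 <- classifyResponse(cs$values, cs$times, div, city = "C")
  expect_identical(responseCategory(lab3), "weak")
  ## categories are exhaustive and exclusive by construction
  expect_true(responseCategory(lab1) %in% c("significant", "obvious", "weak"))
})

test_that("Lantern Festival days are excluded from classification", {
  div <- division2013()
  ## celebration window is 2013-02-09..2013-02-25; the excluded Lantern
  ## period is its final three days. A huge 02:00 peak there must not win.
  cs <- makeCitySeries("2013-01-20", "2013-03-20", 50)
  cs <- setAt(cs, "2013-02-24", 2, 500)
  lab <- classifyResponse(cs$values, cs$times, div, city = "L")
  expect_identical(responseCategory(lab), "weak")
})

test_that("'significant' is invariant under strictly increasing transforms", {
  div <- division2013()
  cs <- makeCitySeries("2013-01-20", "2013-03-20", 50)
  cs <- setAt(cs, "2013-02-10", 2, 300)
  set.seed(5)
  for (i in 1:20) {
    a <- runif(1, 0.2, 5); b <- runif(1, -10, 60); p <- runif(1, 0.3, 2.5)
    f <- function(x) a * x^p + b
    lab <- classifyResponse(f(cs$values), cs$times, div, city = "T")
    expect_identical(responseCategory(lab), "significant")
  }
})

test_that("exactly the spiked stations are classified significant", {
  cfg <- simulationConfig(nStations = 12L, startDate = "2013-01-06",
                          endDate = "2013-03-31",
                          newYearDates = "2013-02-10", spikePeak = 250,
                          spikeFraction = 0.75, seed = 7L)
  out <- generateStationSeries(cfg)
  truthSpiked <- out$truth@stationLocations$station_id[
    out$truth@stationLocations$spiked]
  expect_length(truthSpiked, 9L)
  labs <- classifyAllStations(out$series, division2013())
  expect_setequal(labs$city[labs$category == "significant"], truthSpiked)
})

test_that("the 2013-2016 study span contains 1389 days", {
  cfg <- simulationConfig(nStations = 1L, startDate = "2013-01-18",
                          endDate = "2016-11-06",
                          newYearDates = character(0),
                          seasonalAmplitude = 0, diurnalAmplitude = 0,
                          noiseSd = 0, spikePeak = 0, holidayReduction = 0,
                          seed = 1L)
  s <- generateStationSeries(cfg)$series
  dm <- dailyMaxSeries(nationalHourlyMean(s))
  expect_equal(nrow(dm), 1389L)
})
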