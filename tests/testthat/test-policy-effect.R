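divPair <- function() {
  divs <- divideAllCycles(as.Date(c("2012-01-23", "2013-02-10",
                                    "2014-01-31")))
  list(prev = divs[[1]], this = divs[[2]])
}

test_that("the 34-day baseline averages the adjacent pre/post periods", {
  dp <- divPair()
  ## pre-1 = 2013-01-23..2013-02-08, post-1 = 2013-02-26..2013-03-14
  cs <- makeCitySeries("2013-01-01", "2013-03-31", 0)
  d <- as.Date(cs$times, tz = "UTC")
  cs$values[d >= as.Date("2013-01-23") & d <= as.Date("2013-02-08")] <- 60
  cs$values[d >= as.Date("2013-02-26") & d <= as.Date("2013-03-14")] <- 40
  expect_equal(baseline34day(cs$values, cs$times, dp$prev, dp$this), 50)
  ## constant series -> the constant
  ck <- makeCitySeries("2013-01-01", "2013-03-31", 72.5)
  expect_equal(baseline34day(ck$values, ck$times, dp$prev, dp$this), 72.5)
  ## random fixture vs brute-force oracle
  set.seed(6)
  cr <- makeCitySeries("2013-01-01", "2013-03-31", 0)
  cr$values <- runif(length(cr$times), 10, 90)
  inBase <- (d >= as.Date("2013-01-23") & d <= as.Date("2013-02-08")) |
            (d >= as.Date("2013-02-26") & d <= as.Date("2013-03-14"))
  expect_equal(baseline34day(cr$values, cr$times, dp$prev, dp$this),
               mean(cr$values[inBase]))
})

test_that("baseline completeness is policed", {
  dp <- divPair()
  cs <- makeCitySeries("2013-01-01", "2013-03-31", 50)
  d <- as.Date(cs$times, tz = "UTC")
  inBase <- (d >= as.Date("2013-01-23") & d <= as.Date("2013-02-08")) |
            (d >= as.Date("2013-02-26") & d <= as.Date("2013-03-14"))
  v <- cs$values
  v[which(inBase)[seq_len(floor(0.6 * sum(inBase)))]] <- NA
  expect_warning(baseline34day(v, cs$times, dp$prev, dp$this),
                 "50% data completeness")
  v[inBase] <- NA
  expect_error(baseline34day(v, cs$times, dp$prev, dp$this), "no data")
})

test_that("celebration anomalies subtract the baseline and keep missingness", {
  dp <- divPair()
  cs <- makeCitySeries("2013-01-01", "2013-03-31", 50)
  cs <- setAt(cs, "2013-02-10", 2, 120)
  i <- which(as.Date(cs$times, tz = "UTC") == as.Date("2013-02-12"))[3]
  cs$values[i] <- NA
  a <- celebrationAnomaly(cs$values, cs$times, dp$prev, dp$this)
  expect_equal(nrow(a), 17L * 24L)
  expect_equal(unique(a$baseline), 50)
  hit <- as.Date(a$timestamp, tz = "UTC") == as.Date("2013-02-10") &
    format(a$timestamp, "%H") == "02"
  expect_equal(a$anomaly[hit], 70)
  expect_true(is.na(a$anomaly[a$timestamp == cs$times[i]]))
  expect_equal(sort(unique(a$anomaly[!hit & !is.na(a$anomaly)])), 0)
  ## adding a constant shifts values and baseline equally
  a2 <- celebrationAnomaly(cs$values + 13, cs$times, dp$prev, dp$this)
  expect_equal(a2$anomaly, a$anomaly)
  ## mean anomaly over the baseline window is zero by construction
  d <- as.Date(cs$times, tz = "UTC")
  inBase <- (d >= as.Date("2013-01-23") & d <= as.Date("2013-02-08")) |
            (d >= as.Date("2013-02-26") & d <= as.Date("2013-03-14"))
  expect_equal(mean(cs$values[inBase] - a$baseline[1]), 0,
               tolerance = 1e-12)
})

test_that("policy years show a reduced discharge-window anomaly", {
  cfg <- simulationConfig(nStations = 8L, startDate = "2012-12-15",
                          endDate = "2014-03-31",
                          newYearDates = c("2013-02-10", "2014-01-31"),
                          spikePeak = c(250, 50), seed = 19L)
  s <- generateStationSeries(cfg)$series
  nat <- nationalHourlyMean(s)
  divs <- divideAllCycles(as.Date(c("2012-01-23", "2013-02-10",
                                    "2014-01-31", "2015-02-19")))
  a13 <- celebrationAnomaly(nat$mean, nat$timestamp, divs[[1]], divs[[2]])
  a14 <- celebrationAnomaly(nat$mean, nat$timestamp, divs[[2]], divs[[3]])
  cmp <- comparePolicyYears(
    list(`2013` = a13, `2014` = a14),
    c(`2013` = as.Date("2013-02-10"), `2014` = as.Date("2014-01-31")),
    policyStartYear = 2014)
  expect_true(cmp$dischargeDeclined)
  expect_lt(cmp$dischargeChange, 0)
  ## the sustained level barely moves compared to the burst reduction
  expect_lt(abs(cmp$fullPeriodChange), abs(cmp$dischargeChange) / 4)
  ## identical years -> exactly zero change
  cmp0 <- comparePolicyYears(
    list(`2013` = a13, `2014` = a13),
    c(`2013` = as.Date("2013-02-10"), `2014` = as.Date("2013-02-10")),
    policyStartYear = 2014)
  expect_equal(cmp0$dischargeChange, 0)
  expect_equal(cmp0$fullPeriodChange, 0)
  expect_false(cmp0$dischargeDeclined)
})
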