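## Shared fixtures: small configs and hand-built series.

## A flat, noise-free config for deterministic arithmetic checks.
flatConfig <- function(...) {
  args <- list(
    nStations = 3L, startDate = "2013-01-20", endDate = "2013-03-20",
    newYearDates = "2013-02-10", seasonalAmplitude = 0,
    diurnalAmplitude = 0, baselineMean = 50, noiseSd = 0, spikePeak = 0,
    holidayReduction = 0, cloudMissingProb = 0, seed = 11L
  )
  args[names(list(...))] <- list(...)
  do.call(simulationConfig, args)
}

## Hourly axis and a single-city value vector initialised to a constant.
makeCitySeries <- function(startDate, endDate, value = 50) {
  ts <- seq(as.POSIXct(paste(startDate, "00:00:00"), tz = "UTC"),
            as.POSIXct(paste(endDate, "23:00:00"), tz = "UTC"),
            by = "hour")
  list(times = ts, values = rep(value, length(ts)))
}

## Set the value at a specific date/hour.
setAt <- function(cs, date, hour, value) {
  i <- which(as.Date(cs$times, tz = "UTC") == as.Date(date) &
               as.integer(format(cs$times, "%H", tz = "UTC")) == hour)
  cs$values[i] <- value
  cs
}

## The 2013 -> 2014 cycle division used across tests.
division2013 <- function() {
  divideCycle(celebrationWindow("2013-02-10"),
              celebrationWindow("2014-01-31"))
}

## Random GridField pair on a shared tiny grid, with missingness.
randomAodPair <- function(nlat = 3L, nlon = 3L, pMiss = 0.3) {
  lon <- 0.05 + 0.1 * (seq_len(nlon) - 1)
  lat <- 0.05 + 0.1 * (seq_len(nlat) - 1)
  mk <- function() {
    v <- matrix(runif(nlat * nlon), nlat, nlon)
    v[runif(nlat * nlon) < pMiss] <- NA_real_
    GridField("AOD", "2013-02-10", lon, lat, v)
  }
  list(terra = mk(), aqua = mk())
}
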