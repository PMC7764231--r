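## Synthetic study generator: station networks, hourly PM2.5 series, and
## consistent AOD/meteorology grids with known ground truth.
##
## The hourly station model is
##   pm25 = [baseline + seasonal(doy) + diurnal(hour)] * holidayFactor
##          + AR(1) noise + firework spike,   truncated at 0,
## with the seasonal cosine peaking on 15 January, a bimodal diurnal term
## (bumps near 09:00 and 22:30), a multiplicative emission reduction over
## each 17-day celebration window, and a Gaussian-shaped spike over the
## configured hours of New Year's Day peaking at its central hour.

.seasonal <- function(doy, amplitude) {
  amplitude * cos(2 * pi * (doy - 15) / 365.25)
}

## Circular-distance Gaussian bumps at 09:00 (sd 2 h) and 22:30 (sd 1.5 h).
.diurnal <- function(hour, amplitude) {
  circ <- function(h, center) {
    d <- abs(h - center)
    pmin(d, 24 - d)
  }
  amplitude * (exp(-circ(hour, 9)^2 / (2 * 2^2)) +
               0.8 * exp(-circ(hour, 22.5)^2 / (2 * 1.5^2)))
}

## Smooth spatial modulation used by the gridded truth (not by stations).
.spatialField <- function(lon, lat, cfg) {
  5 * sin(pi * (lon - cfg@lonRange[1]) / diff(cfg@lonRange)) *
    cos(pi * (lat - cfg@latRange[1]) / diff(cfg@latRange))
}

## 1 inside any celebration window scaled by (1 - holidayReduction).
.holidayFactor <- function(dates, cfg) {
  f <- rep(1, length(dates))
  for (nyd in as.list(cfg@newYearDates)) {
    inWin <- dates >= (nyd - 1L) & dates <= (nyd + 15L)
    f[inWin] <- 1 - cfg@holidayReduction
  }
  f
}

## Spike profile over hour-of-day: unit peak at the central spike hour.
.spikeWeight <- function(hour, cfg) {
  hc <- stats::median(as.numeric(cfg@spikeHours))
  w <- exp(-(hour - hc)^2 / 2)
  w[!(hour %in% cfg@spikeHours)] <- 0
  w
}

## The deterministic AOD/meteorology -> PM2.5 relationship the retrieval
## model must recover. Smooth and mildly nonlinear: AOD enters through a
## product with humidity growth and boundary-layer dilution.
.makeTrueMapping <- function(cfg) {
  lonRange <- cfg@lonRange
  latRange <- cfg@latRange
  force(lonRange); force(latRange)
  spatial <- function(lon, lat) {
    5 * sin(pi * (lon - lonRange[1]) / diff(lonRange)) *
      cos(pi * (lat - latRange[1]) / diff(latRange))
  }
  function(lon, lat, doy, aod, rh, temp, ws, sp, hpbl) {
    rest <- 5 + 0.3 * (temp - 280) - 1.5 * ws +
      2 * (sp - 101325) / 1000 + spatial(lon, lat) +
      5 * cos(2 * pi * (doy - 15) / 365.25)
    rest + 40 * aod * (1500 / (hpbl + 500)) * (1 + rh / 100)
  }
}

#' Generate an hourly synthetic station network with known ground truth
#'
#' Simulates hourly PM2.5 for `nStations` stations placed uniformly at
#' random inside the bounding box. Each series is the sum of a baseline, a
#' winter-peaking seasonal cosine, a bimodal diurnal cycle, stationary
#' AR(1) noise, and a firework spike over the configured hours of each New
#' Year's Day; a fractional emission reduction is applied across each
#' 17-day celebration window, and concentrations are truncated at zero.
#' Identical config and seed give bit-identical output.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `series` (a [StationSeries-class]) and `truth`
#'   (a [GroundTruth-class]).
#' @examples
#' out <- generateStationSeries(simulationConfig(nStations = 3, seed = 1))
#' out$series
#' @export
generateStationSeries <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  cfg <- config

  ids <- sprintf("S%03d", seq_len(cfg@nStations))
  loc <- withSeed(subSeed(cfg@seed, 1), {
    data.frame(
      station_id = ids,
      lon = runif(cfg@nStations, cfg@lonRange[1], cfg@lonRange[2]),
      lat = runif(cfg@nStations, cfg@latRange[1], cfg@latRange[2]),
      stringsAsFactors = FALSE
    )
  })
  nSpiked <- ceiling(cfg@spikeFraction * cfg@nStations)
  spikedIdx <- withSeed(subSeed(cfg@seed, 2),
                        sample(cfg@nStations))[seq_len(nSpiked)]
  loc$spiked <- seq_len(cfg@nStations) %in% spikedIdx

  ts <- hourlyAxis(cfg@startDate, cfg@endDate)
  nT <- length(ts)
  dates <- tsDate(ts)
  hours <- tsHour(ts)

  structural <- (cfg@baselineMean +
                 .seasonal(dayOfYear(dates), cfg@seasonalAmplitude) +
                 .diurnal(hours, cfg@diurnalAmplitude)) *
                .holidayFactor(dates, cfg)

  ## Firework spike template per New Year (unit peak, scaled per year).
  peaks <- rep_len(cfg@spikePeak, length(cfg@newYearDates))
  spike <- numeric(nT)
  for (i in seq_along(cfg@newYearDates)) {
    onDay <- dates == cfg@newYearDates[i]
    spike[onDay] <- spike[onDay] + peaks[i] * .spikeWeight(hours[onDay], cfg)
  }

  values <- matrix(0, nrow = cfg@nStations, ncol = nT,
                   dimnames = list(ids, NULL))
  noise <- withSeed(subSeed(cfg@seed, 3), {
    if (cfg@noiseSd > 0) {
      innovSd <- cfg@noiseSd * sqrt(1 - cfg@ar1^2)
      m <- matrix(0, cfg@nStations, nT)
      m[, 1] <- rnorm(cfg@nStations, 0, cfg@noiseSd)
      if (nT > 1) {
        eps <- matrix(rnorm(cfg@nStations * (nT - 1), 0, innovSd),
                      cfg@nStations, nT - 1)
        for (t in 2:nT) m[, t] <- cfg@ar1 * m[, t - 1] + eps[, t - 1]
      }
      m
    } else {
      matrix(0, cfg@nStations, nT)
    }
  })
  for (s in seq_len(cfg@nStations)) {
    v <- structural + noise[s, ]
    if (loc$spiked[s]) v <- v + spike
    values[s, ] <- pmax(v, 0)
  }

  series <- StationSeries(ids, loc$lon, loc$lat, ts, values)
  events <- data.frame(date = cfg@newYearDates, magnitude = peaks)
  events <- events[events$magnitude > 0, , drop = FALSE]
  truth <- new("GroundTruth",
    trueMapping = .makeTrueMapping(cfg),
    stationLocations = loc,
    eventCalendar = events,
    params = list(seed = cfg@seed,
                  diurnalDailyMean = mean(.diurnal(0:23, cfg@diurnalAmplitude)))
  )
  list(series = series, truth = truth)
}

## Daily AR(1) scalar anomaly series, one value per day.
.dailyAR <- function(n, sd, phi = 0.8) {
  if (sd == 0 || n == 0) return(numeric(n))
  z <- numeric(n)
  z[1] <- rnorm(1, 0, sd)
  if (n > 1) {
    innov <- rnorm(n - 1, 0, sd * sqrt(1 - phi^2))
    for (t in 2:n) z[t] <- phi * z[t - 1] + innov[t - 1]
  }
  z
}

#' Generate daily AOD and meteorology grids consistent with ground truth
#'
#' For each day, smooth meteorological fields (RH, TEMP, WS, SP, HPBL) are
#' generated with seasonal cycles, smooth spatial structure, and
#' AR(1)-autocorrelated daily anomalies. The daily true PM2.5 field is the
#' structural station model (daily mean of the diurnal term, holiday
#' reduction applied) plus a smooth spatial modulation; the true AOD field
#' is obtained by inverting the ground-truth mapping at that PM2.5 level,
#' so that with no noise the nine retrieval predictors reproduce true PM2.5
#' exactly. Terra-like and Aqua-like overpasses both observe the daily AOD
#' and are independently cloud-masked pixel-wise with probability
#' `cloudMissingProb`. The emitted PM2.5 label grid adds independent daily
#' observation noise with SD `noiseSd / sqrt(24)` (the daily-mean noise
#' implied by the hourly noise level).
#'
#' @param config a [SimulationConfig-class] (same one used for the series).
#' @param truth the matching [GroundTruth-class].
#' @param dates optional subset of days to generate (default: full span).
#' @return named list (one element per day) of lists with components
#'   `date`, `terra`, `aqua`, `rh`, `temp`, `ws`, `sp`, `hpbl`, `pm25`,
#'   each a [GridField-class] except `date`.
#' @export
generateGrids <- function(config, truth, dates = NULL) {
  stopifnot(is(config, "SimulationConfig"), is(truth, "GroundTruth"))
  validObject(config)
  cfg <- config
  lon <- gridCenters(cfg@lonRange, cfg@gridResolution)
  lat <- gridCenters(cfg@latRange, cfg@gridResolution)
  G <- expand.grid(lat = lat, lon = lon)   # column-major: rows=lat
  nPix <- nrow(G)
  allDays <- seq(cfg@startDate, cfg@endDate, by = "day")
  if (is.null(dates)) dates <- allDays
  dates <- as.Date(dates)
  stopifnot(all(dates %in% allDays))

  spat <- .spatialField(G$lon, G$lat, cfg)
  spatUnit <- spat / 5
  latMid <- mean(cfg@latRange)
  dmean <- mean(.diurnal(0:23, cfg@diurnalAmplitude))

  nD <- length(allDays)
  ar <- withSeed(subSeed(cfg@seed, 4), {
    list(rh = .dailyAR(nD, 6), temp = .dailyAR(nD, 2),
         ws = .dailyAR(nD, 0.7), sp = .dailyAR(nD, 150),
         hpbl = .dailyAR(nD, 80))
  })

  mkField <- function(var, date, vals) {
    GridField(var, date, lon, lat,
              matrix(vals, nrow = length(lat), ncol = length(lon)))
  }

  labelNoiseSd <- cfg@noiseSd / sqrt(24)
  out <- vector("list", length(dates))
  names(out) <- format(dates)
  for (k in seq_along(dates)) {
    d <- dates[k]
    i <- match(d, allDays)
    doy <- dayOfYear(d)

    rh <- pmin(pmax(65 + 10 * sin(2 * pi * (doy + 120) / 365.25) +
                      5 * spatUnit + ar$rh[i], 20), 100)
    temp <- 287 - 12 * cos(2 * pi * (doy - 15) / 365.25) -
      0.5 * (G$lat - latMid) + ar$temp[i]
    ws <- pmax(3 + sin(2 * pi * doy / 365.25) + 0.5 * spatUnit + ar$ws[i],
               0.3)
    sp <- 101325 - 30 * (G$lat - latMid) + ar$sp[i]
    hpbl <- pmax(900 + 400 * cos(2 * pi * (doy - 196) / 365.25) +
                   100 * spatUnit + ar$hpbl[i], 200)

    holiday <- .holidayFactor(d, cfg)
    pmTrue <- (cfg@baselineMean + .seasonal(doy, cfg@seasonalAmplitude) +
                 dmean) * holiday + spat

    ## Invert the true mapping at the daily PM2.5 level to obtain AOD.
    rest <- 5 + 0.3 * (temp - 280) - 1.5 * ws +
      2 * (sp - 101325) / 1000 + spat +
      5 * cos(2 * pi * (doy - 15) / 365.25)
    mult <- 40 * (1500 / (hpbl + 500)) * (1 + rh / 100)
    aod <- pmax((pmTrue - rest) / mult, 0.001)

    dayRng <- withSeed(subSeed(cfg@seed, 5) + i, {
      list(
        maskT = runif(nPix) < cfg@cloudMissingProb,
        maskA = runif(nPix) < cfg@cloudMissingProb,
        labelNoise = if (labelNoiseSd > 0) rnorm(nPix, 0, labelNoiseSd)
                     else numeric(nPix)
      )
    })
    terra <- aod; terra[dayRng$maskT] <- NA_real_
    aqua <- aod; aqua[dayRng$maskA] <- NA_real_
    pmLabel <- pmax(pmTrue + dayRng$labelNoise, 0)

    out[[k]] <- list(
      date = d,
      terra = mkField("AOD", d, terra),
      aqua = mkField("AOD", d, aqua),
      rh = mkField("RH", d, rh),
      temp = mkField("TEMP", d, temp),
      ws = mkField("WS", d, ws),
      sp = mkField("SP", d, sp),
      hpbl = mkField("HPBL", d, hpbl),
      pm25 = mkField("PM2.5", d, pmLabel)
    )
  }
  out
}

#' Assemble retrieval training samples from daily grid sets
#'
#' Merges the Terra-like and Aqua-like overpasses of each day with
#' [mergeDailyAOD()], then collects one row per pixel-day with all nine
#' predictors present, labelled with the day's PM2.5 grid.
#'
#' @param gridDays output of [generateGrids()].
#' @param n optional subsample size (without replacement).
#' @param seed RNG seed for the subsample.
#' @return data.frame with columns `lon`, `lat`, `doy`, `aod`, `rh`,
#'   `temp`, `ws`, `sp`, `hpbl`, `pm25`, `date`.
#' @export
trainingSamples <- function(gridDays, n = NULL, seed = 1L) {
  stopifnot(length(gridDays) > 0)
  rows <- lapply(gridDays, function(day) {
    aod <- mergeDailyAOD(day$terra, day$aqua)
    lat <- gridLat(aod); lon <- gridLon(aod)
    df <- data.frame(
      lon = rep(lon, each = length(lat)),
      lat = rep(lat, times = length(lon)),
      doy = dayOfYear(day$date),
      aod = as.vector(gridValues(aod)),
      rh = as.vector(gridValues(day$rh)),
      temp = as.vector(gridValues(day$temp)),
      ws = as.vector(gridValues(day$ws)),
      sp = as.vector(gridValues(day$sp)),
      hpbl = as.vector(gridValues(day$hpbl)),
      pm25 = as.vector(gridValues(day$pm25))
    )
    df$date <- day$date
    df[stats::complete.cases(df), , drop = FALSE]
  })
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL
  if (!is.null(n) && n < nrow(samples)) {
    keep <- withSeed(seed, sample(nrow(samples), n))
    samples <- samples[sort(keep), , drop = FALSE]
  }
  samples
}
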