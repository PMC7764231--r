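## Constructors, accessors and show() methods for the core classes.

#' Build a simulation configuration
#'
#' All arguments have defaults describing the study conditions the pipeline
#' is exercised under: a modest regional network in central China, a
#' winter-peaking seasonal cycle, a bimodal diurnal cycle, AR(1) hourly
#' noise, a firework spike over 00:00-04:00 of New Year's Day peaking at
#' 02:00, a 10% holiday emission reduction over the 17-day celebration
#' window, and 50% satellite cloud missingness.
#'
#' @param nStations number of monitoring stations.
#' @param lonRange,latRange bounding box in degrees.
#' @param gridResolution cell size in degrees.
#' @param startDate,endDate simulation span (`Date` or parseable string).
#' @param newYearDates Lunar New Year's Day for each simulated year.
#' @param seasonalAmplitude,diurnalAmplitude,baselineMean,noiseSd ug/m3.
#' @param ar1 lag-1 autocorrelation of the hourly noise.
#' @param spikePeak peak firework enhancement (ug/m3); recycled over
#'   `newYearDates`, so prohibition years can be given a reduced spike.
#' @param spikeHours integer hour offsets from 00:00 of New Year's Day.
#' @param spikeFraction fraction of stations receiving the spike.
#' @param holidayReduction fractional emission reduction over the
#'   celebration window.
#' @param cloudMissingProb per-pixel AOD missingness probability.
#' @param seed integer RNG seed.
#' @return a validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nStations = 5, seed = 7)
#' cfg
#' @export
simulationConfig <- function(nStations = 25L,
                             lonRange = c(110, 114),
                             latRange = c(28, 32),
                             gridResolution = 0.1,
                             startDate = "2013-01-01",
                             endDate = "2013-12-31",
                             newYearDates = "2013-02-10",
                             seasonalAmplitude = 30,
                             diurnalAmplitude = 15,
                             baselineMean = 50,
                             noiseSd = 10,
                             ar1 = 0.6,
                             spikePeak = 250,
                             spikeHours = 0:4,
                             spikeFraction = 1,
                             holidayReduction = 0.1,
                             cloudMissingProb = 0.5,
                             seed = 1L) {
  new("SimulationConfig",
    nStations = as.integer(nStations),
    lonRange = as.numeric(lonRange),
    latRange = as.numeric(latRange),
    gridResolution = as.numeric(gridResolution),
    startDate = as.Date(startDate),
    endDate = as.Date(endDate),
    newYearDates = as.Date(newYearDates),
    seasonalAmplitude = as.numeric(seasonalAmplitude),
    diurnalAmplitude = as.numeric(diurnalAmplitude),
    baselineMean = as.numeric(baselineMean),
    noiseSd = as.numeric(noiseSd),
    ar1 = as.numeric(ar1),
    spikePeak = as.numeric(spikePeak),
    spikeHours = as.integer(spikeHours),
    spikeFraction = as.numeric(spikeFraction),
    holidayReduction = as.numeric(holidayReduction),
    cloudMissingProb = as.numeric(cloudMissingProb),
    seed = as.integer(seed)
  )
}

#' Construct a StationSeries
#'
#' @param stationId character vector of station identifiers (unique).
#' @param lon,lat station coordinates, degrees.
#' @param timestamps POSIXct vector, strictly increasing, hourly.
#' @param pm25 matrix stations x hours (ug/m3, `NA` = missing).
#' @return a [StationSeries-class] object.
#' @export
StationSeries <- function(stationId, lon, lat, timestamps, pm25) {
  stopifnot(!anyDuplicated(stationId))
  pm25 <- as.matrix(pm25)
  rownames(pm25) <- stationId
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(pm25 = pm25),
    rowData = S4Vectors::DataFrame(lon = as.numeric(lon),
                                   lat = as.numeric(lat),
                                   row.names = stationId),
    colData = S4Vectors::DataFrame(timestamp = timestamps)
  )
  new("StationSeries", se)
}

#' Extract the PM2.5 matrix of a StationSeries
#' @param x a [StationSeries-class].
#' @return stations x hours numeric matrix (ug/m3).
#' @export
pm25 <- function(x) SummarizedExperiment::assay(x, "pm25")

#' Station metadata of a StationSeries
#' @param x a [StationSeries-class].
#' @return data.frame with `station_id`, `lon`, `lat`.
#' @export
stationInfo <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  data.frame(station_id = rownames(rd), lon = rd$lon, lat = rd$lat,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hourly timestamp axis of a StationSeries
#' @param x a [StationSeries-class].
#' @return POSIXct vector.
#' @export
timestamps <- function(x) SummarizedExperiment::colData(x)$timestamp

setMethod("show", "StationSeries", function(object) {
  ts <- timestamps(object)
  cat("StationSeries:", nrow(object), "stations x", ncol(object), "hours\n")
  cat("  span:", format(min(ts)), "to", format(max(ts)), "\n")
  v <- pm25(object)
  cat(sprintf("  pm25: mean %.1f ug/m3, %.1f%% missing\n",
              mean(v, na.rm = TRUE), 100 * mean(is.na(v))))
})

#' Construct a GridField
#'
#' @param variable one of `"AOD"`, `"RH"`, `"TEMP"`, `"WS"`, `"SP"`,
#'   `"HPBL"`, `"PM2.5"`.
#' @param date calendar day.
#' @param lon,lat ascending pixel-center coordinates, degrees.
#' @param values numeric matrix `length(lat)` x `length(lon)`; `NA` marks
#'   missing pixels.
#' @param units unit string; defaults to the variable's standard unit.
#' @return a [GridField-class] object.
#' @export
GridField <- function(variable, date, lon, lat, values, units = NULL) {
  if (is.null(units)) {
    units <- .GRID_UNITS[[variable]]
    if (is.null(units)) units <- "1"
  }
  new("GridField", variable = variable, units = units, date = as.Date(date),
      lon = as.numeric(lon), lat = as.numeric(lat),
      values = as.matrix(values))
}

#' @describeIn GridField raster values (rows = lat, cols = lon).
#' @param x a [GridField-class].
#' @export
gridValues <- function(x) x@values

#' @describeIn GridField pixel-center longitudes.
#' @export
gridLon <- function(x) x@lon

#' @describeIn GridField pixel-center latitudes.
#' @export
gridLat <- function(x) x@lat

#' @describeIn GridField variable name.
#' @export
gridVariable <- function(x) x@variable

#' @describeIn GridField unit string.
#' @export
gridUnits <- function(x) x@units

#' @describeIn GridField calendar day.
#' @export
gridDate <- function(x) x@date

setMethod("show", "GridField", function(object) {
  cat(sprintf("GridField %s [%s] %s: %d x %d pixels, %.1f%% missing\n",
              object@variable, object@units, format(object@date),
              length(object@lat), length(object@lon),
              100 * mean(is.na(object@values))))
})

#' @describeIn celebrationWindow window start (New Year's Eve).
#' @param x a [CelebrationWindow-class].
#' @export
windowStart <- function(x) x@start

#' @describeIn celebrationWindow window end (day after the Lantern
#'   Festival).
#' @export
windowEnd <- function(x) x@end

#' @describeIn celebrationWindow lunar-year tag.
#' @export
yearTag <- function(x) x@yearTag

setMethod("show", "CelebrationWindow", function(object) {
  cat(sprintf("CelebrationWindow %s: %s to %s (17 days)\n", object@yearTag,
              format(object@start), format(object@end)))
})

#' Period table of a PeriodDivision
#' @param x a [PeriodDivision-class].
#' @return data.frame with `label`, `start`, `end` in chronological order.
#' @export
periodTable <- function(x) x@periods

#' @describeIn periodTable lunar-year tag of the anchoring celebration.
#' @export
cycleTag <- function(x) x@cycleTag

setMethod("show", "PeriodDivision", function(object) {
  p <- object@periods
  res <- p[p$label == "pre-10", ]
  cat(sprintf("PeriodDivision [cycle %s]: 21 periods, %s to %s (pre-10 residual: %d days)\n",
              object@cycleTag, format(min(p$start)), format(max(p$end)),
              as.integer(res$end - res$start) + 1L))
})

setMethod("show", "RetrievalModel", function(object) {
  cat(sprintf("RetrievalModel: %d -> %d -> 1 (%s hidden units)\n",
              nrow(object@W1), ncol(object@W1), object@activation))
  lg <- object@trainingLog
  if (length(lg))
    cat(sprintf("  trained %d epochs (%s), final loss %.3g, seed %d\n",
                lg$epochs, lg$method, lg$finalLoss, lg$seed))
})

#' @describeIn pearsonR construct a FitMetrics object.
#' @param r,rmse,n metric values.
#' @export
FitMetrics <- function(r, rmse, n) {
  new("FitMetrics", r = as.numeric(r), rmse = as.numeric(rmse),
      n = as.integer(n))
}

#' @describeIn pearsonR Pearson correlation stored in a FitMetrics.
#' @param x a [FitMetrics-class].
#' @export
fitR <- function(x) x@r

#' @describeIn pearsonR RMSE stored in a FitMetrics.
#' @export
fitRMSE <- function(x) x@rmse

#' @describeIn pearsonR sample count stored in a FitMetrics.
#' @export
fitN <- function(x) x@n

setMethod("show", "FitMetrics", function(object) {
  cat(sprintf("FitMetrics: R = %.4f, RMSE = %.4f ug/m3 (n = %d)\n",
              object@r, object@rmse, object@n))
})

#' @describeIn classifyResponse category of a ResponseLabel.
#' @param x a [ResponseLabel-class].
#' @export
responseCategory <- function(x) x@category

#' @describeIn classifyResponse per-day evidence table of a ResponseLabel.
#' @export
responseEvidence <- function(x) x@evidence

setMethod("show", "ResponseLabel", function(object) {
  cat(sprintf("ResponseLabel: %s / cycle %s -> %s\n", object@city,
              object@cycleTag, object@category))
})
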