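#' @import methods
#' @importFrom stats rnorm runif sd predict
#' @importFrom utils head tail
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame
NULL

## Canonical predictor order used everywhere in the retrieval chain.
.FEATURES <- c("lon", "lat", "doy", "aod", "rh", "temp", "ws", "sp", "hpbl")

.GRID_UNITS <- c(
  AOD = "1", RH = "%", TEMP = "K", WS = "m/s", SP = "Pa",
  HPBL = "m", PM2.5 = "ug/m3"
)

#' SimulationConfig: parameters of the synthetic study
#'
#' Holds every knob of the synthetic-data generator: the station network,
#' the grid geometry, the calendar (including the Lunar New Year anchor
#' dates), and the components of the generative PM2.5 model (baseline,
#' seasonal and diurnal amplitudes, AR(1) noise, the firework spike, the
#' holiday emission reduction, and satellite cloud missingness).
#'
#' @slot nStations number of monitoring stations.
#' @slot lonRange,latRange bounding box, degrees (pixel-edge extent).
#' @slot gridResolution grid cell size in degrees (default 0.1).
#' @slot startDate,endDate simulated calendar span.
#' @slot newYearDates Lunar New Year's Day for each simulated year.
#' @slot seasonalAmplitude amplitude of the winter-peaking seasonal cosine,
#'   ug/m3.
#' @slot diurnalAmplitude amplitude of the bimodal diurnal term, ug/m3.
#' @slot baselineMean long-term mean concentration, ug/m3.
#' @slot noiseSd marginal SD of the hourly AR(1) noise, ug/m3.
#' @slot ar1 lag-1 autocorrelation of the noise, in [0, 1).
#' @slot spikePeak peak firework enhancement, ug/m3; may be a vector
#'   recycled over `newYearDates` so that prohibition-policy years can
#'   carry a smaller spike.
#' @slot spikeHours hour offsets from 00:00 of New Year's Day that receive
#'   the spike (default 0:4).
#' @slot spikeFraction fraction of stations that experience the firework
#'   spike (1 = all cities discharge).
#' @slot holidayReduction fractional emission reduction applied over the
#'   17-day celebration window, in [0, 1).
#' @slot cloudMissingProb per-pixel probability that a satellite AOD value
#'   is cloud-masked, in [0, 1].
#' @slot seed integer RNG seed; all generator randomness derives from it.
#' @seealso [simulationConfig()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nStations = "integer",
    lonRange = "numeric",
    latRange = "numeric",
    gridResolution = "numeric",
    startDate = "Date",
    endDate = "Date",
    newYearDates = "Date",
    seasonalAmplitude = "numeric",
    diurnalAmplitude = "numeric",
    baselineMean = "numeric",
    noiseSd = "numeric",
    ar1 = "numeric",
    spikePeak = "numeric",
    spikeHours = "integer",
    spikeFraction = "numeric",
    holidayReduction = "numeric",
    cloudMissingProb = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (length(object@nStations) != 1L || object@nStations < 1L)
    msg <- c(msg, "nStations must be a single integer >= 1")
  if (length(object@lonRange) != 2L || diff(object@lonRange) <= 0)
    msg <- c(msg, "lonRange must be an increasing pair")
  if (length(object@latRange) != 2L || diff(object@latRange) <= 0)
    msg <- c(msg, "latRange must be an increasing pair")
  if (object@gridResolution <= 0)
    msg <- c(msg, "gridResolution must be > 0")
  if (object@startDate >= object@endDate)
    msg <- c(msg, "startDate must precede endDate")
  if (length(object@newYearDates) &&
      (any(object@newYearDates < object@startDate) ||
       any(object@newYearDates > object@endDate)))
    msg <- c(msg, "every newYearDate must lie inside [startDate, endDate]")
  nonneg <- c(seasonal = object@seasonalAmplitude,
              diurnal = object@diurnalAmplitude,
              baseline = object@baselineMean, noise = object@noiseSd)
  if (any(nonneg < 0))
    msg <- c(msg, "amplitudes, baseline and noise SD must be >= 0")
  if (any(object@spikePeak < 0)) msg <- c(msg, "spikePeak must be >= 0")
  if (object@ar1 < 0 || object@ar1 >= 1)
    msg <- c(msg, "ar1 must lie in [0, 1)")
  if (any(object@spikeHours < 0L) || any(object@spikeHours > 23L))
    msg <- c(msg, "spikeHours must lie in 0-23")
  if (object@spikeFraction < 0 || object@spikeFraction > 1)
    msg <- c(msg, "spikeFraction must lie in [0, 1]")
  if (object@holidayReduction < 0 || object@holidayReduction >= 1)
    msg <- c(msg, "holidayReduction must lie in [0, 1)")
  if (object@cloudMissingProb < 0 || object@cloudMissingProb > 1)
    msg <- c(msg, "cloudMissingProb must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: what the synthetic generator knows
#'
#' Returned alongside every synthetic [StationSeries] so that recovery tests
#' can compare estimates against the generative truth.
#'
#' @slot trueMapping deterministic function
#'   `(lon, lat, doy, aod, rh, temp, ws, sp, hpbl) -> PM2.5` (ug/m3); the
#'   smooth nonlinear relationship the retrieval model must recover.
#' @slot stationLocations data.frame with `station_id`, `lon`, `lat`, and
#'   logical `spiked` (whether the station receives the firework spike).
#' @slot eventCalendar data.frame with `date` (New Year's Day) and
#'   `magnitude` (peak spike, ug/m3) per simulated year.
#' @slot params list of internal generative coefficients (reproducible from
#'   the config seed).
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    trueMapping = "function",
    stationLocations = "data.frame",
    eventCalendar = "data.frame",
    params = "list"
  )
)

setValidity("GroundTruth", function(object) {
  if (nrow(object@eventCalendar) && any(object@eventCalendar$magnitude <= 0))
    return("event magnitudes must be > 0")
  TRUE
})

#' StationSeries: hourly PM2.5 observations for a station network
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay `"pm25"`
#' (stations x hours, ug/m3, `NA` = missing), station coordinates in
#' `rowData` (`lon`, `lat`), and the hourly timestamp axis in
#' `colData(x)$timestamp` (POSIXct, one national clock, no DST).
#'
#' @seealso [StationSeries()], [pm25()], [stationInfo()], [timestamps()]
#' @exportClass StationSeries
setClass("StationSeries", contains = "SummarizedExperiment")

setValidity("StationSeries", function(object) {
  msg <- character()
  if (!"pm25" %in% SummarizedExperiment::assayNames(object))
    return("assay 'pm25' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("lon", "lat") %in% colnames(rd)))
    return("rowData must contain 'lon' and 'lat'")
  if (any(rd$lon < -180 | rd$lon > 180)) msg <- c(msg, "lon outside [-180, 180]")
  if (any(rd$lat < -90 | rd$lat > 90)) msg <- c(msg, "lat outside [-90, 90]")
  ts <- SummarizedExperiment::colData(object)$timestamp
  if (is.null(ts) || !inherits(ts, "POSIXct"))
    return("colData must contain POSIXct 'timestamp'")
  if (length(ts) > 1L) {
    dt <- diff(as.numeric(ts))
    if (any(dt != 3600))
      msg <- c(msg, "timestamps must be strictly increasing at 1-hour resolution")
  }
  v <- SummarizedExperiment::assay(object, "pm25")
  if (any(v < 0, na.rm = TRUE)) msg <- c(msg, "pm25 must be >= 0 or missing")
  if (length(msg)) msg else TRUE
})

#' GridField: one georeferenced daily raster
#'
#' A single variable (AOD, a meteorological field, or retrieved PM2.5) on a
#' regular lon/lat grid for one calendar day. Values are stored as a matrix
#' with rows = latitude (ascending) and columns = longitude (ascending);
#' `NA` marks missing pixels. Coordinates are pixel centers.
#'
#' @slot variable variable name, one of AOD, RH, TEMP, WS, SP, HPBL, PM2.5.
#' @slot units unit string (preserved verbatim through file round trips).
#' @slot date calendar day.
#' @slot lon,lat pixel-center coordinate vectors, degrees, ascending.
#' @slot values numeric matrix `length(lat)` x `length(lon)`.
#' @seealso [GridField()], [readGrid()], [writeGrid()], [mergeDailyAOD()]
#' @exportClass GridField
setClass("GridField",
  representation(
    variable = "character",
    units = "character",
    date = "Date",
    lon = "numeric",
    lat = "numeric",
    values = "matrix"
  )
)

setValidity("GridField", function(object) {
  msg <- character()
  if (!identical(dim(object@values),
                 c(length(object@lat), length(object@lon))))
    return("values must be a length(lat) x length(lon) matrix")
  if (length(object@lon) > 1L && any(diff(object@lon) <= 0))
    msg <- c(msg, "lon must be strictly increasing")
  if (length(object@lat) > 1L && any(diff(object@lat) <= 0))
    msg <- c(msg, "lat must be strictly increasing")
  if (any(object@lon < -180 | object@lon > 180))
    msg <- c(msg, "lon outside [-180, 180]")
  if (any(object@lat < -90 | object@lat > 90))
    msg <- c(msg, "lat outside [-90, 90]")
  if (identical(object@variable, "AOD") &&
      any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "AOD must be >= 0 where present")
  if (length(msg)) msg else TRUE
})

#' CelebrationWindow: the 17-day New Year celebration period
#'
#' The festival window runs from Lunar New Year's Eve through the day after
#' the Lantern Festival (lunar day 16), a fixed span of 17 days; New Year's
#' Day is the second day of the window.
#'
#' @slot yearTag label for the lunar year (calendar year of New Year's Day).
#' @slot start New Year's Eve.
#' @slot end day after the Lantern Festival (`start + 16`).
#' @seealso [celebrationWindow()]
#' @exportClass CelebrationWindow
setClass("CelebrationWindow",
  representation(yearTag = "character", start = "Date", end = "Date")
)

setValidity("CelebrationWindow", function(object) {
  if (as.integer(object@end - object@start) + 1L != 17L)
    return("celebration window must span exactly 17 days")
  TRUE
})

#' PeriodDivision: one lunar cycle tiled into 21 labeled periods
#'
#' A lunar cycle (one celebration window through the day before the next)
#' split into the celebration period, ten post-celebration periods, and ten
#' pre-celebration periods (the following year's run-up). All periods are
#' 17 days except `pre-10`, which absorbs the cycle's residual days.
#'
#' @slot cycleTag lunar-year identifier of the anchoring celebration.
#' @slot periods data.frame with columns `label`, `start`, `end`, in
#'   chronological order (`celebration`, `post-1` ... `post-10`, `pre-10`,
#'   `pre-9` ... `pre-1`).
#' @seealso [divideCycle()], [assignPeriod()]
#' @exportClass PeriodDivision
setClass("PeriodDivision",
  representation(cycleTag = "character", periods = "data.frame")
)

setValidity("PeriodDivision", function(object) {
  p <- object@periods
  if (!all(c("label", "start", "end") %in% colnames(p)))
    return("periods needs columns label, start, end")
  if (nrow(p) != 21L) return("a cycle must contain exactly 21 periods")
  len <- as.integer(p$end - p$start) + 1L
  full <- p$label != "pre-10"
  if (any(len[full] != 17L))
    return("all periods except pre-10 must span exactly 17 days")
  if (len[p$label == "pre-10"] < 0L)
    return("pre-10 residual length must be >= 0")
  ne <- p[len > 0L, ]
  if (nrow(ne) > 1L) {
    gaps <- as.integer(ne$start[-1L] - ne$end[-nrow(ne)])
    if (any(gaps != 1L)) return("periods must tile the cycle contiguously")
  }
  TRUE
})

#' RetrievalModel: the trained 9-18-1 back-propagation network
#'
#' Weights, biases, and normalization constants of the three-layer
#' feed-forward network that maps the nine predictors (lon, lat, day of
#' year, AOD, RH, TEMP, WS, SP, HPBL) to daily PM2.5. Inputs and label are
#' z-scored before training; predictions are clamped at zero.
#'
#' @slot featureNames predictor names in canonical order.
#' @slot center,scale per-feature z-score constants.
#' @slot labelCenter,labelScale label z-score constants.
#' @slot W1 input-to-hidden weight matrix (9 x hidden).
#' @slot b1 hidden biases.
#' @slot W2 hidden-to-output weight matrix (hidden x 1).
#' @slot b2 output bias (length 1).
#' @slot activation hidden activation name (`"tanh"`).
#' @slot trainingLog list: epochs run, final loss, seed, method.
#' @seealso [trainRetrieval()], [predict,RetrievalModel-method]
#' @exportClass RetrievalModel
setClass("RetrievalModel",
  representation(
    featureNames = "character",
    center = "numeric",
    scale = "numeric",
    labelCenter = "numeric",
    labelScale = "numeric",
    W1 = "matrix",
    b1 = "numeric",
    W2 = "matrix",
    b2 = "numeric",
    activation = "character",
    trainingLog = "list"
  )
)

setValidity("RetrievalModel", function(object) {
  h <- ncol(object@W1)
  msg <- character()
  if (nrow(object@W1) != length(object@featureNames))
    msg <- c(msg, "W1 rows must match the number of features")
  if (!identical(dim(object@W2), c(h, 1L)))
    msg <- c(msg, "W2 must be hidden x 1")
  if (length(object@b1) != h) msg <- c(msg, "b1 length must match hidden size")
  if (length(object@b2) != 1L) msg <- c(msg, "b2 must have length 1")
  if (length(msg)) msg else TRUE
})

#' FitMetrics: correlation and error of a retrieval fit
#'
#' @slot r Pearson correlation between observed and predicted PM2.5.
#' @slot rmse root-mean-square error, ug/m3.
#' @slot n number of samples.
#' @seealso [pearsonR()], [rmse()], [crossValidate()]
#' @exportClass FitMetrics
setClass("FitMetrics",
  representation(r = "numeric", rmse = "numeric", n = "integer")
)

setValidity("FitMetrics", function(object) {
  msg <- character()
  if (object@rmse < 0) msg <- c(msg, "rmse must be >= 0")
  if (object@n < 2L) msg <- c(msg, "n must be >= 2")
  if (abs(object@r) > 1 + 1e-12) msg <- c(msg, "r must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' ResponseLabel: a city's response category for one celebration
#'
#' Category follows the three-rule scheme: `significant` if the city's
#' celebration-period maximum falls within 00:00-04:00 of New Year's Day;
#' `obvious` if, failing that, both the 00:00-04:00 increase and increase
#' rate on New Year's Day strictly exceed those of every other considered
#' day; otherwise `weak`. Lantern Festival days are excluded throughout.
#'
#' @slot city city/station identifier.
#' @slot cycleTag lunar-year identifier.
#' @slot category one of `"significant"`, `"obvious"`, `"weak"`.
#' @slot evidence data.frame of per-day window statistics (value at 00:00,
#'   value at 04:00, increase, increase rate, daily window maximum).
#' @seealso [classifyResponse()]
#' @exportClass ResponseLabel
setClass("ResponseLabel",
  representation(
    city = "character",
    cycleTag = "character",
    category = "character",
    evidence = "data.frame"
  )
)

setValidity("ResponseLabel", function(object) {
  if (!object@category %in% c("significant", "obvious", "weak"))
    return("category must be significant, obvious, or weak")
  TRUE
})
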