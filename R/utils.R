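## Internal helpers shared across modules.

## Evaluate expr under a private RNG stream, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a sub-seed for an independent stream, kept below 2^31.
subSeed <- function(seed, offset) {
  (as.numeric(seed) * 1009 + offset) %% 2147483647
}

## Hourly POSIXct axis covering [startDate, endDate] (one national clock,
## represented as UTC; no DST).
hourlyAxis <- function(startDate, endDate) {
  seq(as.POSIXct(paste(startDate, "00:00:00"), tz = "UTC"),
      as.POSIXct(paste(endDate, "23:00:00"), tz = "UTC"),
      by = "hour")
}

tsDate <- function(ts) as.Date(ts, tz = "UTC")
tsHour <- function(ts) as.integer(format(ts, "%H", tz = "UTC"))

dayOfYear <- function(d) as.integer(format(as.Date(d), "%j"))

## Pixel-center coordinates for a bounding box at a given resolution.
gridCenters <- function(range, resolution) {
  n <- max(1L, round(diff(range) / resolution))
  range[1] + resolution * (seq_len(n) - 0.5)
}

## ISO-8601 timestamp formatting (no timezone suffix by design: the study
## uses a single national clock).
formatISO <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
parseISO <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
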