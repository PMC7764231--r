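## Instantaneous-effect statistics: the national hourly mean, its daily
## maxima and their hour-of-day, peak-to-baseline ratios around New Year's
## Day, and the three-rule per-city response classification.

#' National hourly mean PM2.5
#'
#' Unweighted mean over all stations reporting in each hour; hours with no
#' reporting station are missing.
#'
#' @param series a [StationSeries-class].
#' @return data.frame with `timestamp` and `mean` (ug/m3).
#' @export
nationalHourlyMean <- function(series) {
  stopifnot(is(series, "StationSeries"))
  v <- pm25(series)
  if (nrow(v) == 0L || ncol(v) == 0L) stop("empty series")
  m <- colMeans(v, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  data.frame(timestamp = timestamps(series), mean = m)
}

#' Daily maxima of an hourly national series
#'
#' For each calendar day, the maximum hourly value and the hour at which
#' it occurred (ties broken toward the earliest hour). Days with no data
#' are kept as flagged missing records.
#'
#' @param national data.frame with `timestamp` and `mean`, as returned by
#'   [nationalHourlyMean()].
#' @return data.frame with `date`, `max_value` (ug/m3), `max_hour` (0-23);
#'   `max_value` is `NA` for fully missing days.
#' @export
dailyMaxSeries <- function(national) {
  stopifnot(all(c("timestamp", "mean") %in% colnames(national)))
  d <- tsDate(national$timestamp)
  h <- tsHour(national$timestamp)
  idx <- split(seq_along(d), d)
  res <- lapply(idx, function(i) {
    vals <- national$mean[i]
    if (all(is.na(vals)))
      return(data.frame(date = d[i[1L]], max_value = NA_real_,
                        max_hour = NA_integer_))
    j <- which(vals == max(vals, na.rm = TRUE))[1L]   # earliest tie wins
    data.frame(date = d[i[1L]], max_value = vals[j], max_hour = h[i][j])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Peak-to-baseline ratio of a New Year's Day maximum
#'
#' The event day's daily maximum expressed as a percentage of the mean
#' daily maximum of the flanking days (default: one day on each side).
#'
#' @param dailyMax data.frame from [dailyMaxSeries()].
#' @param eventDate the day of interest (New Year's Day).
#' @param window number of flanking days on each side (default 1).
#' @return percentage (e.g. 209 means the event peak was 209% of the
#'   flanking level).
#' @export
peakRatio <- function(dailyMax, eventDate, window = 1L) {
  eventDate <- as.Date(eventDate)
  lookup <- function(day) {
    v <- dailyMax$max_value[dailyMax$date == day]
    if (length(v) != 1L || is.na(v))
      stop("daily maximum missing for ", format(day))
    v
  }
  ev <- lookup(eventDate)
  flankDays <- c(eventDate - seq_len(window), eventDate + seq_len(window))
  flank <- mean(vapply(flankDays, lookup, numeric(1)))
  100 * ev / flank
}

## Days considered for classification: the celebration window minus the
## Lantern Festival period (lunar days 14-16, i.e. the window's final
## three days).
.consideredDays <- function(division) {
  p <- periodTable(division)
  cel <- p[p$label == "celebration", ]
  days <- seq(cel$start, cel$end, by = "day")
  head(days, -3L)
}

#' Classify a city's PM2.5 response to New Year fireworks
#'
#' Three-rule scheme over one celebration period (Lantern Festival days
#' excluded): (1) *significant* if the city's maximum concentration falls
#' within 00:00-04:00 of New Year's Day (strictly: the window maximum must
#' exceed every value outside the window, so a flat series never
#' qualifies); (2) *obvious* if, failing that,
#' both the increase (value at 04:00 minus value at 00:00) and the
#' increase rate (increase divided by the value at 00:00) of New Year's
#' Day strictly exceed those of every other considered day; (3) *weak*
#' otherwise. Ties fail rule 2. Missing 00:00/04:00 values trigger a
#' completeness warning and the affected day is dropped from rule-2
#' comparisons.
#'
#' @param values hourly PM2.5 vector for one city (ug/m3, `NA` allowed).
#' @param times POSIXct timestamps matching `values`.
#' @param division the [PeriodDivision-class] whose celebration period is
#'   classified.
#' @param city city identifier for the label.
#' @return a [ResponseLabel-class].
#' @export
classifyResponse <- function(values, times, division, city = "city") {
  stopifnot(length(values) == length(times), is(division, "PeriodDivision"))
  p <- periodTable(division)
  cel <- p[p$label == "celebration", ]
  newYearDay <- cel$start + 1L
  days <- .consideredDays(division)

  d <- tsDate(times)
  h <- tsHour(times)
  keep <- d %in% days
  if (!any(keep)) stop("series does not cover the celebration period")
  dv <- values[keep]; dd <- d[keep]; dh <- h[keep]

  ## Per-day 00:00-04:00 window statistics.
  ev <- do.call(rbind, lapply(days, function(day) {
    i <- dd == day
    at <- function(hour) {
      x <- dv[i & dh == hour]
      if (length(x) == 1L) x else NA_real_
    }
    v00 <- at(0L); v04 <- at(4L)
    winVals <- dv[i & dh %in% 0:4]
    data.frame(date = day, v00 = v00, v04 = v04,
               increase = v04 - v00,
               rate = if (!is.na(v00) && v00 != 0) (v04 - v00) / v00
                      else NA_real_,
               window_max = if (length(winVals) && any(!is.na(winVals)))
                 max(winVals, na.rm = TRUE) else NA_real_)
  }))
  rownames(ev) <- NULL

  nyRow <- ev[ev$date == newYearDay, ]
  if (is.na(nyRow$v00) || is.na(nyRow$v04))
    warning("incomplete 00:00/04:00 data on New Year's Day for ", city,
            "; classifying on available hours")

  ## Rule 1: the period maximum falls in the discharge window. The window
  ## maximum must strictly exceed every value outside the window, so that
  ## a flat series (tied everywhere) does not qualify.
  winMask <- dd == newYearDay & dh %in% 0:4
  winMax <- if (any(winMask & !is.na(dv)))
    max(dv[winMask], na.rm = TRUE) else NA_real_
  outMax <- if (any(!winMask & !is.na(dv)))
    max(dv[!winMask], na.rm = TRUE) else NA_real_
  category <- "weak"
  if (any(!is.na(dv))) {
    if (!is.na(winMax) && (is.na(outMax) || winMax > outMax)) {
      category <- "significant"
    } else if (!is.na(nyRow$increase) && !is.na(nyRow$rate)) {
      others <- ev[ev$date != newYearDay, ]
      others <- others[!is.na(others$increase) & !is.na(others$rate), ]
      if (nrow(others) &&
          all(nyRow$increase > others$increase) &&
          all(nyRow$rate > others$rate))
        category <- "obvious"
    }
  }
  new("ResponseLabel", city = city, cycleTag = cycleTag(division),
      category = category, evidence = ev)
}

#' Classify every station of a network for one celebration
#'
#' @param series a [StationSeries-class] (stations stand in for cities).
#' @param division a [PeriodDivision-class].
#' @return data.frame with `city`, `cycle`, `category`.
#' @export
classifyAllStations <- function(series, division) {
  v <- pm25(series)
  ts <- timestamps(series)
  info <- stationInfo(series)
  labs <- lapply(seq_len(nrow(v)), function(i)
    classifyResponse(v[i, ], ts, division, city = info$station_id[i]))
  data.frame(
    city = vapply(labs, function(l) l@city, character(1)),
    cycle = vapply(labs, function(l) l@cycleTag, character(1)),
    category = vapply(labs, responseCategory, character(1)),
    stringsAsFactors = FALSE
  )
}
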