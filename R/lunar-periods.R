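## The 17-day time-division schema: celebration windows anchored on Lunar
## New Year's Day, and the division of each lunar cycle into 21 labeled
## periods (pre-10 ... pre-1, celebration, post-1 ... post-10).

#' Lunar New Year anchor dates, 2002-2016
#'
#' Gregorian dates of Chinese Lunar New Year's Day. These are fixed
#' calendar facts supplied as a configuration table rather than computed
#' astronomically.
#'
#' @param years optional subset of calendar years.
#' @return data.frame with `year` and `new_year_day` (`Date`).
#' @examples
#' lunarNewYearDates(2013:2016)
#' @export
lunarNewYearDates <- function(years = NULL) {
  tab <- data.frame(
    year = 2002:2016,
    new_year_day = as.Date(c(
      "2002-02-12", "2003-02-01", "2004-01-22", "2005-02-09",
      "2006-01-29", "2007-02-18", "2008-02-07", "2009-01-26",
      "2010-02-14", "2011-02-03", "2012-01-23", "2013-02-10",
      "2014-01-31", "2015-02-19", "2016-02-08"
    ))
  )
  if (!is.null(years)) tab <- tab[tab$year %in% years, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Build the 17-day celebration window for a New Year's Day
#'
#' The window runs from Lunar New Year's Eve (the day before New Year's
#' Day) through the day after the Lantern Festival (lunar day 16), a fixed
#' 17-day span; the Eve is included because the night-time displays that
#' produce the 02:00 concentration peak begin on the Eve.
#'
#' @param newYearDay Lunar New Year's Day (`Date` or parseable string).
#' @return a [CelebrationWindow-class].
#' @examples
#' celebrationWindow("2013-02-10")   # 2013-02-09 .. 2013-02-25
#' @export
celebrationWindow <- function(newYearDay) {
  d <- as.Date(newYearDay)
  new("CelebrationWindow", yearTag = format(d, "%Y"),
      start = d - 1L, end = d + 15L)
}

.periodLabels <- c("celebration", paste0("post-", 1:10), "pre-10",
                   paste0("pre-", 9:1))

#' Divide one lunar cycle into 21 labeled periods
#'
#' The cycle runs from the start of one celebration window to the day
#' before the next. It is tiled, in order, by: the 17-day celebration
#' period; ten consecutive 17-day post-celebration periods; the residual
#' pre-10 period (whatever days remain, possibly zero); and nine
#' consecutive 17-day pre-celebration periods counted back from the next
#' celebration window, ending the day before it starts.
#'
#' @param thisWindow,nextWindow consecutive [CelebrationWindow-class]
#'   objects (`nextWindow` must start after `thisWindow` ends).
#' @return a [PeriodDivision-class] tagged with `thisWindow`'s lunar year.
#' @examples
#' divideCycle(celebrationWindow("2013-02-10"),
#'             celebrationWindow("2014-01-31"))
#' @export
divideCycle <- function(thisWindow, nextWindow) {
  stopifnot(is(thisWindow, "CelebrationWindow"),
            is(nextWindow, "CelebrationWindow"))
  if (windowStart(nextWindow) <= windowEnd(thisWindow))
    stop("next celebration window must start after this one ends")
  cycleStart <- windowStart(thisWindow)
  cycleEnd <- windowStart(nextWindow) - 1L
  nDays <- as.integer(cycleEnd - cycleStart) + 1L
  residual <- nDays - 20L * 17L
  if (residual < 0L)
    stop("cycle too short: ", nDays, " days cannot fit 20 17-day periods ",
         "(deficit ", -residual, " days)")

  starts <- c(
    cycleStart,                                   # celebration
    windowEnd(thisWindow) + 1L + 17L * (0:9),     # post-1 .. post-10
    windowEnd(thisWindow) + 1L + 17L * 10L,       # pre-10 (residual)
    windowStart(nextWindow) - 17L * (9:1)         # pre-9 .. pre-1
  )
  ends <- c(
    windowEnd(thisWindow),
    windowEnd(thisWindow) + 17L * (1:10),
    windowEnd(thisWindow) + 17L * 10L + residual,
    windowStart(nextWindow) - 17L * (9:1) + 16L
  )
  periods <- data.frame(label = .periodLabels, start = starts, end = ends,
                        stringsAsFactors = FALSE)
  new("PeriodDivision", cycleTag = yearTag(thisWindow), periods = periods)
}

#' Look up the period label of a date within a cycle
#'
#' @param date a `Date` (or parseable string) inside the cycle.
#' @param division a [PeriodDivision-class].
#' @return the period label (e.g. `"celebration"`, `"post-1"`).
#' @export
assignPeriod <- function(date, division) {
  stopifnot(is(division, "PeriodDivision"))
  d <- as.Date(date)
  p <- periodTable(division)
  hit <- which(d >= p$start & d <= p$end)
  if (length(hit) != 1L)
    stop("date ", format(d), " is outside cycle ", cycleTag(division))
  p$label[hit]
}

#' Divide a sequence of anchors into consecutive cycle divisions
#'
#' @param anchors vector of New Year's Days (`Date`), ascending; at least
#'   two are needed to delimit one cycle.
#' @return list of [PeriodDivision-class], one per consecutive anchor pair.
#' @export
divideAllCycles <- function(anchors) {
  anchors <- sort(as.Date(anchors))
  if (length(anchors) < 2L)
    stop("need at least two anchor dates to delimit a cycle")
  wins <- lapply(anchors, celebrationWindow)
  lapply(seq_len(length(anchors) - 1L), function(i)
    divideCycle(wins[[i]], wins[[i + 1L]]))
}
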