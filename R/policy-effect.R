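## Prohibition-policy analysis: hourly anomalies of the celebration period
## against a 34-day flanking baseline (the adjacent 17-day pre- and
## post-celebration periods), and year-over-year comparison of the
## discharge-window anomaly before and after a policy takes effect.

## Date ranges of the pre-1/post-1 periods flanking the celebration of
## `division`; the adjacent pre-1 lives in the preceding cycle's division,
## so both divisions are required.
flankingPeriods <- function(prevDivision, division) {
  pPrev <- periodTable(prevDivision)
  p <- periodTable(division)
  list(pre1 = pPrev[pPrev$label == "pre-1", c("start", "end")],
       post1 = p[p$label == "post-1", c("start", "end")])
}

#' 34-day flanking baseline concentration
#'
#' Mean of all hourly values within the adjacent pre-celebration period
#' (17 days) and post-celebration period (17 days), representing the
#' normal concentration level around one celebration.
#'
#' @param values hourly PM2.5 vector for one city (ug/m3).
#' @param times POSIXct timestamps matching `values`.
#' @param prevDivision the [PeriodDivision-class] of the preceding cycle
#'   (supplies the adjacent pre-1 period).
#' @param division the [PeriodDivision-class] anchored at the celebration
#'   being analysed (supplies post-1).
#' @return baseline concentration, ug/m3. Warns below 50% data
#'   completeness; errors with no data at all.
#' @export
baseline34day <- function(values, times, prevDivision, division) {
  fl <- flankingPeriods(prevDivision, division)
  d <- tsDate(times)
  inBase <- (d >= fl$pre1$start & d <= fl$pre1$end) |
            (d >= fl$post1$start & d <= fl$post1$end)
  v <- values[inBase]
  if (length(v) == 0L || all(is.na(v)))
    stop("no data in the 34-day baseline window")
  if (mean(!is.na(v)) < 0.5 || length(v) < 0.5 * 34 * 24)
    warning("less than 50% data completeness in the 34-day baseline")
  mean(v, na.rm = TRUE)
}

#' Hourly anomaly over the celebration period
#'
#' `anomaly(t) = value(t) - baseline`, for every hour of the 17-day
#' celebration window; missing hours stay missing. The baseline is the
#' single scalar from [baseline34day()].
#'
#' @inheritParams baseline34day
#' @return data.frame with `timestamp`, `value`, `anomaly`, `baseline`.
#' @export
celebrationAnomaly <- function(values, times, prevDivision, division) {
  base <- baseline34day(values, times, prevDivision, division)
  p <- periodTable(division)
  cel <- p[p$label == "celebration", ]
  d <- tsDate(times)
  inCel <- d >= cel$start & d <= cel$end
  data.frame(timestamp = times[inCel], value = values[inCel],
             anomaly = values[inCel] - base, baseline = base)
}

#' Compare celebration anomalies across policy years
#'
#' Summarises, per year: the mean anomaly over the concentrated discharge
#' window (00:00-04:00 of New Year's Day) and over the full celebration
#' period; then flags whether the discharge-window anomaly declined after
#' the prohibition policy took effect.
#'
#' @param anomalies named list of data.frames from [celebrationAnomaly()];
#'   names are the celebration years (e.g. `"2013"`).
#' @param newYearDays named `Date` vector (same names) giving each year's
#'   New Year's Day.
#' @param policyStartYear first year the prohibition policy was in force.
#' @return list with `table` (per-year summary), `dischargeDeclined`
#'   (logical: post-policy mean discharge-window anomaly below
#'   pre-policy), and `dischargeChange` / `fullPeriodChange` (post minus
#'   pre mean, ug/m3).
#' @export
comparePolicyYears <- function(anomalies, newYearDays, policyStartYear) {
  stopifnot(length(anomalies) >= 2L,
            all(names(anomalies) %in% names(newYearDays)))
  tab <- do.call(rbind, lapply(names(anomalies), function(yr) {
    a <- anomalies[[yr]]
    nyd <- as.Date(newYearDays[[yr]])
    d <- tsDate(a$timestamp)
    h <- tsHour(a$timestamp)
    win <- d == nyd & h %in% 0:4
    data.frame(
      year = as.integer(yr),
      discharge_anomaly = mean(a$anomaly[win], na.rm = TRUE),
      celebration_anomaly = mean(a$anomaly, na.rm = TRUE),
      post_policy = as.integer(yr) >= policyStartYear,
      stringsAsFactors = FALSE
    )
  }))
  rownames(tab) <- NULL
  if (!any(tab$post_policy) || all(tab$post_policy))
    stop("need at least one year on each side of policyStartYear")
  preD <- mean(tab$discharge_anomaly[!tab$post_policy])
  postD <- mean(tab$discharge_anomaly[tab$post_policy])
  preF <- mean(tab$celebration_anomaly[!tab$post_policy])
  postF <- mean(tab$celebration_anomaly[tab$post_policy])
  list(table = tab,
       dischargeDeclined = postD < preD,
       dischargeChange = postD - preD,
       fullPeriodChange = postF - preF)
}
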