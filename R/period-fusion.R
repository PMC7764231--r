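## Multi-year fusion: daily retrieved PM2.5 grids carrying the same period
## label are averaged across all years into one distribution map per label,
## and station series are summarised into per-period national means.

#' Fuse daily PM2.5 grids by period label across years
#'
#' Every input grid's date is assigned to a cycle period; for each label,
#' the fused map is the per-pixel mean over all non-missing daily values
#' across all contributing years. A fused pixel is missing only when no
#' contributing value exists.
#'
#' @param grids list of daily [GridField-class] objects (variable
#'   `"PM2.5"`).
#' @param divisions list of [PeriodDivision-class] covering the grid dates.
#' @param onUnassigned what to do with grids whose date falls outside all
#'   cycles: `"error"` (default) or `"drop"`.
#' @return named list of fused [GridField-class] objects, one per label
#'   present in the input.
#' @export
fusePeriods <- function(grids, divisions,
                        onUnassigned = c("error", "drop")) {
  onUnassigned <- match.arg(onUnassigned)
  if (length(grids) == 0L) stop("empty input: no grids to fuse")
  if (length(divisions) == 0L) stop("empty input: no period divisions")

  labelOf <- function(d) {
    for (div in divisions) {
      p <- periodTable(div)
      hit <- which(d >= p$start & d <= p$end)
      if (length(hit) == 1L) return(p$label[hit])
    }
    NA_character_
  }
  labels <- vapply(grids, function(g) labelOf(gridDate(g)), character(1))
  if (anyNA(labels)) {
    if (onUnassigned == "error")
      stop("grid date not assignable to any cycle: ",
           format(gridDate(grids[[which(is.na(labels))[1L]]])))
    grids <- grids[!is.na(labels)]
    labels <- labels[!is.na(labels)]
    if (length(grids) == 0L) stop("empty input: all grids unassignable")
  }

  out <- list()
  for (lab in unique(labels)) {
    members <- grids[labels == lab]
    ref <- members[[1L]]
    acc <- matrix(0, nrow(gridValues(ref)), ncol(gridValues(ref)))
    cnt <- acc
    for (g in members) {
      v <- gridValues(g)
      if (!identical(dim(v), dim(acc)))
        stop("grids for label ", lab, " have mismatched shapes")
      ok <- !is.na(v)
      acc[ok] <- acc[ok] + v[ok]
      cnt <- cnt + ok
    }
    fused <- ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
    out[[lab]] <- GridField("PM2.5", gridDate(ref), gridLon(ref),
                            gridLat(ref), fused, units = gridUnits(ref))
  }
  out
}

#' Per-period national mean PM2.5 from station observations
#'
#' For each cycle and each of its 21 periods, the unweighted mean over all
#' stations and all hours falling inside the period. Periods with zero
#' observations get a missing mean and are flagged by `n_hours = 0`.
#'
#' @param series a [StationSeries-class].
#' @param divisions list of [PeriodDivision-class].
#' @return data.frame with `cycle`, `label`, `start`, `end`, `mean`
#'   (ug/m3), `n_values`.
#' @export
periodMeans <- function(series, divisions) {
  stopifnot(is(series, "StationSeries"), length(divisions) > 0L)
  ts <- timestamps(series)
  d <- tsDate(ts)
  v <- pm25(series)
  rows <- lapply(divisions, function(div) {
    p <- periodTable(div)
    do.call(rbind, lapply(seq_len(nrow(p)), function(i) {
      inP <- d >= p$start[i] & d <= p$end[i]
      vals <- v[, inP, drop = FALSE]
      nVal <- sum(!is.na(vals))
      data.frame(cycle = cycleTag(div), label = p$label[i],
                 start = p$start[i], end = p$end[i],
                 mean = if (nVal) mean(vals, na.rm = TRUE) else NA_real_,
                 n_values = nVal, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare each celebration period against its flanking baseline
#'
#' For every celebration whose immediate neighbours are available, the
#' flanking level is the equal-weight mean of the adjacent pre-celebration
#' (pre-1) and post-celebration (post-1) period means; `deficit` is
#' flanking minus celebration, so a positive deficit means the celebration
#' period was cleaner than its surroundings. With `flanking = "all"` the
#' baseline instead averages all available pre-* and post-* period means.
#'
#' @param series a [StationSeries-class].
#' @param divisions list of consecutive [PeriodDivision-class] (the pre-1
#'   period preceding a celebration lives in the previous cycle's
#'   division).
#' @param flanking `"adjacent"` (default, pre-1/post-1) or `"all"`.
#' @return data.frame with `cycle`, `celebration_mean`, `pre_mean`,
#'   `post_mean`, `flanking_mean`, `deficit` (all ug/m3).
#' @export
celebrationComparison <- function(series, divisions,
                                  flanking = c("adjacent", "all")) {
  flanking <- match.arg(flanking)
  pm <- periodMeans(series, divisions)
  tags <- vapply(divisions, cycleTag, character(1))
  rows <- list()
  for (i in seq_along(divisions)) {
    tag <- tags[i]
    celeb <- pm$mean[pm$cycle == tag & pm$label == "celebration"]
    if (flanking == "adjacent") {
      post <- pm$mean[pm$cycle == tag & pm$label == "post-1"]
      ## pre-1 adjacent to this celebration belongs to the previous cycle.
      pre <- if (i > 1L) pm$mean[pm$cycle == tags[i - 1L] &
                                   pm$label == "pre-1"] else NA_real_
    } else {
      post <- mean(pm$mean[pm$cycle == tag &
                             grepl("^post-", pm$label)], na.rm = TRUE)
      pre <- if (i > 1L) mean(pm$mean[pm$cycle == tags[i - 1L] &
                                        grepl("^pre-", pm$label)],
                              na.rm = TRUE) else NA_real_
    }
    if (!length(pre)) pre <- NA_real_
    if (!length(post)) post <- NA_real_
    flank <- mean(c(pre, post))
    rows[[i]] <- data.frame(
      cycle = tag, celebration_mean = celeb, pre_mean = pre,
      post_mean = post, flanking_mean = flank,
      deficit = flank - celeb, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
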