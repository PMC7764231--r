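#' Merge same-day Terra and Aqua AOD grids
#'
#' Per-pixel combination of the two daily overpasses: if both values are
#' missing the merged pixel is missing; if both are present their
#' arithmetic mean is used; if exactly one is present that value is taken.
#'
#' @param terra,aqua [GridField-class] objects with variable `"AOD"`, the
#'   same date, and identical grids.
#' @return a [GridField-class] with variable `"AOD"`.
#' @examples
#' lon <- c(0.05, 0.15); lat <- 0.05
#' t1 <- GridField("AOD", "2013-02-10", lon, lat, matrix(c(0.3, NA), 1))
#' a1 <- GridField("AOD", "2013-02-10", lon, lat, matrix(c(0.5, 0.5), 1))
#' gridValues(mergeDailyAOD(t1, a1))   # 0.4, 0.5
#' @export
mergeDailyAOD <- function(terra, aqua) {
  stopifnot(is(terra, "GridField"), is(aqua, "GridField"))
  if (!identical(gridDate(terra), gridDate(aqua)))
    stop("Terra and Aqua grids are for different dates")
  if (!isTRUE(all.equal(gridLon(terra), gridLon(aqua))) ||
      !isTRUE(all.equal(gridLat(terra), gridLat(aqua))))
    stop("Terra and Aqua grids have mismatched extent or resolution")
  tv <- gridValues(terra)
  av <- gridValues(aqua)
  if (!identical(dim(tv), dim(av)))
    stop("Terra and Aqua grids have mismatched shapes")

  s <- ifelse(is.na(tv), 0, tv) + ifelse(is.na(av), 0, av)
  npresent <- (!is.na(tv)) + (!is.na(av))
  merged <- ifelse(npresent == 0L, NA_real_, s / pmax(npresent, 1L))
  GridField("AOD", gridDate(terra), gridLon(terra), gridLat(terra),
            matrix(merged, nrow = nrow(tv)), units = gridUnits(terra))
}
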