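## File formats: station CSV (long form) and CF-style NetCDF grids.
## Timestamps are written as ISO-8601 without a timezone suffix and
## interpreted on the single national clock; missing PM2.5 values are
## written as empty fields in CSV and as a fill value with mask in NetCDF.

#' Write a StationSeries to CSV
#'
#' Long format with columns `station_id`, `lon`, `lat`, `timestamp`
#' (ISO-8601, no timezone suffix), `pm25` (empty = missing). Writing then
#' reading reproduces the series exactly.
#'
#' @param series a [StationSeries-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeStationCsv <- function(series, path) {
  stopifnot(is(series, "StationSeries"))
  info <- stationInfo(series)
  ts <- timestamps(series)
  v <- pm25(series)
  df <- data.frame(
    station_id = rep(info$station_id, each = length(ts)),
    lon = rep(info$lon, each = length(ts)),
    lat = rep(info$lat, each = length(ts)),
    timestamp = rep(formatISO(ts), times = nrow(info)),
    pm25 = as.vector(t(v)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a StationSeries from CSV
#'
#' Validates the file: malformed rows are reported with their line number,
#' negative concentrations and duplicate (station, timestamp) keys are
#' rejected. Stations are aligned onto the common hourly axis spanning the
#' file's full time range; absent hours become missing values.
#'
#' @param path CSV file written by [writeStationCsv()] (or equivalent).
#' @return a [StationSeries-class].
#' @export
readStationCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("station CSV needs a header and data rows")
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  req <- c("station_id", "lon", "lat", "timestamp", "pm25")
  if (!identical(header, req))
    stop("station CSV header must be: ", paste(req, collapse = ","))
  body <- lines[-1L]
  body <- body[nzchar(body)]
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  ## A trailing empty pm25 field is dropped by strsplit; 4 fields means
  ## a missing value, anything else is malformed.
  bad <- which(nf != 5L & nf != 4L)
  if (length(bad))
    stop("malformed row at line ", bad[1L] + 1L, ": '", body[bad[1L]], "'")
  get <- function(i) vapply(parts, function(p) {
    if (length(p) >= i) p[[i]] else ""
  }, character(1))
  stationId <- get(1L)
  lonS <- as.numeric(get(2L))
  latS <- as.numeric(get(3L))
  tsStr <- get(4L)
  pm25v <- suppressWarnings(as.numeric(get(5L)))
  pm25v[get(5L) == ""] <- NA_real_
  tsv <- parseISO(tsStr)
  badTs <- which(is.na(tsv))
  if (length(badTs))
    stop("malformed row at line ", badTs[1L] + 1L,
         ": unparseable timestamp '", tsStr[badTs[1L]], "'")
  neg <- which(!is.na(pm25v) & pm25v < 0)
  if (length(neg))
    stop("validation error at line ", neg[1L] + 1L,
         ": negative pm25 (", pm25v[neg[1L]], ")")
  key <- paste(stationId, tsStr)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (station, timestamp) key at line ", dup[1L] + 1L,
         ": ", key[dup[1L]])

  stations <- unique(stationId)
  coords <- do.call(rbind, lapply(stations, function(s) {
    i <- which(stationId == s)[1L]
    data.frame(station_id = s, lon = lonS[i], lat = latS[i])
  }))
  axis <- hourlyAxis(min(tsDate(tsv)), max(tsDate(tsv)))
  axis <- axis[axis >= min(tsv) & axis <= max(tsv)]
  m <- matrix(NA_real_, nrow = length(stations), ncol = length(axis),
              dimnames = list(stations, NULL))
  col <- match(as.numeric(tsv), as.numeric(axis))
  if (anyNA(col))
    stop("validation error at line ", which(is.na(col))[1L] + 1L,
         ": timestamp not on the hourly grid")
  m[cbind(match(stationId, stations), col)] <- pm25v
  StationSeries(coords$station_id, coords$lon, coords$lat, axis, m)
}

#' Write a GridField to NetCDF
#'
#' CF-style file with `lon`/`lat` coordinate variables (pixel-center
#' registration), one data variable named after the field, its `units`
#' attribute preserved verbatim, and a `date` global attribute. Missing
#' pixels are stored via the fill value.
#'
#' @param field a [GridField-class].
#' @param path output `.nc` file.
#' @return `path`, invisibly.
#' @export
writeGrid <- function(field, path) {
  stopifnot(is(field, "GridField"))
  dimLon <- ncdf4::ncdim_def("lon", "degrees_east", gridLon(field))
  dimLat <- ncdf4::ncdim_def("lat", "degrees_north", gridLat(field))
  var <- ncdf4::ncvar_def(gridVariable(field), gridUnits(field),
                          list(dimLon, dimLat), missval = -9999,
                          prec = "double")
  nc <- ncdf4::nc_create(path, list(var))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ## GridField stores rows = lat, cols = lon; NetCDF wants (lon, lat).
  ncdf4::ncvar_put(nc, var, t(gridValues(field)))
  ncdf4::ncatt_put(nc, 0, "date", format(gridDate(field)))
  invisible(path)
}

#' Read a GridField from NetCDF
#'
#' @param path `.nc` file written by [writeGrid()] (or any file with
#'   `lon`/`lat` coordinate variables and a single data variable).
#' @return a [GridField-class].
#' @export
readGrid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  dims <- names(nc$dim)
  if (!all(c("lon", "lat") %in% dims))
    stop("format error: missing lon/lat coordinate variables")
  lon <- nc$dim$lon$vals
  lat <- nc$dim$lat$vals
  vars <- names(nc$var)
  if (length(vars) != 1L)
    stop("format error: expected exactly one data variable, found ",
         length(vars))
  v <- ncdf4::ncvar_get(nc, vars[1L], collapse_degen = FALSE)
  if (!identical(dim(v)[1:2], c(length(lon), length(lat))))
    stop("format error: raster shape does not match coordinates")
  units <- ncdf4::ncatt_get(nc, vars[1L], "units")$value
  dateAtt <- ncdf4::ncatt_get(nc, 0, "date")
  if (!isTRUE(dateAtt$hasatt)) stop("format error: missing date attribute")
  GridField(vars[1L], as.Date(dateAtt$value), lon, lat,
            t(matrix(v, nrow = length(lon))), units = units)
}
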