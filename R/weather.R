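#' Weather series
#'
#' A weather series is a data frame of daily records (columns \code{date},
#' \code{tmin}, \code{tmax}, \code{precip}, \code{vap}, \code{wind},
#' \code{sunshine} and optionally \code{radiation} in kJ m-2 d-1) carrying a
#' \code{station} attribute (name, lon, lat).  Construction validates the
#' physical invariants: strictly increasing gap-free dates, tmax >= tmin,
#' non-negative precipitation, sunshine within [0, 24].
#'
#' @param records Data frame of daily records.
#' @param station Named list or one-row data frame with \code{name},
#'   \code{lon}, \code{lat}.
#' @return An object of class \code{weather_series} (a data frame).
#' @export
weather_series <- function(records,
                           station = list(name = "station", lon = 0, lat = 0)) {
  req <- c("date", "tmin", "tmax", "precip", "vap", "wind", "sunshine")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("weather records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  records$date <- as.Date(records$date)
  if (anyNA(records$date))
    stop("unparseable dates in weather records", call. = FALSE)
  if (anyDuplicated(records$date))
    stop("duplicate dates in weather records", call. = FALSE)
  d <- diff(as.integer(records$date))
  if (any(d <= 0))
    stop("weather dates must be strictly increasing", call. = FALSE)
  if (any(d > 1))
    stop("gap in weather dates after ",
         format(records$date[which(d > 1)[1]]), call. = FALSE)
  bad <- which(records$tmax < records$tmin)
  if (length(bad))
    stop("tmax < tmin on row ", bad[1], " (", format(records$date[bad[1]]),
         ")", call. = FALSE)
  if (any(records$precip < 0))
    stop("negative precipitation", call. = FALSE)
  if (any(records$sunshine < 0 | records$sunshine > 24))
    stop("sunshine outside [0, 24] h", call. = FALSE)
  if (!is.null(records$radiation) && any(records$radiation < 0, na.rm = TRUE))
    stop("negative radiation", call. = FALSE)
  station <- as.list(station)
  stopifnot(station$lon >= -180, station$lon <= 180,
            station$lat >= -90, station$lat <= 90)
  structure(as.data.frame(records), station = station,
            class = c("weather_series", "data.frame"))
}

#' Read / write station weather CSV
#'
#' One file per station with a single header row naming the seven weather
#' variables (\code{date,tmin,tmax,precip,vap,wind,sunshine}) and an
#' optional \code{radiation} column; dates ISO-8601.
#'
#' @param path CSV file path.
#' @param station Station metadata passed to [weather_series()].
#' @return A \code{weather_series}.
#' @export
read_weather_csv <- function(path,
                             station = list(name = basename(path),
                                            lon = 0, lat = 0)) {
  if (!file.exists(path)) stop("weather file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  weather_series(df, station = station)
}

#' @rdname read_weather_csv
#' @param ws A \code{weather_series}.
#' @export
write_weather_csv <- function(ws, path) {
  stopifnot(inherits(ws, "weather_series"))
  df <- as.data.frame(ws)
  df$date <- format(df$date)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.weather_series <- function(x, ...) {
  st <- attr(x, "station")
  cat("Weather series: ", st$name, " (", st$lon, ", ", st$lat, "), ",
      nrow(x), " days ", format(min(x$date)), " .. ", format(max(x$date)),
      "\n", sep = "")
  invisible(x)
}

#' Inverse-distance-weighted interpolation between stations
#'
#' Interpolates a value at a target location from source stations with
#' weights proportional to great-circle distance to the power
#' \code{-power}.  An exact positional match returns that source's value.
#'
#' @param target List or one-row data frame with \code{lon}, \code{lat}.
#' @param sources Data frame with columns \code{lon}, \code{lat},
#'   \code{value}.
#' @param power Positive exponent (default 2).
#' @return Interpolated value.
#' @examples
#' src <- data.frame(lon = c(112.4, 112.9), lat = c(26.4, 27.1),
#'                   value = c(10, 20))
#' idw_interpolate(list(lon = 112.65, lat = 26.75), src)
#' @export
idw_interpolate <- function(target, sources, power = 2) {
  if (is.null(sources) || nrow(sources) == 0)
    stop("idw_interpolate needs at least one source", call. = FALSE)
  stopifnot(power > 0)
  d_km <- geosphere::distHaversine(
    cbind(target$lon, target$lat),
    cbind(sources$lon, sources$lat)) / 1000
  hit <- which(d_km == 0)
  if (length(hit)) return(sources$value[hit[1]])
  w <- d_km^(-power)
  sum(w * sources$value) / sum(w)
}

#' Interpolate a full weather series to a target location
#'
#' Applies [idw_interpolate()] variable-by-variable and day-by-day across a
#' list of station series sharing a common date range.  If interpolation of
#' tmin/tmax independently ever produces tmax < tmin the pair is clamped
#' (tmax raised to tmin) and the event reported via a warning.
#'
#' @param target Station list (\code{name}, \code{lon}, \code{lat}).
#' @param series_list List of \code{weather_series} objects.
#' @param power IDW exponent.
#' @return A \code{weather_series} at the target location.
#' @export
idw_weather <- function(target, series_list, power = 2) {
  stopifnot(length(series_list) >= 1)
  dates <- as.Date(Reduce(intersect, lapply(series_list, function(s)
    as.character(s$date))))
  if (!length(dates)) stop("station series share no dates", call. = FALSE)
  dates <- sort(dates)
  st <- lapply(series_list, attr, "station")
  lon <- vapply(st, `[[`, 0, "lon"); lat <- vapply(st, `[[`, 0, "lat")
  d_km <- geosphere::distHaversine(cbind(target$lon, target$lat),
                                   cbind(lon, lat)) / 1000
  w <- if (any(d_km == 0)) {
    as.numeric(seq_along(d_km) == which(d_km == 0)[1])  # collocated wins
  } else d_km^(-power)
  w <- w / sum(w)
  vars <- c("tmin", "tmax", "precip", "vap", "wind", "sunshine")
  out <- data.frame(date = dates)
  for (v in vars) {
    m <- vapply(series_list, function(s)
      s[[v]][match(dates, s$date)], numeric(length(dates)))
    out[[v]] <- as.numeric(m %*% w)
  }
  ncross <- sum(out$tmax < out$tmin)
  if (ncross) {
    warning(ncross, " day(s) with interpolated tmax < tmin; clamped")
    out$tmax <- pmax(out$tmax, out$tmin)
  }
  weather_series(out, station = target)
}

# Ensure a radiation column exists, deriving it from sunshine duration when
# absent (Angstrom-Prescott with the series' station latitude).
ensure_radiation <- function(ws, a = 0.25, b = 0.50) {
  if (!is.null(ws$radiation) && !anyNA(ws$radiation)) return(ws)
  lat <- attr(ws, "station")$lat
  rad <- angstrom_radiation(pmin(ws$sunshine, day_length(ws$date, lat)),
                            ws$date, lat, a = a, b = b)
  if (is.null(ws$radiation)) ws$radiation <- rad
  else ws$radiation[is.na(ws$radiation)] <- rad[is.na(ws$radiation)]
  ws
}
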