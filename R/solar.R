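# Daily solar geometry shared by the Angstrom radiation estimate and the
# canopy assimilation routine.  Standard agro-meteorological closed forms:
# declination from day of year, astronomical day length, and the daily
# integrals of sin(beta) used to distribute irradiance over the day.

solar_geometry <- function(date, lat) {
  doy <- as.integer(strftime(as.Date(date), "%j"))
  rad <- pi / 180
  dec <- -asin(sin(23.45 * rad) * cos(2 * pi * (doy + 10) / 365))
  sinld <- sin(lat * rad) * sin(dec)
  cosld <- cos(lat * rad) * cos(dec)
  aob <- pmin(pmax(sinld / cosld, -1), 1)
  dayl <- 12 * (1 + 2 * asin(aob) / pi)
  # integral of sin(beta) over the day, s
  dsinb <- 3600 * (dayl * sinld + 24 * cosld * sqrt(1 - aob^2) / pi)
  # same with the (1 + 0.4 sin beta) atmospheric-transmission correction
  dsinbe <- 3600 * (dayl * (sinld + 0.4 * (sinld^2 + cosld^2 * 0.5)) +
                      12 * cosld * (2 + 3 * 0.4 * sinld) *
                        sqrt(1 - aob^2) / pi)
  sc <- 1370 * (1 + 0.033 * cos(2 * pi * doy / 365))  # W m-2
  list(dec = dec, sinld = sinld, cosld = cosld, daylength = dayl,
       dsinb = dsinb, dsinbe = dsinbe, solar_const = sc,
       angot_kj = sc * dsinb / 1000)  # extraterrestrial, kJ m-2 d-1
}

#' Astronomical day length
#'
#' @param date Calendar date(s).
#' @param lat Latitude in decimal degrees.
#' @return Day length in hours.
#' @export
day_length <- function(date, lat) solar_geometry(date, lat)$daylength

#' Global radiation from sunshine duration (Angstrom-Prescott)
#'
#' Estimates daily global radiation as
#' \eqn{R = (a + b \, n/N) \, R_a}, where \eqn{n} is bright-sunshine
#' duration, \eqn{N} the astronomical day length and \eqn{R_a} the
#' extraterrestrial radiation from standard solar geometry.
#'
#' @param sunshine Sunshine duration, hours (vectorized).
#' @param date Calendar date(s).
#' @param lat Latitude, decimal degrees.
#' @param a,b Angstrom coefficients (defaults 0.25 and 0.50).
#' @return Global radiation, kJ m-2 d-1.
#' @examples
#' angstrom_radiation(3.3, "2021-03-15", 26.98)
#' @export
angstrom_radiation <- function(sunshine, date, lat, a = 0.25, b = 0.50) {
  geo <- solar_geometry(date, lat)
  if (any(sunshine < 0))
    stop("sunshine duration must be non-negative", call. = FALSE)
  if (any(sunshine > geo$daylength + 1e-6))
    stop("sunshine duration exceeds astronomical day length (",
         format(max(geo$daylength)), " h)", call. = FALSE)
  (a + b * sunshine / geo$daylength) * geo$angot_kj
}
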