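#' Apparent sunset time (NOAA solar position algorithm)
#'
#' Computes the UTC time of apparent sunset (solar zenith 90.833 degrees,
#' including standard atmospheric refraction and the solar disc radius) for a
#' civil date and location, using the NOAA solar calculator equations
#' (low-precision ephemeris, accurate to well under a minute for
#' non-polar latitudes). Fledgling departure timing is expressed relative to
#' this instant.
#'
#' @param date a `Date` (or string coercible to one): the civil date at the
#'   location.
#' @param lon,lat location in degrees WGS84 (east/north positive). Latitudes
#'   poleward of 66 degrees are rejected (no polar day/night handling).
#' @return a list of class `sunset_spec` with `date`, `lon`, `lat` and
#'   `sunset_utc` (POSIXct, UTC).
#' @export
apparent_sunset <- function(date, lon, lat) {
  date <- as.Date(date)
  if (abs(lat) >= 66)
    stop("unsupported latitude ", lat,
         ": polar day/night regimes are not handled")
  if (abs(lon) > 180 || abs(lat) > 90) stop("coordinates out of range")
  jd0 <- as.numeric(date) + 2440587.5   # JD of 00:00 UTC on `date`
  ## Iterate: evaluate the ephemeris at the current sunset estimate.
  minutes <- 720
  for (it in 1:3) {
    eph <- solar_ephemeris(jd0 + minutes / 1440)
    ha <- sunset_hour_angle(lat, eph$decl)
    solar_noon <- 720 - 4 * lon - eph$eqtime
    minutes <- solar_noon + 4 * ha * 180 / pi
  }
  sunset_utc <- as.POSIXct(date, tz = "UTC") + minutes * 60
  structure(list(date = date, lon = lon, lat = lat, sunset_utc = sunset_utc),
            class = "sunset_spec")
}

#' @export
print.sunset_spec <- function(x, ...) {
  cat(sprintf("<sunset_spec %s at (%.4f, %.4f): %s UTC>\n",
              format(x$date), x$lon, x$lat, format(x$sunset_utc)))
  invisible(x)
}

## NOAA solcalc equations; jd is a full Julian date. Returns the equation of
## time (minutes) and solar declination (radians).
solar_ephemeris <- function(jd) {
  d2r <- pi / 180
  jc <- (jd - 2451545) / 36525
  gml <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  gma <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eqctr <- sin(gma * d2r) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * gma * d2r) * (0.019993 - 0.000101 * jc) +
    sin(3 * gma * d2r) * 0.000289
  app_long <- gml + eqctr - 0.00569 -
    0.00478 * sin((125.04 - 1934.136 * jc) * d2r)
  mean_obliq <- 23 + (26 + (21.448 - jc * (46.815 + jc *
    (0.00059 - jc * 0.001813))) / 60) / 60
  obliq <- mean_obliq + 0.00256 * cos((125.04 - 1934.136 * jc) * d2r)
  decl <- asin(sin(obliq * d2r) * sin(app_long * d2r))
  vary <- tan(obliq / 2 * d2r)^2
  eqtime <- 4 / d2r * (vary * sin(2 * gml * d2r) -
    2 * ecc * sin(gma * d2r) +
    4 * ecc * vary * sin(gma * d2r) * cos(2 * gml * d2r) -
    0.5 * vary^2 * sin(4 * gml * d2r) -
    1.25 * ecc^2 * sin(2 * gma * d2r))
  list(eqtime = eqtime, decl = decl)
}

## Hour angle (radians) of apparent sunset for zenith 90.833 degrees.
sunset_hour_angle <- function(lat, decl) {
  d2r <- pi / 180
  arg <- cos(90.833 * d2r) / (cos(lat * d2r) * cos(decl)) -
    tan(lat * d2r) * tan(decl)
  if (arg < -1 || arg > 1)
    stop("sun does not set on this date at latitude ", lat)
  acos(arg)
}
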