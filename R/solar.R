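# Solar geometry after the NOAA solar-calculator equations (Julian-century
# polynomials for the sun's mean elements, equation of centre, apparent
# longitude and obliquity), giving the equation of time and solar declination
# to well under a minute of sunrise/sunset error for recent decades. The
# cheaper fractional-year Fourier fit drifts by 2-3 minutes near the
# equinoxes at this epoch, too coarse for minute-level validation, so the
# full spreadsheet form is used.

DEG2RAD <- pi / 180
SUNRISE_ZENITH_DEG <- 90.833

# Equation of time (minutes) and solar declination (radians) at POSIXct UTC.
.sun_ephemeris <- function(time) {
  jc <- (as.numeric(time) / 86400 + 2440587.5 - 2451545) / 36525
  l0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  m <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  mr <- m * DEG2RAD
  eqcent <- sin(mr) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * mr) * (0.019993 - 0.000101 * jc) +
    sin(3 * mr) * 0.000289
  true_long <- l0 + eqcent
  omega <- (125.04 - 1934.136 * jc) * DEG2RAD
  app_long <- (true_long - 0.00569 - 0.00478 * sin(omega)) * DEG2RAD
  obliq0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 -
    jc * 0.001813))) / 60) / 60
  obliq <- (obliq0 + 0.00256 * cos(omega)) * DEG2RAD
  decl <- asin(sin(obliq) * sin(app_long))
  y <- tan(obliq / 2)^2
  l0r <- l0 * DEG2RAD
  eqtime <- 4 / DEG2RAD * (y * sin(2 * l0r) - 2 * ecc * sin(mr) +
    4 * ecc * y * sin(mr) * cos(2 * l0r) -
    0.5 * y^2 * sin(4 * l0r) - 1.25 * ecc^2 * sin(2 * mr))
  list(eqtime = eqtime, decl = decl)
}

#' Solar zenith angle
#'
#' Zenith angle of the sun (degrees from vertical) at given UTC times and
#' positions, via the NOAA solar-calculator equations.
#'
#' @param time POSIXct, UTC.
#' @param lon,lat degrees (east/north positive); recycled against `time`.
#' @return numeric vector of zenith angles in degrees.
#' @export
solar_zenith <- function(time, lon, lat) {
  if (any(abs(lat) > 90, na.rm = TRUE)) stop("latitude outside [-90, 90]")
  if (any(abs(lon) > 180, na.rm = TRUE)) stop("longitude outside [-180, 180]")
  n <- max(length(time), length(lon), length(lat))
  time <- rep_len(time, n); lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  se <- .sun_ephemeris(time)
  min_utc <- as.numeric(time) %% 86400 / 60
  tst <- min_utc + se$eqtime + 4 * lon          # true solar time, minutes
  ha <- (tst / 4 - 180) * DEG2RAD               # hour angle
  latr <- lat * DEG2RAD
  cosz <- sin(latr) * sin(se$decl) + cos(latr) * cos(se$decl) * cos(ha)
  acos(pmin(1, pmax(-1, cosz))) / DEG2RAD
}

#' Day or night at a time and place
#'
#' A timestamp is "day" when the sun is above the standard sunrise/sunset
#' horizon (zenith < 90.833 degrees, i.e. refraction plus solar radius) --
#' exactly the interval between local sunrise and sunset, without the date
#' bookkeeping, and gracefully all-day / all-night under polar conditions.
#'
#' @inheritParams solar_zenith
#' @return character vector, `"day"` or `"night"`.
#' @export
is_daytime <- function(time, lon, lat) {
  ifelse(solar_zenith(time, lon, lat) < SUNRISE_ZENITH_DEG, "day", "night")
}

#' Local sunrise and sunset (UTC)
#'
#' Sunrise and sunset instants for the civil date at a location, from the
#' NOAA hour-angle equation at zenith 90.833 degrees, refined by re-evaluating
#' the ephemeris at the event time. Returned in UTC. Under polar day the pair
#' is `NA` with `polar = "day"`; under polar night likewise with
#' `polar = "night"`.
#'
#' @param date a `Date` (the local calendar date of interest).
#' @param lon,lat degrees.
#' @return data.frame with columns `sunrise`, `sunset` (POSIXct UTC) and
#'   `polar` (`NA`, `"day"` or `"night"`).
#' @export
sunrise_sunset <- function(date, lon, lat) {
  if (any(abs(lat) > 90)) stop("latitude outside [-90, 90]")
  n <- max(length(date), length(lon), length(lat))
  date <- rep_len(as.Date(date), n)
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  out <- data.frame(sunrise = as.POSIXct(rep(NA_real_, n), tz = "UTC",
                                         origin = "1970-01-01"),
                    sunset = as.POSIXct(rep(NA_real_, n), tz = "UTC",
                                        origin = "1970-01-01"),
                    polar = rep(NA_character_, n))
  for (i in seq_len(n)) {
    # local solar noon (approximate) anchors the civil date at this longitude
    midnight <- as.POSIXct(paste(date[i], "00:00:00"), tz = "UTC")
    polar <- NA_character_
    ev <- c(sunrise = NA_real_, sunset = NA_real_)
    for (which in c("sunrise", "sunset")) {
      t_guess <- midnight + (720 - 4 * lon[i]) * 60
      minutes <- NA_real_
      for (pass in 1:3) {
        se <- .sun_ephemeris(t_guess)
        latr <- lat[i] * DEG2RAD
        cosha <- cos(SUNRISE_ZENITH_DEG * DEG2RAD) /
          (cos(latr) * cos(se$decl)) - tan(latr) * tan(se$decl)
        if (cosha < -1) { polar <- "day"; break }
        if (cosha > 1) { polar <- "night"; break }
        ha_deg <- acos(cosha) / DEG2RAD
        sign <- if (which == "sunrise") +1 else -1
        minutes <- 720 - 4 * (lon[i] + sign * ha_deg) - se$eqtime
        t_guess <- midnight + minutes * 60
      }
      ev[which] <- if (is.na(polar)) minutes else NA_real_
    }
    if (is.na(polar)) {
      out$sunrise[i] <- midnight + ev["sunrise"] * 60
      out$sunset[i] <- midnight + ev["sunset"] * 60
    }
    out$polar[i] <- polar
  }
  out
}
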