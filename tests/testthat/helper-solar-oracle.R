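# Independent solar oracle: Meeus-style sun ephemeris (Julian centuries,
# equation of centre, apparent longitude, obliquity, sidereal time) with
# bisection on solar elevation = -0.833 deg. Deliberately a different
# algorithm from the package's NOAA Fourier-series implementation.

oracle_sun_elevation <- function(time, lon, lat) {
  d2r <- pi / 180
  jd <- as.numeric(time) / 86400 + 2440587.5
  T <- (jd - 2451545) / 36525
  L0 <- (280.46646 + 36000.76983 * T + 0.0003032 * T^2) %% 360
  M <- (357.52911 + 35999.05029 * T - 0.0001537 * T^2) %% 360
  C <- (1.914602 - 0.004817 * T - 0.000014 * T^2) * sin(M * d2r) +
    (0.019993 - 0.000101 * T) * sin(2 * M * d2r) +
    0.000289 * sin(3 * M * d2r)
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * T
  lambda <- true_long - 0.00569 - 0.00478 * sin(omega * d2r)
  eps0 <- 23.43929111 - 0.0130042 * T - 1.64e-7 * T^2
  eps <- eps0 + 0.00256 * cos(omega * d2r)
  decl <- asin(sin(eps * d2r) * sin(lambda * d2r))
  ra <- atan2(cos(eps * d2r) * sin(lambda * d2r), cos(lambda * d2r)) / d2r
  gmst <- (280.46061837 + 360.98564736629 * (jd - 2451545)) %% 360
  ha <- ((gmst + lon - ra + 540) %% 360 - 180) * d2r
  phi <- lat * d2r
  asin(sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)) / d2r
}

# sunrise/sunset (POSIXct UTC) for the given civil date by bisection
oracle_sunrise_sunset <- function(date, lon, lat) {
  target <- -0.833
  noon <- as.POSIXct(paste(date, "12:00:00"), tz = "UTC") - lon / 15 * 3600
  bisect <- function(lo, hi, rising) {
    for (i in 1:45) {
      mid <- lo + (hi - lo) / 2
      e <- oracle_sun_elevation(mid, lon, lat)
      up <- e > target
      if (rising == up) hi <- mid else lo <- mid
    }
    lo + (hi - lo) / 2
  }
  list(sunrise = bisect(noon - 12 * 3600, noon, rising = TRUE),
       sunset = bisect(noon, noon + 12 * 3600, rising = FALSE))
}
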