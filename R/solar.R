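#' Solar altitude (geometric, no refraction)
#'
#' Sun elevation angle above the horizon, from the standard NOAA solar
#' position equations (Julian-century polynomial ephemeris, equation of
#' time, hour angle). Atmospheric refraction is ignored, so "daylight"
#' means geometric sun altitude >= 0. Accuracy is well within a couple of
#' minutes of sunrise/sunset timing for any terrestrial latitude.
#'
#' @param time POSIXct timestamps (UTC).
#' @param lat,lon geographic coordinates in decimal degrees (recycled).
#' @return solar altitude in degrees.
#' @export
solar_altitude <- function(time, lat, lon) {
  d2r <- pi / 180
  jd <- as.numeric(time) / 86400 + 2440587.5
  t <- (jd - 2451545) / 36525
  l0 <- (280.46646 + t * (36000.76983 + 0.0003032 * t)) %% 360
  m <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  ecc <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
  c_eq <- sin(m * d2r) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(2 * m * d2r) * (0.019993 - 0.000101 * t) +
    sin(3 * m * d2r) * 0.000289
  true_long <- l0 + c_eq
  omega <- 125.04 - 1934.136 * t
  lambda <- true_long - 0.00569 - 0.00478 * sin(omega * d2r)
  eps0 <- 23 + (26 + (21.448 - t * (46.815 + t * (0.00059 - t * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(omega * d2r)
  decl <- asin(sin(eps * d2r) * sin(lambda * d2r))
  y <- tan(eps * d2r / 2)^2
  eot <- 4 / d2r * (y * sin(2 * l0 * d2r) - 2 * ecc * sin(m * d2r) +
                      4 * ecc * y * sin(m * d2r) * cos(2 * l0 * d2r) -
                      0.5 * y^2 * sin(4 * l0 * d2r) -
                      1.25 * ecc^2 * sin(2 * m * d2r))   # minutes
  utc_minutes <- (as.numeric(time) %% 86400) / 60
  tst <- (utc_minutes + eot + 4 * lon) %% 1440
  hour_angle <- tst / 4 - 180
  cos_zen <- sin(lat * d2r) * sin(decl) +
    cos(lat * d2r) * cos(decl) * cos(hour_angle * d2r)
  cos_zen <- pmin(pmax(cos_zen, -1), 1)
  90 - acos(cos_zen) / d2r
}
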