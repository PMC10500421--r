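# Solar (sun-anchored) time. Clock timestamps are mapped to radians so that
# sunrise is pi/2 and sunset is 3*pi/2 at every station and date; day and
# night are each stretched linearly between the anchors. This equalizes day
# length across latitudes and seasons so diel activity is comparable.
# Sunrise/sunset come from the NOAA solar position equations (zenith
# 90.833 degrees, i.e. including standard refraction).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Vectorized NOAA sunrise/sunset for civil dates at given coordinates.
# Returns POSIXct (UTC). Dates are interpreted at the station's meridian.
noaa_sun_times <- function(date, latitude, longitude) {
  date <- as.Date(date)
  n <- max(length(date), length(latitude), length(longitude))
  date <- rep_len(date, n)
  latitude <- rep_len(latitude, n)
  longitude <- rep_len(longitude, n)
  if (any(abs(latitude) >= 66.5))
    stop("latitudes poleward of 66.5 degrees are not supported ",
         "(polar day/night)")
  # Julian day at local solar noon
  jd <- as.numeric(date) + 2440587.5 + 0.5 - longitude / 360
  tc <- (jd - 2451545) / 36525
  l0 <- (280.46646 + tc * (36000.76983 + 0.0003032 * tc)) %% 360
  m <- 357.52911 + tc * (35999.05029 - 0.0001537 * tc)
  ecc <- 0.016708634 - tc * (0.000042037 + 0.0000001267 * tc)
  ctr <- sin(deg2rad(m)) * (1.914602 - tc * (0.004817 + 0.000014 * tc)) +
    sin(deg2rad(2 * m)) * (0.019993 - 0.000101 * tc) +
    sin(deg2rad(3 * m)) * 0.000289
  true_long <- l0 + ctr
  omega <- 125.04 - 1934.136 * tc
  lambda_app <- true_long - 0.00569 - 0.00478 * sin(deg2rad(omega))
  eps0 <- 23 + (26 + (21.448 - tc * (46.815 + tc * (0.00059 -
                                                      tc * 0.001813))) / 60) / 60
  eps_corr <- eps0 + 0.00256 * cos(deg2rad(omega))
  decl <- asin(sin(deg2rad(eps_corr)) * sin(deg2rad(lambda_app)))
  var_y <- tan(deg2rad(eps_corr / 2))^2
  eot <- 4 * rad2deg(var_y * sin(2 * deg2rad(l0)) -
                       2 * ecc * sin(deg2rad(m)) +
                       4 * ecc * var_y * sin(deg2rad(m)) * cos(2 * deg2rad(l0)) -
                       0.5 * var_y^2 * sin(4 * deg2rad(l0)) -
                       1.25 * ecc^2 * sin(2 * deg2rad(m)))
  cos_ha <- cos(deg2rad(90.833)) / (cos(deg2rad(latitude)) * cos(decl)) -
    tan(deg2rad(latitude)) * tan(decl)
  bad <- which(cos_ha < -1 | cos_ha > 1)
  if (length(bad) > 0)
    stop("no sunrise/sunset on ", date[bad[1]], " at latitude ",
         format(latitude[bad[1]], digits = 4))
  ha <- rad2deg(acos(cos_ha))
  noon_min <- 720 - 4 * longitude - eot
  day0 <- as.POSIXct(as.numeric(date) * 86400,
                     origin = "1970-01-01", tz = "UTC")
  list(sunrise = day0 + (noon_min - ha * 4) * 60,
       sunset = day0 + (noon_min + ha * 4) * 60)
}

#' Sunrise and sunset for a date and location
#'
#' @param date a `Date` (or coercible), vectorized.
#' @param latitude,longitude degrees; latitude must satisfy
#'   `abs(latitude) < 66.5`.
#' @return list with POSIXct (UTC) `sunrise` and `sunset`.
#' @export
sun_times <- function(date, latitude, longitude) {
  noaa_sun_times(date, latitude, longitude)
}

#' Transform clock timestamps to sun-anchored radians
#'
#' Maps each timestamp to `[0, 2*pi)` with sunrise at `pi/2` and sunset at
#' `3*pi/2` (double anchoring): daytime is stretched linearly between the
#' day's sunrise and sunset, night-time between sunset and the next
#' sunrise. Solar noon maps to `pi` and the middle of the night to 0.
#'
#' @param time POSIXct (UTC or with timezone) or ISO-8601 strings.
#' @param latitude,longitude station coordinates in degrees (recycled).
#' @return numeric radians in `[0, 2*pi)`.
#' @export
solar_transform <- function(time, latitude, longitude) {
  tt <- parse_timestamps(time)
  n <- length(tt)
  latitude <- rep_len(latitude, n)
  longitude <- rep_len(longitude, n)
  if (any(abs(latitude) >= 66.5))
    stop("latitudes poleward of 66.5 degrees are not supported")
  if (any(longitude < -180 | longitude > 180))
    stop("longitude must be in [-180, 180]")
  # civil date at the station's meridian
  d0 <- as.Date(tt + longitude / 15 * 3600)
  st0 <- noaa_sun_times(d0, latitude, longitude)
  stm <- noaa_sun_times(d0 - 1, latitude, longitude)
  stp <- noaa_sun_times(d0 + 1, latitude, longitude)
  out <- numeric(n)
  day <- tt >= st0$sunrise & tt <= st0$sunset
  before <- tt < st0$sunrise
  after <- tt > st0$sunset
  out[day] <- pi / 2 + pi *
    as.numeric(tt[day] - st0$sunrise[day], units = "secs") /
    as.numeric(st0$sunset[day] - st0$sunrise[day], units = "secs")
  out[before] <- 3 * pi / 2 + pi *
    as.numeric(tt[before] - stm$sunset[before], units = "secs") /
    as.numeric(st0$sunrise[before] - stm$sunset[before], units = "secs")
  out[after] <- 3 * pi / 2 + pi *
    as.numeric(tt[after] - st0$sunset[after], units = "secs") /
    as.numeric(stp$sunrise[after] - st0$sunset[after], units = "secs")
  out %% (2 * pi)
}
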