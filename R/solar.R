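#' Solar elevation angle
#'
#' Geometric solar elevation (degrees above the horizon, no refraction
#' correction) at given UTC instants, computed with the standard NOAA solar
#' position equations. Accuracy is well under 0.1 degrees for the current
#' era, ample for day/night classification.
#'
#' @param time POSIXct (UTC) or numeric seconds since the Unix epoch.
#' @param lat,lon site coordinates, decimal degrees (east positive).
#' @return numeric vector of elevations in degrees.
#' @export
solar_elevation <- function(time, lat, lon) {
  t <- as.numeric(time)
  rad <- pi / 180
  jd <- t / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525
  gmls <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eqctr <- sin(rad * gmas) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * rad * gmas) * (0.019993 - 0.000101 * jc) +
    sin(3 * rad * gmas) * 0.000289
  truelong <- gmls + eqctr
  omega <- 125.04 - 1934.136 * jc
  applong <- truelong - 0.00569 - 0.00478 * sin(rad * omega)
  mobliq <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obliq <- mobliq + 0.00256 * cos(rad * omega)
  declin <- asin(sin(rad * obliq) * sin(rad * applong))
  vary <- tan(rad * obliq / 2)^2
  eqtime <- 4 / rad * (vary * sin(2 * rad * gmls) - 2 * ecc * sin(rad * gmas) +
    4 * ecc * vary * sin(rad * gmas) * cos(2 * rad * gmls) -
    0.5 * vary^2 * sin(4 * rad * gmls) - 1.25 * ecc^2 * sin(2 * rad * gmas))
  mins_utc <- (t %% 86400) / 60
  tst <- (mins_utc + eqtime + 4 * lon) %% 1440
  ha <- tst / 4 - 180
  ha[ha < -180] <- ha[ha < -180] + 360
  cosz <- sin(rad * lat) * sin(declin) + cos(rad * lat) * cos(declin) * cos(rad * ha)
  cosz <- pmin(1, pmax(-1, cosz))
  90 - acos(cosz) / rad
}

#' Classify time bins as day or night
#'
#' A bin is daytime iff solar elevation at the bin midpoint is above zero
#' degrees (no twilight band). An override table of sunrise/sunset instants
#' may be supplied instead, in which case the solar algorithm is bypassed and
#' a bin is daytime iff its midpoint falls in any [sunrise, sunset) interval.
#'
#' @param t0 start of the first bin (POSIXct UTC or epoch seconds).
#' @param n_bins number of bins.
#' @param lat,lon site coordinates (decimal degrees). `abs(lat)` must be
#'   below 66.6 (polar day/night unsupported).
#' @param dt bin width in seconds (default 15).
#' @param override optional data.frame with columns `sunrise`, `sunset`
#'   (POSIXct UTC or epoch seconds), one row per solar cycle.
#' @return An object of class `diel_calendar`: list with `t0`, `dt`,
#'   `n_bins`, `period` (character "day"/"night" per bin), `solar_day`
#'   (integer id per bin, advancing at each sunrise so a night is never split
#'   across ids), and `sun` (data.table of sunrise/sunset instants).
#' @export
classify_diel <- function(t0, n_bins, lat, lon, dt = 15, override = NULL) {
  t0 <- as.numeric(t0)
  stopifnot(n_bins >= 1, dt > 0)
  mid <- t0 + dt * (seq_len(n_bins) - 1) + dt / 2
  if (is.null(override)) {
    if (abs(lat) > 66.6) stop("polar day/night unsupported: |lat| > 66.6")
    day <- solar_elevation(mid, lat, lon) > 0
  } else {
    sr <- as.numeric(override$sunrise); ss <- as.numeric(override$sunset)
    stopifnot(length(sr) == length(ss), all(ss > sr))
    day <- rep(FALSE, n_bins)
    for (k in seq_along(sr)) day[mid >= sr[k] & mid < ss[k]] <- TRUE
  }
  # sunrise = night->day transition; solar day id advances at each sunrise
  rises <- which(diff(c(FALSE, day)) == 1L)
  sets  <- which(diff(c(day, FALSE)) == -1L)
  solar_day <- cumsum(seq_len(n_bins) %in% rises)
  sun <- data.table::data.table(
    sunrise = t0 + dt * (rises - 1),
    sunset  = t0 + dt * sets
  )
  structure(list(t0 = t0, dt = dt, n_bins = as.integer(n_bins),
                 period = ifelse(day, "day", "night"),
                 solar_day = as.integer(solar_day), sun = sun),
            class = "diel_calendar")
}

#' Daylight duration on a civil date
#'
#' Length of the period with positive solar elevation on the UTC civil day
#' containing `date`, found by scanning elevations at 30 s resolution.
#'
#' @param date a Date (or coercible).
#' @param lat,lon site coordinates.
#' @return daylight duration in hours.
#' @export
daylight_hours <- function(date, lat, lon) {
  d0 <- as.numeric(as.POSIXct(paste(as.Date(date), "00:00:00"), tz = "UTC"))
  tt <- d0 + seq(0, 86400 - 30, by = 30)
  sum(solar_elevation(tt + 15, lat, lon) > 0) * 30 / 3600
}
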