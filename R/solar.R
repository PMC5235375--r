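# Sun and moon timing. Sunrise/sunset follow the standard NOAA solar position
# equations (zenith 90.833 deg, i.e. including refraction and the solar disc);
# lunar phase uses a Meeus-style synodic approximation anchored at the
# 2000-01-06 18:14 UTC new moon. Both are adequate to the minute/level of a
# phenology analysis; an exact ephemeris table can be supplied instead
# wherever a phase is consumed.

#' Default recording-station coordinates
#'
#' A seasonally flooded cattle pasture in the northern Pantanal (Mato Grosso,
#' Brazil), timezone UTC-4. Used as the default [solar_context()].
#' @export
pantanal_station <- function() {
  list(latitude = -16.50303, longitude = -56.74533, tz_offset = -4)
}

#' Solar context: per-date sunrise and sunset for a station
#'
#' @param latitude,longitude degrees (south/west negative).
#' @param tz_offset hours relative to UTC of the local clock.
#' @return an object of class `solar_context` with a `sun_times(date)` method
#'   accessible via [sun_times()].
#' @export
solar_context <- function(latitude, longitude, tz_offset) {
  structure(list(latitude = latitude, longitude = longitude,
                 tz_offset = tz_offset),
            class = "solar_context")
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# NOAA solar equations; date is a Date, returns list of minutes-past-local-
# midnight for sunrise and sunset.
noaa_sun_minutes <- function(date, lat, lon, tz) {
  jd <- as.numeric(date) + 2440587.5   # Julian day at 00:00 UTC
  t <- (jd + 0.5 - 2451545) / 36525    # Julian century, midday-ish is fine
  l0 <- (280.46646 + t * (36000.76983 + 0.0003032 * t)) %% 360
  m <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  ecc <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
  mr <- deg2rad(m)
  ctr <- sin(mr) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(2 * mr) * (0.019993 - 0.000101 * t) + sin(3 * mr) * 0.000289
  true_long <- l0 + ctr
  omega <- 125.04 - 1934.136 * t
  lambda <- true_long - 0.00569 - 0.00478 * sin(deg2rad(omega))
  eps0 <- 23 + (26 + (21.448 - t * (46.815 + t * (0.00059 - t * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(deg2rad(omega))
  decl <- asin(sin(deg2rad(eps)) * sin(deg2rad(lambda)))
  y <- tan(deg2rad(eps / 2))^2
  l0r <- deg2rad(l0)
  eqtime <- 4 * rad2deg(y * sin(2 * l0r) - 2 * ecc * sin(mr) +
                          4 * ecc * y * sin(mr) * cos(2 * l0r) -
                          0.5 * y^2 * sin(4 * l0r) - 1.25 * ecc^2 * sin(2 * mr))
  latr <- deg2rad(lat)
  cos_ha <- cos(deg2rad(90.833)) / (cos(latr) * cos(decl)) - tan(latr) * tan(decl)
  if (cos_ha > 1 || cos_ha < -1) {
    stop("sun does not rise/set at this latitude/date")
  }
  ha <- rad2deg(acos(cos_ha))
  sunrise_utc <- 720 - 4 * (lon + ha) - eqtime
  sunset_utc <- 720 - 4 * (lon - ha) - eqtime
  list(sunrise = sunrise_utc + tz * 60, sunset = sunset_utc + tz * 60)
}

#' Sunrise and sunset for a date
#'
#' @param solar a [solar_context()].
#' @param date a `Date` (or coercible).
#' @return data.frame with `date`, `sunrise`, `sunset` as POSIXct in a fixed
#'   UTC-offset clock (the station clock).
#' @export
sun_times <- function(solar, date) {
  date <- as.Date(date)
  res <- lapply(date, function(d)
    noaa_sun_minutes(d, solar$latitude, solar$longitude, solar$tz_offset))
  base <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  data.frame(
    date = date,
    sunrise = base + vapply(res, `[[`, numeric(1), "sunrise") * 60,
    sunset = base + vapply(res, `[[`, numeric(1), "sunset") * 60
  )
}

# ---- moon -------------------------------------------------------------------

SYNODIC_MONTH <- 29.530588853
# new moon epoch: 2000-01-06 18:14 UTC, as days since 1970-01-01
NEW_MOON_EPOCH <- as.numeric(as.POSIXct("2000-01-06 18:14:00", tz = "UTC")) / 86400

#' Lunar age of a date
#'
#' Days since the preceding new moon (0 = new, ~14.77 = full), synodic
#' approximation.
#' @param date `Date` vector.
#' @return numeric vector of ages in days, in \[0, 29.53).
#' @export
lunar_age <- function(date) {
  d <- as.numeric(as.Date(date)) + 0.5  # local midnight-ish of the night
  ((d - NEW_MOON_EPOCH) %% SYNODIC_MONTH)
}

#' Is a night moonlit?
#'
#' A night is flagged moonlit when its lunar age lies within `window` days of
#' full moon.
#' @param date `Date` vector (the night of date -> date+1).
#' @param window half-width in days around full moon, default 4.
#' @return logical vector.
#' @export
is_moonlit <- function(date, window = 4) {
  abs(lunar_age(date) - SYNODIC_MONTH / 2) <= window
}
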