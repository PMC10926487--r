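#' @title Solar twilight geometry
#' @description Sunrise, sunset and twilight events from a low-precision
#'   solar ephemeris, plus evening counting windows and twilight-scaled
#'   time axes.
#' @name solar
NULL

.deg2rad <- function(d) d * pi / 180
.rad2deg <- function(r) r * 180 / pi

# Sun declination (deg) and equation of time (minutes) at a UTC instant,
# from the compact Meeus low-accuracy series. Good to well under a minute
# of event time at mid latitudes.
.sun_position <- function(jd) {
  T <- (jd - 2451545) / 36525
  L0 <- (280.46646 + 36000.76983 * T + 0.0003032 * T^2) %% 360
  M <- .deg2rad((357.52911 + 35999.05029 * T - 0.0001537 * T^2) %% 360)
  e <- 0.016708634 - 0.000042037 * T
  C <- (1.914602 - 0.004817 * T - 0.000014 * T^2) * sin(M) +
    (0.019993 - 0.000101 * T) * sin(2 * M) + 0.000289 * sin(3 * M)
  true_long <- L0 + C
  omega <- .deg2rad(125.04 - 1934.136 * T)
  app_long <- .deg2rad(true_long - 0.00569 - 0.00478 * sin(omega))
  eps0 <- 23 + 26 / 60 + 21.448 / 3600 -
    (46.815 * T + 0.00059 * T^2 - 0.001813 * T^3) / 3600
  eps <- .deg2rad(eps0 + 0.00256 * cos(omega))
  decl <- asin(sin(eps) * sin(app_long))
  y <- tan(eps / 2)^2
  L0r <- .deg2rad(L0)
  eqt <- y * sin(2 * L0r) - 2 * e * sin(M) + 4 * e * y * sin(M) * cos(2 * L0r) -
    0.5 * y^2 * sin(4 * L0r) - 1.25 * e^2 * sin(2 * M)
  list(declination = decl, eqtime_min = 4 * .rad2deg(eqt))
}

.julian_day <- function(date, minutes_utc = 720) {
  # days since epoch; Date is days since 1970-01-01; JD of 1970-01-01 00:00
  # UTC is 2440587.5
  2440587.5 + as.numeric(date) + minutes_utc / 1440
}

# Minutes UTC of the event where the sun centre reaches zenith angle
# `zenith` (deg), rising (morning) or setting (evening). NA if it never
# does on that date.
.solar_event_utc <- function(lat, lon, date, zenith, evening) {
  t <- 720 - 4 * lon  # first guess: local solar noon
  for (i in 1:3) {
    sp <- .sun_position(.julian_day(date, t))
    cos_ha <- (cos(.deg2rad(zenith)) -
                 sin(.deg2rad(lat)) * sin(sp$declination)) /
      (cos(.deg2rad(lat)) * cos(sp$declination))
    if (is.na(cos_ha) || abs(cos_ha) > 1) return(NA_real_)
    ha <- .rad2deg(acos(cos_ha))
    if (!evening) ha <- -ha
    t <- 720 - 4 * (lon - ha) - sp$eqtime_min
  }
  t
}

.solar_noon_utc <- function(lon, date) {
  t <- 720 - 4 * lon
  for (i in 1:2) {
    sp <- .sun_position(.julian_day(date, t))
    t <- 720 - 4 * lon - sp$eqtime_min
  }
  t
}

.event_posix <- function(date, minutes_utc) {
  if (is.na(minutes_utc)) return(as.POSIXct(NA, tz = "UTC"))
  as.POSIXct(as.POSIXlt(date, tz = "UTC"), tz = "UTC") + minutes_utc * 60
}

#' Solar and twilight events for one site-date
#'
#' Computes sunrise, sunset, and civil (-6°), nautical (-12°) and
#' astronomical (-18°) dawn/dusk for a latitude/longitude and calendar
#' date, using a low-precision solar ephemeris (declination and equation
#' of time series; standard refraction of 0.833° at the horizon). Event
#' times are accurate to about a minute at mid latitudes.
#'
#' Times are returned as POSIXct in UTC; `utc_offset` is carried so
#' local clock times can be formatted with [local_time()]. The evening
#' (morning) twilight duration is the span from sunset to astronomical
#' dusk (astronomical dawn to sunrise), in seconds.
#'
#' @param lat,lon Site latitude and longitude in decimal degrees
#'   (positive north/east). `abs(lat)` must be below 66 degrees.
#' @param date Calendar `Date` (the local date; the matching events are
#'   those closest to that date's local noon).
#' @param utc_offset Fixed UTC offset of local clock time, in hours
#'   (e.g. 11 for AEDT).
#' @param site_id Optional site label carried through.
#' @return An object of class `solar_day`: a list with `site_id`, `date`,
#'   POSIXct event times `sunrise`, `sunset`, `dawn_civil`,
#'   `dawn_nautical`, `dawn_astro`, `dusk_civil`, `dusk_nautical`,
#'   `dusk_astro`, durations `morning_twilight_duration` and
#'   `evening_twilight_duration` (seconds), and `utc_offset`.
#' @examples
#' sd <- solar_events(-36.456, 148.263, as.Date("2021-02-18"), utc_offset = 11)
#' local_time(sd$dusk_nautical, sd$utc_offset)
#' @export
solar_events <- function(lat, lon, date, utc_offset = 0, site_id = NA_character_) {
  stopifnot(is.finite(lat), is.finite(lon), abs(lat) < 66)
  date <- as.Date(date)
  base <- date
  # anchor on the solar noon whose local clock time falls on the
  # requested date: morning events are the ones in the 12 h before it,
  # evening events (sunset and the dusks that follow it, possibly past
  # local midnight) in the 12 h after it
  noon_abs <- NA_real_
  for (k in -1:1) {
    sn <- as.numeric(.event_posix(base + k, .solar_noon_utc(lon, base + k)))
    if (as.Date(floor((sn + utc_offset * 3600) / 86400),
                origin = "1970-01-01") == base) {
      noon_abs <- sn
      break
    }
  }
  if (is.na(noon_abs)) stop("could not locate solar noon for ", format(base))
  mk <- function(zenith, evening) {
    for (k in -1:1) {
      d <- base + k
      m <- .solar_event_utc(lat, lon, d, zenith, evening)
      if (is.na(m)) next
      ev_abs <- as.numeric(.event_posix(d, m))
      ok <- if (evening) ev_abs > noon_abs && ev_abs <= noon_abs + 43200
      else ev_abs <= noon_abs && ev_abs > noon_abs - 43200
      if (ok) return(.event_posix(d, m))
    }
    as.POSIXct(NA, tz = "UTC")
  }
  out <- list(
    site_id = site_id,
    date = date,
    sunrise = mk(90.833, FALSE),
    sunset = mk(90.833, TRUE),
    dawn_civil = mk(96, FALSE),
    dawn_nautical = mk(102, FALSE),
    dawn_astro = mk(108, FALSE),
    dusk_civil = mk(96, TRUE),
    dusk_nautical = mk(102, TRUE),
    dusk_astro = mk(108, TRUE),
    utc_offset = utc_offset
  )
  out$morning_twilight_duration <-
    as.numeric(difftime(out$sunrise, out$dawn_astro, units = "secs"))
  out$evening_twilight_duration <-
    as.numeric(difftime(out$dusk_astro, out$sunset, units = "secs"))
  structure(out, class = "solar_day")
}

#' @export
print.solar_day <- function(x, ...) {
  cat(sprintf("<solar_day> %s %s (UTC%+03d)\n",
              ifelse(is.na(x$site_id), "", x$site_id),
              format(x$date), as.integer(x$utc_offset)))
  for (ev in c("sunrise", "sunset", "dusk_civil", "dusk_nautical", "dusk_astro"))
    cat(sprintf("  %-14s %s\n", ev, local_time(x[[ev]], x$utc_offset)))
  invisible(x)
}

#' Format a UTC instant as local clock time under a fixed UTC offset
#'
#' @param t POSIXct (UTC).
#' @param utc_offset Offset in hours.
#' @param fmt `strftime` format.
#' @return Character local clock time.
#' @export
local_time <- function(t, utc_offset, fmt = "%Y-%m-%d %H:%M:%S") {
  format(t + utc_offset * 3600, fmt, tz = "UTC")
}

#' Evening counting window for one solar day
#'
#' The half-open interval from sunset to the requested dusk, used to
#' count detections and capture-log images for one evening.
#'
#' @param day A `solar_day` from [solar_events()].
#' @param definition Which dusk closes the window; counting defaults to
#'   astronomical dusk (the activity peak is over by then and almost all
#'   detections precede it).
#' @return List with `site_id`, `evening_date`, `start`, `end` (POSIXct
#'   UTC); the interval is `[start, end)`.
#' @export
evening_window <- function(day,
                           definition = c("sunset_to_astro",
                                          "sunset_to_nautical",
                                          "sunset_to_civil")) {
  definition <- match.arg(definition)
  stopifnot(inherits(day, "solar_day"))
  dusk <- switch(definition,
                 sunset_to_civil = day$dusk_civil,
                 sunset_to_nautical = day$dusk_nautical,
                 sunset_to_astro = day$dusk_astro)
  if (is.na(day$sunset) || is.na(dusk))
    stop("requested dusk does not occur on ", format(day$date))
  list(site_id = day$site_id, evening_date = day$date,
       start = day$sunset, end = dusk)
}

#' Express a time on a twilight-scaled axis
#'
#' Time relative to sunset (or sunrise), divided by the duration of
#' evening (morning) twilight, so that the anchor maps to 0 and the
#' astronomical dusk (dawn-side analogue) maps to 1.
#'
#' @param t POSIXct instant (UTC).
#' @param day A `solar_day`.
#' @param anchor `"sunset"` (evening axis, positive after sunset) or
#'   `"sunrise"` (morning axis, positive after sunrise).
#' @return Unitless signed scaled offset.
#' @export
twilight_scaled_time <- function(t, day, anchor = c("sunset", "sunrise")) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(day, "solar_day"))
  if (anchor == "sunset") {
    as.numeric(difftime(t, day$sunset, units = "secs")) /
      day$evening_twilight_duration
  } else {
    as.numeric(difftime(t, day$sunrise, units = "secs")) /
      day$morning_twilight_duration
  }
}

#' Twilight table for sites and dates
#'
#' Convenience wrapper running [solar_events()] over a site metadata
#' table and a span of dates; the backbone for evening windows and the
#' twilight-duration covariate.
#'
#' @param sites Data frame with `site_id`, `lat`, `lon`,
#'   `utc_offset_hours`.
#' @param dates Vector of `Date`s.
#' @param definition Window definition passed to [evening_window()].
#' @return Data frame: site_id, date, sunset, dusk_civil, dusk_nautical,
#'   dusk_astro, window_start, window_end, evening_twilight_duration.
#' @export
solar_table <- function(sites, dates,
                        definition = "sunset_to_astro") {
  dates <- as.Date(dates)
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    for (d in as.list(dates)) {
      sd <- solar_events(sites$lat[i], sites$lon[i], d,
                         utc_offset = sites$utc_offset_hours[i],
                         site_id = sites$site_id[i])
      w <- evening_window(sd, definition)
      rows[[length(rows) + 1]] <- data.frame(
        site_id = sd$site_id, date = sd$date,
        sunrise = sd$sunrise, sunset = sd$sunset,
        dusk_civil = sd$dusk_civil, dusk_nautical = sd$dusk_nautical,
        dusk_astro = sd$dusk_astro,
        window_start = w$start, window_end = w$end,
        evening_twilight_duration = sd$evening_twilight_duration,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
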