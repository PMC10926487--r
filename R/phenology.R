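#' @title Arrival/departure phenology
#' @description The cumulative-maximum occupancy model: per-evening
#'   detection rates, an arrival curve (running maximum of the rate up to
#'   the seasonal peak), a departure curve (reverse running maximum from
#'   the peak), and median arrival/departure dates at half the peak rate.
#' @name phenology
NULL

#' Per-evening detection rate
#'
#' Detections per image: `count / exposure` per site-evening. Evenings
#' the camera was off are simply absent — never zero-filled.
#'
#' @param evenings Data frame from [evening_counts()].
#' @return Data frame `site_id`, `date`, `rate`.
#' @export
per_evening_rate <- function(evenings) {
  stopifnot(all(evenings$exposure >= 1))
  out <- data.frame(site_id = evenings$site_id,
                    date = as.Date(evenings$evening_date),
                    rate = evenings$count / evenings$exposure,
                    stringsAsFactors = FALSE)
  out[order(out$site_id, out$date), , drop = FALSE]
}

#' Build the occupancy envelope for one site
#'
#' The relative abundance of aestivating moths is modelled by the
#' cumulative maximum of detections per image over all preceding
#' evenings; the arrival phase ends on the date the absolute maximum is
#' reached (earliest such date on ties). The departure phase runs the
#' same construction backwards from the peak. Calendar gaps (camera
#' outages) are bridged by the running maxima.
#'
#' @param dates Ordered calendar dates with data.
#' @param rate Detections per image on those dates.
#' @param site_id Optional label.
#' @return Object of class `phenology_series`: list with `dates`,
#'   `rate`, `peak_date`, `peak_rate`, `arrival` (data frame `date`,
#'   `level` for dates up to the peak) and `departure` (`date`, `level`
#'   from the peak on).
#' @export
build_phenology <- function(dates, rate, site_id = NA_character_) {
  stopifnot(length(dates) == length(rate), length(rate) >= 1)
  o <- order(dates)
  dates <- as.Date(dates)[o]; rate <- rate[o]
  peak_i <- which.max(rate)  # earliest date on ties
  arrival <- data.frame(date = dates[seq_len(peak_i)],
                        level = cummax(rate[seq_len(peak_i)]))
  dep_idx <- seq(peak_i, length(rate))
  departure <- data.frame(date = dates[dep_idx],
                          level = rev(cummax(rev(rate[dep_idx]))))
  structure(list(site_id = site_id, dates = dates, rate = rate,
                 peak_date = dates[peak_i], peak_rate = rate[peak_i],
                 arrival = arrival, departure = departure),
            class = "phenology_series")
}

#' @export
print.phenology_series <- function(x, ...) {
  cat(sprintf("<phenology_series> %s: %d evenings, peak %.4g det/image on %s\n",
              ifelse(is.na(x$site_id), "", x$site_id), length(x$dates),
              x$peak_rate, format(x$peak_date)))
  invisible(x)
}

#' Median arrival and departure dates
#'
#' The median arrival date is the earliest date whose arrival-curve
#' level reaches half the peak rate; the median departure date is the
#' latest date whose departure-curve level still does ("at least half"
#' on both sides, so a rate exactly at the half level counts as
#' arrived).
#'
#' @param ph A `phenology_series`.
#' @return Object of class `phenology_summary`: list `site_id`,
#'   `A_half`, `D_half`, `half_level`, `peak_date`, `peak_rate`. If the
#'   peak rate is zero the site was never occupied and `A_half`/`D_half`
#'   are `NA` with `occupied = FALSE`.
#' @export
median_dates <- function(ph) {
  stopifnot(inherits(ph, "phenology_series"))
  if (ph$peak_rate <= 0) {
    return(structure(list(site_id = ph$site_id, A_half = as.Date(NA),
                          D_half = as.Date(NA), half_level = 0,
                          peak_date = ph$peak_date, peak_rate = 0,
                          occupied = FALSE), class = "phenology_summary"))
  }
  half <- ph$peak_rate / 2
  A <- ph$arrival$date[which(ph$arrival$level >= half)[1]]
  D <- ph$departure$date[max(which(ph$departure$level >= half))]
  structure(list(site_id = ph$site_id, A_half = A, D_half = D,
                 half_level = half, peak_date = ph$peak_date,
                 peak_rate = ph$peak_rate, occupied = TRUE),
            class = "phenology_summary")
}

#' @export
print.phenology_summary <- function(x, ...) {
  if (!x$occupied) {
    cat("<phenology_summary> no occupancy (peak rate 0)\n")
  } else {
    cat(sprintf("<phenology_summary> %s: A1/2 %s, D1/2 %s, half level %.4g\n",
                ifelse(is.na(x$site_id), "", x$site_id),
                format(x$A_half), format(x$D_half), x$half_level))
  }
  invisible(x)
}

#' Thermal lead-up to arrival and departure
#'
#' 3-day average maximum temperatures (inclusive of the event date) at
#' the nearest station, optionally lapse-adjusted to a target elevation.
#'
#' @param summary A `phenology_summary`.
#' @param weather Weather data frame for the mapped station.
#' @param station_elevation Station elevation (m).
#' @param to_elevation Elevation to project to (m); default the station
#'   elevation (no adjustment).
#' @param lapse_rate °C per 1000 m.
#' @return Data frame: `event` ("A_half"/"D_half"), `date`, `tmax_3day`
#'   (projected), `sd`, `n_days`.
#' @export
phenology_temperatures <- function(summary, weather, station_elevation,
                                   to_elevation = station_elevation,
                                   lapse_rate = 9.1) {
  stopifnot(inherits(summary, "phenology_summary"))
  if (!summary$occupied) stop("no occupancy: no arrival/departure dates")
  one <- function(event, date) {
    r <- rolling_3day_avg_max(weather, date)
    data.frame(event = event, date = date,
               tmax_3day = lapse_adjust(r$mean, station_elevation,
                                        to_elevation, rate = lapse_rate),
               sd = r$sd, n_days = r$n_days, stringsAsFactors = FALSE)
  }
  rbind(one("A_half", summary$A_half), one("D_half", summary$D_half))
}

#' Export phenology curves as tidy CSV
#'
#' @param ph A `phenology_series`.
#' @param path Output CSV (`date`, `phase`, `level`).
#' @return Invisibly, the tidy data frame.
#' @export
write_phenology_curves <- function(ph, path) {
  tidy <- rbind(
    data.frame(site_id = ph$site_id, date = ph$arrival$date,
               phase = "arrival", level = ph$arrival$level),
    data.frame(site_id = ph$site_id, date = ph$departure$date,
               phase = "departure", level = ph$departure$level))
  utils::write.csv(tidy, path, row.names = FALSE)
  invisible(tidy)
}
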