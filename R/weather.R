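#' @title Weather covariates
#' @description Station weather ingest, lapse-rate temperature
#'   projection, covariate-table assembly for the abundance regression,
#'   and greedy collinearity pruning.
#' @name weather
NULL

#' Read a daily weather table
#'
#' BOM-style daily observations: one row per station-day with columns
#' `station_id`, `date`, `tmax`, `tmin`, `t9am`, `t3pm`, `max_gust_ms`,
#' `rainfall_mm`, `rh9am_pct`. Empty cells stay `NA`.
#'
#' @param path CSV path.
#' @return Data frame with `date` as `Date` and numeric measurements.
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "date", "tmax", "tmin", "t9am", "t3pm",
            "max_gust_ms", "rainfall_mm", "rh9am_pct")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("weather CSV missing columns: ",
                         paste(miss, collapse = ", "))
  raw$date <- as.Date(raw$date)
  for (cl in need[-(1:2)]) raw[[cl]] <- as.numeric(raw[[cl]])
  bad <- !is.na(raw$tmin) & !is.na(raw$tmax) & raw$tmin > raw$tmax
  if (any(bad)) stop("tmin > tmax at row ", which(bad)[1])
  raw
}

#' Project a temperature between elevations with an adiabatic lapse rate
#'
#' `temp - rate * (to_elevation - from_elevation) / 1000`: temperatures
#' cool by `rate` degrees Celsius per 1000 m climbed. The default rate of
#' 9.1 °C/1000 m is the dry-adiabatic value used to relate station
#' temperatures to camera-site elevations.
#'
#' @param temp Temperature (°C) at `from_elevation`.
#' @param from_elevation,to_elevation Elevations (m).
#' @param rate Lapse rate, °C per 1000 m.
#' @return Temperature (°C) at `to_elevation`.
#' @examples
#' lapse_adjust(17.3, 2005, 2152)  # 16.0 to one decimal place
#' @export
lapse_adjust <- function(temp, from_elevation, to_elevation, rate = 9.1) {
  temp - rate * (to_elevation - from_elevation) / 1000
}

#' Rolling 3-day average of daily maximum temperature
#'
#' Mean (and sample SD) of `tmax` over the three days ending at
#' `end_date` inclusive, skipping missing days. Used to summarise the
#' thermal lead-up to arrival and departure dates.
#'
#' @param weather Weather data frame (one station).
#' @param end_date Last day of the 3-day window (`Date`).
#' @return List `mean`, `sd`, `n_days` (days with data; `mean` is `NA`
#'   when all three are missing; `sd` is `NA` when fewer than 2).
#' @export
rolling_3day_avg_max <- function(weather, end_date) {
  end_date <- as.Date(end_date)
  days <- seq(end_date - 2, end_date, by = "day")
  v <- weather$tmax[match(days, weather$date)]
  v <- v[!is.na(v)]
  list(mean = if (length(v)) mean(v) else NA_real_,
       sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
       n_days = length(v))
}

#' Assemble the covariate table for the abundance regression
#'
#' Joins per-evening counts to site metadata, solar twilight durations
#' and mapped station weather. Each retained row carries the abiotic
#' covariates entered in the evening-count regression: `elevation`,
#' `tmax`, `tmin`, `temp_range` (tmax − tmin), `max_gust`,
#' `twilight_duration` (seconds of evening twilight), `study_year`
#' (integer season index, first season = 1), `rh9am`, `latitude`,
#' `rainfall`. Temperatures are lapse-adjusted from station elevation to
#' site elevation by default. Rows with any missing covariate are
#' dropped; the tally is attached as `attr(x, "dropped")`.
#'
#' @param evenings Data frame from [evening_counts()].
#' @param weather Weather data frame (all stations).
#' @param sites Site metadata: `site_id`, `lat`, `lon`, `elevation_m`,
#'   `utc_offset_hours`.
#' @param solar Data frame from [solar_table()] (needs `site_id`, `date`,
#'   `evening_twilight_duration`).
#' @param station_map Named character vector, site_id -> station_id.
#' @param stations Data frame `station_id`, `elevation_m`.
#' @param lapse_rate °C per 1000 m for the temperature projection.
#' @param adjust_temperatures Project station temperatures to site
#'   elevation (default TRUE).
#' @return Covariate table: `site_id`, `evening_date`, `count`,
#'   `exposure`, then the covariate columns; `attr(,"covariate_names")`
#'   holds their order, `attr(,"dropped")` the missing-data tally.
#' @export
assemble_covariates <- function(evenings, weather, sites, solar, station_map,
                                stations, lapse_rate = 9.1,
                                adjust_temperatures = TRUE) {
  unmapped <- setdiff(unique(evenings$site_id), names(station_map))
  if (length(unmapped))
    stop("no station mapped for site(s): ", paste(unmapped, collapse = ", "))
  si <- match(evenings$site_id, sites$site_id)
  if (anyNA(si)) stop("site metadata missing for: ",
                      evenings$site_id[which(is.na(si))[1]])
  stn <- station_map[evenings$site_id]
  st_elev <- stations$elevation_m[match(stn, stations$station_id)]
  if (anyNA(st_elev)) stop("station elevation missing for: ",
                           stn[which(is.na(st_elev))[1]])
  wkey <- paste(weather$station_id, weather$date)
  wi <- match(paste(stn, evenings$evening_date), wkey)
  skey <- paste(solar$site_id, solar$date)
  oi <- match(paste(evenings$site_id, evenings$evening_date), skey)
  if (anyNA(oi)) stop("solar table does not cover all site-evenings")

  adj <- function(v) {
    if (adjust_temperatures)
      lapse_adjust(v, st_elev, sites$elevation_m[si], rate = lapse_rate)
    else v
  }
  season_year <- function(d) as.integer(format(as.Date(d) + 184, "%Y"))
  sy <- season_year(evenings$evening_date)
  out <- data.frame(
    site_id = evenings$site_id,
    evening_date = as.Date(evenings$evening_date),
    count = evenings$count,
    exposure = evenings$exposure,
    elevation = sites$elevation_m[si],
    tmax = adj(weather$tmax[wi]),
    tmin = adj(weather$tmin[wi]),
    max_gust = weather$max_gust_ms[wi],
    twilight_duration = solar$evening_twilight_duration[oi],
    study_year = sy - min(sy) + 1L,
    rh9am = weather$rh9am_pct[wi],
    latitude = sites$lat[si],
    rainfall = weather$rainfall_mm[wi],
    stringsAsFactors = FALSE)
  out$temp_range <- out$tmax - out$tmin
  cov_names <- c("elevation", "tmax", "tmin", "temp_range", "max_gust",
                 "twilight_duration", "study_year", "rh9am", "latitude",
                 "rainfall")
  complete <- stats::complete.cases(out[, cov_names])
  dropped <- sum(!complete)
  out <- out[complete, c("site_id", "evening_date", "count", "exposure",
                         cov_names)]
  rownames(out) <- NULL
  attr(out, "covariate_names") <- cov_names
  attr(out, "dropped") <- dropped
  out
}

#' Pruning configuration
#'
#' @param r2_threshold Largest pairwise Pearson R² tolerated between
#'   retained covariates (default 0.3).
#' @return List of class `prune_config`.
#' @export
prune_config <- function(r2_threshold = 0.3) {
  stopifnot(r2_threshold > 0, r2_threshold < 1)
  structure(list(r2_threshold = r2_threshold), class = "prune_config")
}

#' Greedy collinearity pruning of covariates
#'
#' Repeatedly finds the covariate pair with the largest pairwise Pearson
#' R²; while it exceeds the threshold, removes the member of the pair
#' whose absolute Pearson correlation with the response (the per-evening
#' detection rate, count/exposure, by default) is smaller, and repeats.
#' Zero-variance covariates are removed first (their correlations are
#' undefined). Ties — equal pair R² or equal response correlations — are
#' broken by lexicographic covariate name, so the result is
#' deterministic.
#'
#' @param table Covariate table from [assemble_covariates()] (or any
#'   data frame with the covariate columns).
#' @param response Numeric response per row; default
#'   `table$count / table$exposure`.
#' @param cfg A [prune_config()].
#' @param covariate_names Covariates to consider; defaults to
#'   `attr(table, "covariate_names")`.
#' @return List: `retained` (ordered names), `removed` (data frame
#'   `step`, `covariate_a`, `covariate_b`, `r_squared`, `removed`,
#'   `reason`).
#' @export
prune_collinear <- function(table, response = NULL, cfg = prune_config(),
                            covariate_names = attr(table, "covariate_names")) {
  stopifnot(inherits(cfg, "prune_config"))
  if (is.null(covariate_names))
    stop("covariate_names not given and not attached to table")
  if (is.null(response)) response <- table$count / table$exposure
  stopifnot(length(covariate_names) >= 2, nrow(table) >= 3)
  keep <- sort(covariate_names)
  log_rows <- list()
  step <- 0L
  add_log <- function(a, b, r2, rm, reason) {
    step <<- step + 1L
    log_rows[[step]] <<- data.frame(step = step, covariate_a = a,
                                    covariate_b = b, r_squared = r2,
                                    removed = rm, reason = reason,
                                    stringsAsFactors = FALSE)
  }
  # constant covariates out first: correlation undefined
  for (nm in keep) {
    if (stats::sd(table[[nm]]) == 0) {
      add_log(nm, NA_character_, NA_real_, nm, "zero variance")
    }
  }
  keep <- setdiff(keep, vapply(log_rows, function(r) r$removed, ""))
  while (length(keep) >= 2) {
    cm <- stats::cor(as.matrix(table[, keep]))^2
    diag(cm) <- -Inf
    m <- max(cm)
    if (m <= cfg$r2_threshold) break
    idx <- which(cm == m, arr.ind = TRUE)
    # first pair in (sorted-name) order; upper triangle only
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    a <- keep[idx[1, 1]]; b <- keep[idx[1, 2]]
    ra <- abs(stats::cor(table[[a]], response))
    rb <- abs(stats::cor(table[[b]], response))
    rm <- if (ra < rb) a else if (rb < ra) b else max(a, b)
    add_log(a, b, m, rm, "collinear pair")
    keep <- setdiff(keep, rm)
  }
  retained <- covariate_names[covariate_names %in% keep]
  list(retained = retained,
       removed = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(step = integer(), covariate_a = character(),
                    covariate_b = character(), r_squared = numeric(),
                    removed = character(), reason = character()))
}
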