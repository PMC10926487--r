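#' @title Synthetic field data
#' @description Seeded generators that emulate the statistical structure
#'   of the camera-trap data: an evening-twilight activity peak,
#'   weather-modulated Poisson counts with image-count exposure, a
#'   trapezoidal seasonal occupancy envelope, and uni-/bimodal circular
#'   track directions. A truth ledger records every intermediate so each
#'   pipeline stage can be tested against exact bookkeeping.
#' @name synthetic-data
NULL

.default_sites <- function() {
  data.frame(
    site_id = c("alpine_high", "alpine_low"),
    lat = c(-36.456, -35.573),
    lon = c(148.263, 148.777),
    elevation_m = c(2152, 1839),
    utc_offset_hours = c(11, 11),
    camera_azimuth_deg = c(0, 0),
    stringsAsFactors = FALSE)
}

.default_stations <- function() {
  data.frame(station_id = c("stn_thredbo", "stn_ginini"),
             elevation_m = c(1957, 1760),
             tmax_midsummer = c(18, 20), tmax_amplitude = c(8, 8),
             tmax_sd = c(3, 3), temp_range_mean = c(9, 9),
             temp_range_sd = c(2, 2), gust_mean = c(12, 10),
             gust_sd = c(4, 4), rain_prob = c(0.3, 0.3),
             rain_mean_mm = c(4, 4), rh_mean = c(65, 60), rh_sd = c(12, 12),
             stringsAsFactors = FALSE)
}

.default_envelopes <- function() {
  list(
    alpine_high = list(onset = as.Date("2020-10-20"), rise_days = 14,
                       plateau_rate = 10, fall_start = as.Date("2021-02-20"),
                       fall_days = 21),
    alpine_low = list(onset = as.Date("2020-10-05"), rise_days = 14,
                      plateau_rate = 5, fall_start = as.Date("2021-01-10"),
                      fall_days = 21))
}

#' Season simulation configuration
#'
#' Defaults emulate the field deployment: two alpine sites followed from
#' mid-September to early April (a ~200-evening season), a 10-minute
#' image cadence, trapezoidal occupancy envelopes peaking at 5-10
#' detections per image (on the order of a hundred detections per
#' evening at peak, matching the magnitude of the field counts),
#' weather modulation with a positive maximum-temperature and negative
#' gust-speed effect, and detection times concentrated in evening
#' twilight (von Mises kernel).
#'
#' @param sites,stations,station_map Site and station tables and the
#'   site-to-station mapping.
#' @param date_start,date_end Season span (local dates).
#' @param image_interval_min Image cadence, minutes (1-60).
#' @param envelopes Named list (per site) of trapezoid parameters:
#'   `onset`, `rise_days`, `plateau_rate` (detections/image),
#'   `fall_start`, `fall_days`.
#' @param glm_beta Named log-rate coefficients applied to centred
#'   weather covariates.
#' @param beta_centers Centring constants for the weather covariates.
#' @param twilight_kappa Concentration of the within-window detection
#'   time kernel.
#' @param qc_fail Named fractions of detections drawn to fail each
#'   quality filter (`score`, `snr`, `freq`); all 0 by default.
#' @param false_positive_rate Expected rain-caused false detections per
#'   rainy pre-onset evening.
#' @param seed Mandatory integer seed.
#' @return List of class `season_config`.
#' @export
season_config <- function(sites = .default_sites(),
                          stations = .default_stations(),
                          station_map = c(alpine_high = "stn_thredbo",
                                          alpine_low = "stn_ginini"),
                          date_start = as.Date("2020-09-15"),
                          date_end = as.Date("2021-04-02"),
                          image_interval_min = 10,
                          envelopes = .default_envelopes(),
                          glm_beta = c(tmax = 0.06, max_gust = -0.05,
                                       rainfall = 0.01, rh9am = -0.005),
                          beta_centers = c(tmax = 15, max_gust = 12,
                                           rainfall = 1.5, rh9am = 62),
                          twilight_kappa = 2,
                          qc_fail = c(score = 0, snr = 0, freq = 0),
                          false_positive_rate = 0,
                          seed = 1) {
  stopifnot(image_interval_min >= 1, image_interval_min <= 60,
            all(names(envelopes) %in% sites$site_id) ||
              all(sites$site_id %in% names(envelopes)))
  for (env in envelopes) {
    stopifnot(env$plateau_rate >= 0)
    if (env$onset < date_start || env$fall_start + env$fall_days > date_end)
      stop("envelope dates outside the season span")
  }
  structure(list(sites = sites, stations = stations,
                 station_map = station_map, date_start = as.Date(date_start),
                 date_end = as.Date(date_end),
                 image_interval_min = image_interval_min,
                 envelopes = envelopes, glm_beta = glm_beta,
                 beta_centers = beta_centers,
                 twilight_kappa = twilight_kappa, qc_fail = qc_fail,
                 false_positive_rate = false_positive_rate,
                 seed = as.integer(seed)),
            class = "season_config")
}

#' Trapezoidal occupancy envelope
#'
#' Linear rise over `rise_days` from `onset`, a plateau at
#' `plateau_rate`, and a linear fall over `fall_days` from `fall_start`.
#' The half-rise date is `onset + rise_days/2`; the half-fall date
#' `fall_start + fall_days/2`.
#'
#' @param dates Vector of `Date`s.
#' @param env Envelope parameter list.
#' @return Expected detections per image on each date.
#' @export
trapezoid_envelope <- function(dates, env) {
  d <- as.numeric(as.Date(dates))
  onset <- as.numeric(env$onset); fs <- as.numeric(env$fall_start)
  up <- pmin(pmax((d - onset) / env$rise_days, 0), 1)
  down <- pmin(pmax((fs + env$fall_days - d) / env$fall_days, 0), 1)
  env$plateau_rate * pmin(up, down)
}

.draw_qc <- function(n, qc_fail, thresholds = filter_thresholds()) {
  fail_score <- stats::runif(n) < qc_fail["score"]
  fail_snr <- stats::runif(n) < qc_fail["snr"]
  fail_freq <- stats::runif(n) < qc_fail["freq"]
  score <- ifelse(fail_score,
                  stats::runif(n, 0, thresholds$min_score - 1e-9),
                  stats::runif(n, thresholds$min_score, 1))
  snr <- ifelse(fail_snr,
                thresholds$snr_range[2] + stats::runif(n, 1, 30),
                stats::runif(n, thresholds$snr_range[1], thresholds$snr_range[2]))
  freq <- ifelse(fail_freq,
                 ifelse(stats::runif(n) < 0.5,
                        stats::runif(n, 5, thresholds$freq_range_hz[1] - 1e-6),
                        stats::runif(n, thresholds$freq_range_hz[2] + 1e-6, 120)),
                 stats::runif(n, thresholds$freq_range_hz[1],
                              thresholds$freq_range_hz[2]))
  data.frame(score = score, wingbeat_snr = snr, wingbeat_freq = freq,
             passes = !(fail_score | fail_snr | fail_freq))
}

#' Simulate a monitoring season
#'
#' Draws daily station weather, builds evening twilight windows and a
#' capture log at the configured cadence, draws per-evening moth counts
#' as Poisson with mean `envelope(date) * exp(beta . (weather - centre))
#' * n_images`, places detection timestamps inside the window with a von
#' Mises twilight kernel, attaches quality-control fields (a
#' configurable fraction failing each filter), and injects rain-caused
#' false positives on rainy pre-onset evenings. Every intermediate is
#' recorded in the truth ledger.
#'
#' @param cfg A [season_config()].
#' @return List of class `season_sim`: `detections` (data frame in the
#'   detection-CSV dialect, parsed timestamps), `captures`, `weather`,
#'   `sites`, `stations`, `solar` (window table), and `truth` (per
#'   site-evening: `n_images`, `envelope`, `weather_multiplier`,
#'   `lambda_per_image`, `count_moth`, `count_fp`, `count_pass` — the
#'   count a quality-filtered pipeline should reproduce — and `rate`).
#' @export
simulate_season <- function(cfg = season_config()) {
  stopifnot(inherits(cfg, "season_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  dates <- seq(cfg$date_start, cfg$date_end, by = "day")
  ndays <- length(dates)

  # --- weather -----------------------------------------------------------
  midsummer <- as.Date(paste0(format(cfg$date_start, "%Y"), "-12-31")) + 15
  wx <- do.call(rbind, lapply(seq_len(nrow(cfg$stations)), function(i) {
    st <- cfg$stations[i, ]
    seasonal <- st$tmax_midsummer + st$tmax_amplitude *
      cos(2 * pi * as.numeric(dates - midsummer) / 365.25)
    tmax <- seasonal + stats::rnorm(ndays, 0, st$tmax_sd)
    rng <- pmax(stats::rnorm(ndays, st$temp_range_mean, st$temp_range_sd), 0.5)
    tmin <- tmax - rng
    gust <- pmax(stats::rnorm(ndays, st$gust_mean, st$gust_sd), 0.5)
    rain <- ifelse(stats::runif(ndays) < st$rain_prob,
                   round(stats::rexp(ndays, 1 / st$rain_mean_mm), 1), 0)
    rh <- pmin(pmax(stats::rnorm(ndays, st$rh_mean, st$rh_sd), 5), 100)
    data.frame(station_id = st$station_id, date = dates,
               tmax = round(tmax, 1), tmin = round(tmin, 1),
               t9am = round(tmin + 0.3 * rng, 1),
               t3pm = round(tmax - 0.2 * rng, 1),
               max_gust_ms = round(gust, 1), rainfall_mm = rain,
               rh9am_pct = round(rh), stringsAsFactors = FALSE)
  }))

  # --- solar windows and capture log -------------------------------------
  solar <- solar_table(cfg$sites, dates)
  caps <- list(); dets <- list(); truth <- list()
  for (s in cfg$sites$site_id) {
    srow <- cfg$sites[cfg$sites$site_id == s, ]
    env <- cfg$envelopes[[s]]
    stn <- cfg$station_map[[s]]
    sol <- solar[solar$site_id == s, ]
    wkey <- match(paste(stn, sol$date), paste(wx$station_id, wx$date))
    wrow <- wx[wkey, ]
    x <- rbind(tmax = wrow$tmax, max_gust = wrow$max_gust_ms,
               rainfall = wrow$rainfall_mm, rh9am = wrow$rh9am_pct)
    mult <- exp(colSums(cfg$glm_beta[rownames(x)] *
                          (x - cfg$beta_centers[rownames(x)])))
    envl <- trapezoid_envelope(sol$date, env)

    # capture log: cadence across [sunset - 30 min, dusk_astro + 30 min]
    cap_times <- lapply(seq_len(nrow(sol)), function(i) {
      seq(sol$window_start[i] - 1800, sol$window_end[i] + 1800,
          by = cfg$image_interval_min * 60)
    })
    n_img <- vapply(seq_len(nrow(sol)), function(i) {
      sum(cap_times[[i]] >= sol$window_start[i] &
            cap_times[[i]] < sol$window_end[i])
    }, 0L)
    caps[[s]] <- data.frame(site_id = s,
                            timestamp = do.call(c, cap_times),
                            utc_offset_hours = srow$utc_offset_hours)

    lambda <- envl * mult
    count_moth <- stats::rpois(nrow(sol), lambda * n_img)
    rainy_preonset <- wrow$rainfall_mm > 0 & sol$date < env$onset
    count_fp <- ifelse(rainy_preonset,
                       stats::rpois(nrow(sol), cfg$false_positive_rate), 0L)

    ts_list <- lapply(seq_len(nrow(sol)), function(i) {
      nm <- count_moth[i]; nf <- count_fp[i]
      if (nm + nf == 0) return(NULL)
      frac_m <- if (nm) wrap180(rvonmises(nm, 0, cfg$twilight_kappa) *
                                  180 / pi) / 360 + 0.5 else numeric()
      frac_f <- if (nf) stats::runif(nf) else numeric()
      dur <- as.numeric(sol$window_end[i] - sol$window_start[i], units = "secs")
      sol$window_start[i] + c(frac_m, frac_f) * dur * 0.999999
    })
    n_tot <- count_moth + count_fp
    if (sum(n_tot) > 0) {
      qc <- .draw_qc(sum(n_tot), cfg$qc_fail)
      dets[[s]] <- data.frame(
        site_id = s,
        timestamp = do.call(c, Filter(Negate(is.null), ts_list)),
        utc_offset_hours = srow$utc_offset_hours,
        score = qc$score, wingbeat_snr = qc$wingbeat_snr,
        wingbeat_freq = qc$wingbeat_freq,
        track_dx = NA_real_, track_dy = NA_real_, source = "still",
        passes_qc = qc$passes,
        evening_date = rep(sol$date, n_tot), stringsAsFactors = FALSE)
      pass_by_evening <- vapply(seq_len(nrow(sol)), function(i)
        sum(qc$passes[rep(seq_len(nrow(sol)), n_tot) == i]), 0L)
    } else {
      pass_by_evening <- integer(nrow(sol))
    }
    truth[[s]] <- data.frame(
      site_id = s, date = sol$date, n_images = n_img, envelope = envl,
      weather_multiplier = mult, lambda_per_image = lambda,
      count_moth = count_moth, count_fp = count_fp,
      count_pass = pass_by_evening,
      rate = ifelse(n_img > 0, pass_by_evening / n_img, NA_real_),
      stringsAsFactors = FALSE)
  }
  detections <- do.call(rbind, dets)
  if (is.null(detections)) {
    detections <- cbind(empty_detections(), passes_qc = logical(),
                        evening_date = as.Date(character()))
  }
  rownames(detections) <- NULL
  structure(list(detections = detections,
                 captures = do.call(rbind, caps),
                 weather = wx, sites = cfg$sites, stations = cfg$stations,
                 solar = solar, truth = do.call(rbind, truth),
                 config = cfg),
            class = "season_sim")
}

#' Write a simulated season to plain-text files
#'
#' Emits the detection CSV, capture-log CSV, weather CSV, site and
#' station metadata CSVs, and the truth ledger as JSON, in the dialects
#' the ingest functions read.
#'
#' @param sim A `season_sim`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_season <- function(sim, dir) {
  stopifnot(inherits(sim, "season_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iso <- function(t, off) {
    paste0(format(t + off * 3600, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
           sprintf("%+03d:%02d", as.integer(off), as.integer(abs(off) %% 1 * 60)))
  }
  det <- sim$detections
  det_out <- data.frame(site_id = det$site_id,
                        timestamp = iso(det$timestamp, det$utc_offset_hours),
                        score = det$score, wingbeat_snr = det$wingbeat_snr,
                        wingbeat_freq = det$wingbeat_freq,
                        track_dx = det$track_dx, track_dy = det$track_dy,
                        source = det$source)
  cap <- sim$captures
  cap_out <- data.frame(site_id = cap$site_id,
                        timestamp = iso(cap$timestamp, cap$utc_offset_hours))
  paths <- c(detections = file.path(dir, "detections.csv"),
             captures = file.path(dir, "captures.csv"),
             weather = file.path(dir, "weather.csv"),
             sites = file.path(dir, "sites.csv"),
             stations = file.path(dir, "stations.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(det_out, paths["detections"], row.names = FALSE, na = "")
  utils::write.csv(cap_out, paths["captures"], row.names = FALSE)
  utils::write.csv(sim$weather, paths["weather"], row.names = FALSE, na = "")
  utils::write.csv(sim$sites, paths["sites"], row.names = FALSE)
  utils::write.csv(sim$stations[, c("station_id", "elevation_m")],
                   paths["stations"], row.names = FALSE)
  tr <- sim$truth; tr$date <- as.character(tr$date)
  jsonlite::write_json(tr, paths["truth"], dataframe = "rows", digits = NA)
  invisible(paths)
}

#' Direction-sample configuration
#'
#' @param model_id One of the orientation family names (see
#'   [fit_orientation_models()]); governs which mixture is sampled.
#' @param mu1,kappa1,mu2,kappa2 Component mean directions (degrees) and
#'   concentrations.
#' @param lambda Weight of the first component, in \[0, 1\].
#' @param n Draws per location.
#' @param locations Character vector of location ids.
#' @param magnitudes `"unit"` or `"lognormal"` track magnitudes.
#' @param seed Integer seed.
#' @return List of class `direction_config`.
#' @export
direction_config <- function(model_id = "bimodal_shared_free",
                             mu1 = 60, kappa1 = 4, mu2 = 200, kappa2 = 4,
                             lambda = 0.6, n = 2000,
                             locations = "loc1", magnitudes = "unit",
                             seed = 1) {
  stopifnot(lambda >= 0, lambda <= 1, kappa1 >= 0, kappa2 >= 0, n >= 1)
  structure(list(model_id = model_id, mu1 = mu1, kappa1 = kappa1,
                 mu2 = mu2, kappa2 = kappa2, lambda = lambda, n = n,
                 locations = locations, magnitudes = magnitudes,
                 seed = as.integer(seed)),
            class = "direction_config")
}

#' Simulate circular track-direction samples
#'
#' I.i.d. draws from the configured one- or two-component von Mises
#' mixture (`uniform` gives the uniform circle; `unimodal` ignores the
#' second component). Identical seeds give identical samples.
#'
#' @param cfg A [direction_config()].
#' @return Named list (per location) of data frames `direction`
#'   (degrees, \[0, 360)) and `magnitude`.
#' @export
simulate_directions <- function(cfg = direction_config()) {
  stopifnot(inherits(cfg, "direction_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  out <- list()
  for (loc in cfg$locations) {
    ang <- if (cfg$model_id == "uniform") {
      stats::runif(cfg$n, 0, 2 * pi)
    } else if (cfg$model_id %in% c("unimodal", "unimodal_uniform")) {
      from1 <- if (cfg$model_id == "unimodal") rep(TRUE, cfg$n) else
        stats::runif(cfg$n) < cfg$lambda
      ifelse(from1, rvonmises(cfg$n, cfg$mu1 * pi / 180, cfg$kappa1),
             stats::runif(cfg$n, 0, 2 * pi))
    } else {
      mu2 <- if (grepl("^axial", cfg$model_id)) cfg$mu1 + 180 else cfg$mu2
      k2 <- if (grepl("shared|axial", cfg$model_id)) cfg$kappa1 else cfg$kappa2
      from1 <- stats::runif(cfg$n) < cfg$lambda
      a1 <- rvonmises(cfg$n, cfg$mu1 * pi / 180, cfg$kappa1)
      a2 <- rvonmises(cfg$n, mu2 * pi / 180, k2)
      ifelse(from1, a1, a2)
    }
    mag <- switch(cfg$magnitudes,
                  unit = rep(1, cfg$n),
                  lognormal = stats::rlnorm(cfg$n, 2, 0.5),
                  stop("unknown magnitudes model: ", cfg$magnitudes))
    out[[loc]] <- data.frame(direction = wrap360(ang * 180 / pi),
                             magnitude = mag)
  }
  out
}

#' Simulate a covariate table with known coefficients
#'
#' A calibration-scale generator for the Poisson regression: covariates
#' drawn as independent normals, counts as Poisson with mean
#' `exposure * exp(beta0 + X beta)`. Used to verify coefficient
#' recovery and confidence-interval coverage.
#'
#' @param n Number of evenings (rows).
#' @param beta Named coefficient vector (log-rate per covariate unit).
#' @param beta0 Intercept (log detections per image at covariate 0).
#' @param exposure_range Integer range of per-evening image counts.
#' @param seed Integer seed.
#' @return Covariate table (with `covariate_names` attribute) plus
#'   `attr(,"beta")`/`attr(,"beta0")`.
#' @export
simulate_covariate_table <- function(n = 500,
                                     beta = c(tmax = 0.06, max_gust = -0.05,
                                              rainfall = 0.01),
                                     beta0 = 0.5, exposure_range = c(8, 20),
                                     seed = 1) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  X <- vapply(names(beta), function(nm) stats::rnorm(n), numeric(n))
  exposure <- sample(exposure_range[1]:exposure_range[2], n, replace = TRUE)
  eta <- beta0 + as.vector(X %*% beta)
  count <- stats::rpois(n, exposure * exp(eta))
  out <- data.frame(site_id = "sim", evening_date = as.Date("2020-10-01") +
                      seq_len(n) - 1, count = count, exposure = exposure,
                    X, stringsAsFactors = FALSE)
  attr(out, "covariate_names") <- names(beta)
  attr(out, "beta") <- beta
  attr(out, "beta0") <- beta0
  out
}
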