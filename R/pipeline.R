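#' @title Pipeline orchestration
#' @description End-to-end drivers for the two studies: the seasonal
#'   abundance study (ingest, filter, twilight windows, evening counts,
#'   covariates, pruning, Poisson regression, phenology) and the
#'   single-night orientation study (track directions, uniformity and
#'   homogeneity tests, orientation-model selection, summit-relative
#'   analysis, time-elevation regression, activity binning). All
#'   randomness sits behind one seed recorded in the run manifest.
#' @name pipeline
NULL

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Read a run configuration
#'
#' YAML with input `paths` (detections, captures, weather, sites,
#' stations — and for study 2: tracks, lux), filter thresholds, twilight
#' window definition, `station_map`, `lapse_rate`, `r2_threshold`,
#' circular-test settings (`mc_reps`, `seed`), summit coordinates, and
#' the output directory.
#'
#' @param path YAML file.
#' @return Config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  yaml::read_yaml(path)
}

.manifest <- function(cfg, inputs, out_dir) {
  list(config = cfg,
       inputs = lapply(inputs, function(p)
         list(path = p, md5 = unname(tools::md5sum(p)))),
       r_version = as.character(getRversion()),
       package_version = as.character(utils::packageVersion("alpinemoth")),
       seed = cfg$seed)
}

#' Run the seasonal abundance study
#'
#' Executes ingest, quality filtering, twilight windowing, evening
#' counting, covariate assembly, collinearity pruning, the
#' exposure-offset Poisson fit, and the arrival/departure phenology
#' model; writes the fit report (JSON + text), phenology summary and
#' curves (CSV), the pruning removal log, and a run manifest with input
#' checksums.
#'
#' @param cfg Config list (see [read_run_config()]): needs
#'   `paths$detections`, `paths$captures`, `paths$weather`,
#'   `paths$sites`, `paths$stations`, `station_map`, and optionally
#'   `min_score`/`snr_range`/`freq_range_hz`, `window_definition`,
#'   `lapse_rate`, `r2_threshold`, `seed`, `output_dir`.
#' @param output_dir Overrides `cfg$output_dir`.
#' @return Invisibly, a list: `counts`, `covariates`, `pruning`, `fit`,
#'   `effects`, `phenology` (per-site summaries), `manifest`.
#' @export
run_study1 <- function(cfg, output_dir = cfg$output_dir) {
  stopifnot(!is.null(output_dir))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$paths
  for (nm in c("detections", "captures", "weather", "sites", "stations"))
    if (is.null(p[[nm]]) || !file.exists(p[[nm]]))
      stop("stage 'inputs' failed: missing input file '", nm, "'")

  det <- .stage("ingest", read_detections(p$detections, dialect = "csv"))
  caps <- .stage("ingest", read_capture_log(p$captures))
  sites <- .stage("ingest", utils::read.csv(p$sites, stringsAsFactors = FALSE))
  stations <- .stage("ingest", utils::read.csv(p$stations, stringsAsFactors = FALSE))
  wx <- .stage("weather", read_weather(p$weather))

  thr <- filter_thresholds(
    min_score = cfg$min_score %||% 0.8,
    snr_range = cfg$snr_range %||% c(1, 50),
    freq_range_hz = cfg$freq_range_hz %||% c(27, 78))
  det_f <- .stage("filter", apply_quality_filters(det, thr))

  span <- range(as.Date(caps$timestamp + caps$utc_offset_hours * 3600))
  solar <- .stage("solar", solar_table(
    sites, seq(span[1], span[2], by = "day"),
    definition = cfg$window_definition %||% "sunset_to_astro"))
  counts <- .stage("counts", evening_counts(det_f, caps, solar))

  station_map <- unlist(cfg$station_map)
  covs <- .stage("covariates", assemble_covariates(
    counts, wx, sites, solar, station_map, stations,
    lapse_rate = cfg$lapse_rate %||% 9.1))
  pr <- .stage("pruning", prune_collinear(
    covs, cfg = prune_config(cfg$r2_threshold %||% 0.3)))
  fit <- .stage("glm", fit_poisson_exposure(covs, pr$retained))
  eff <- .stage("glm", scaled_effects(fit, covs))

  phen <- list()
  rates <- per_evening_rate(counts)
  for (s in unique(rates$site_id)) {
    r <- rates[rates$site_id == s, ]
    ph <- .stage("phenology", build_phenology(r$date, r$rate, site_id = s))
    sm <- .stage("phenology", median_dates(ph))
    write_phenology_curves(ph, file.path(output_dir,
                                         paste0("phenology_curves_", s, ".csv")))
    phen[[s]] <- sm
  }
  phen_df <- do.call(rbind, lapply(phen, function(sm) data.frame(
    site_id = sm$site_id, occupied = sm$occupied,
    peak_date = as.character(sm$peak_date), peak_rate = sm$peak_rate,
    A_half = as.character(sm$A_half), D_half = as.character(sm$D_half),
    half_level = sm$half_level, stringsAsFactors = FALSE)))
  utils::write.csv(phen_df, file.path(output_dir, "phenology_summary.csv"),
                   row.names = FALSE)
  write_fit_report(fit, eff, pr$removed, file.path(output_dir, "glm_fit.json"))
  utils::write.csv(pr$removed, file.path(output_dir, "pruning_log.csv"),
                   row.names = FALSE)
  manifest <- .manifest(cfg, p[c("detections", "captures", "weather",
                                 "sites", "stations")], output_dir)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(counts = counts, covariates = covs, pruning = pr,
                 fit = fit, effects = eff, phenology = phen,
                 manifest = manifest))
}

#' Run the single-night orientation study
#'
#' From a track table (`location_id`, `timestamp`, `dx_px`, `dy_px`,
#' optional `magnitude`, `elevation_m`) and site metadata with camera
#' azimuths: computes compass track directions, per-location Moore
#' uniformity tests, pairwise Mardia-Watson-Wheeler tests (skipped with
#' a notice when only one location), orientation-model AIC tables per
#' location, a pooled summit-relative model fit, the time-elevation
#' regression, and 2-minute binned activity (with log-linear illuminance
#' when a lux file is supplied).
#'
#' @param cfg Config list: `paths$tracks`, `paths$sites`, optional
#'   `paths$lux`; `summit` (list `lat`, `lon`); `mc_reps`; `seed`;
#'   `min_time_local` ("HH:MM" first valid local clock time, day-mode
#'   clips before it are dropped); `output_dir`.
#' @param output_dir Overrides `cfg$output_dir`.
#' @return Invisibly, a list: `tracks` (with directions), `uniformity`,
#'   `pairwise`, `model_fits`, `summit_fit`, `time_elevation`,
#'   `activity`, `manifest`.
#' @export
run_study2 <- function(cfg, output_dir = cfg$output_dir) {
  stopifnot(!is.null(output_dir))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$paths
  for (nm in c("tracks", "sites"))
    if (is.null(p[[nm]]) || !file.exists(p[[nm]]))
      stop("stage 'inputs' failed: missing input file '", nm, "'")
  seed <- cfg$seed %||% 1
  mc_reps <- cfg$mc_reps %||% 10000

  tracks <- .stage("ingest", utils::read.csv(p$tracks, stringsAsFactors = FALSE))
  sites <- .stage("ingest", utils::read.csv(p$sites, stringsAsFactors = FALSE))
  ts <- .stage("ingest", parse_timestamp(tracks$timestamp))
  tracks$time_utc <- ts$utc
  tracks$utc_offset_hours <- ts$offset
  if (!is.null(cfg$min_time_local)) {
    local_hm <- format(tracks$time_utc + tracks$utc_offset_hours * 3600,
                       "%H:%M", tz = "UTC")
    keep <- local_hm >= cfg$min_time_local
    message(sum(!keep), " track(s) before ", cfg$min_time_local,
            " local dropped (day-mode)")
    tracks <- tracks[keep, ]
  }
  si <- match(tracks$location_id, sites$site_id)
  if (anyNA(si)) stop("stage 'directions' failed: unknown location ",
                      tracks$location_id[which(is.na(si))[1]])
  tracks$direction <- .stage("directions", track_direction(
    tracks$dx_px, tracks$dy_px, sites$camera_azimuth_deg[si]))
  tracks$elevation <- sites$elevation_m[si]

  locs <- sort(unique(tracks$location_id))
  uniformity <- do.call(rbind, lapply(locs, function(l) {
    d <- tracks[tracks$location_id == l, ]
    tst <- .stage("uniformity", moore_rayleigh_test(
      d$direction, if ("magnitude" %in% names(d)) d$magnitude,
      mc_reps = mc_reps, seed = seed))
    data.frame(location_id = l, statistic = tst$statistic,
               p_value = tst$p_value, n = tst$n, stringsAsFactors = FALSE)
  }))
  pairwise <- NULL
  if (length(locs) < 2) {
    message("single location: pairwise Mardia-Watson-Wheeler stage skipped")
  } else {
    prs <- utils::combn(locs, 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
      a <- tracks$direction[tracks$location_id == prs[1, k]]
      b <- tracks$direction[tracks$location_id == prs[2, k]]
      tst <- .stage("pairwise", mww_test(a, b, seed = seed))
      data.frame(location_a = prs[1, k], location_b = prs[2, k],
                 W = tst$statistic, p_value = tst$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  model_fits <- lapply(stats::setNames(locs, locs), function(l)
    .stage("models", fit_orientation_models(
      tracks$direction[tracks$location_id == l])))

  summit_fit <- NULL
  if (!is.null(cfg$summit)) {
    rel <- unlist(lapply(locs, function(l) {
      s <- sites[sites$site_id == l, ]
      summit_relative(tracks$direction[tracks$location_id == l],
                      s$lat, s$lon, cfg$summit$lat, cfg$summit$lon)$relative
    }))
    summit_fit <- .stage("summit", fit_orientation_models(wrap360(rel)))
  }
  te <- NULL
  if (length(unique(tracks$elevation)) >= 2) {
    te <- .stage("regression", time_elevation_regression(
      tracks$time_utc, tracks$elevation))
  } else {
    message("single elevation: time-elevation regression stage skipped")
  }
  act <- .stage("binning", bin_activity(tracks$time_utc, 2))
  if (!is.null(p$lux) && file.exists(p$lux)) {
    lx <- utils::read.csv(p$lux, stringsAsFactors = FALSE)
    lts <- parse_timestamp(lx$timestamp)
    mid <- act$bin_start + 60
    ok <- mid >= min(lts$utc) & mid <= max(lts$utc)
    act$lux <- NA_real_
    act$lux[ok] <- interpolate_lux(lts$utc, lx$illuminance_lx, mid[ok])
  }

  utils::write.csv(uniformity, file.path(output_dir, "uniformity_tests.csv"),
                   row.names = FALSE)
  if (!is.null(pairwise))
    utils::write.csv(pairwise, file.path(output_dir, "pairwise_mww.csv"),
                     row.names = FALSE)
  aic_tab <- do.call(rbind, lapply(locs, function(l)
    cbind(location_id = l, model_fits[[l]]$ranking)))
  utils::write.csv(aic_tab, file.path(output_dir, "orientation_aic.csv"),
                   row.names = FALSE)
  utils::write.csv(act, file.path(output_dir, "binned_activity.csv"),
                   row.names = FALSE)
  results <- list(
    uniformity = uniformity, pairwise = pairwise,
    best_models = vapply(model_fits, function(f) f$best, ""),
    summit_best = if (!is.null(summit_fit)) summit_fit$best else NULL,
    time_elevation = if (!is.null(te)) unclass(te) else NULL,
    seed = seed, mc_reps = mc_reps)
  jsonlite::write_json(results, file.path(output_dir, "study2_results.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- .manifest(c(cfg, list(seed = seed)),
                        Filter(Negate(is.null), p[c("tracks", "sites", "lux")]),
                        output_dir)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(tracks = tracks, uniformity = uniformity,
                 pairwise = pairwise, model_fits = model_fits,
                 summit_fit = summit_fit, time_elevation = te,
                 activity = act, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
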