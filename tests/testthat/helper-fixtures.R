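# Small in-code fixtures shared across test files.

# a detection data frame in the parsed (post-read) layout
make_detections <- function(site_id, timestamp, score = 0.9,
                            snr = 10, freq = 40, offset = 11) {
  n <- length(timestamp)
  data.frame(site_id = rep_len(site_id, n),
             timestamp = as.POSIXct(timestamp, tz = "UTC"),
             utc_offset_hours = rep_len(offset, n),
             score = rep_len(score, n),
             wingbeat_snr = rep_len(snr, n),
             wingbeat_freq = rep_len(freq, n),
             track_dx = rep_len(NA_real_, n),
             track_dy = rep_len(NA_real_, n),
             source = rep_len("still", n), stringsAsFactors = FALSE)
}

# one manual evening window
make_window <- function(site_id, date, start, end) {
  data.frame(site_id = site_id, evening_date = as.Date(date),
             window_start = as.POSIXct(start, tz = "UTC"),
             window_end = as.POSIXct(end, tz = "UTC"),
             stringsAsFactors = FALSE)
}

# a compact single-site season for pipeline smoke tests
small_season_config <- function(seed = 1, ...) {
  sites <- data.frame(site_id = "s1", lat = -36.456, lon = 148.263,
                      elevation_m = 2100, utc_offset_hours = 11,
                      camera_azimuth_deg = 0, stringsAsFactors = FALSE)
  envs <- list(s1 = list(onset = as.Date("2020-10-10"), rise_days = 6,
                         plateau_rate = 4, fall_start = as.Date("2020-11-20"),
                         fall_days = 6))
  season_config(sites = sites, station_map = c(s1 = "stn_thredbo"),
                date_start = as.Date("2020-10-01"),
                date_end = as.Date("2020-12-15"),
                envelopes = envs, seed = seed, ...)
}

# single-site trapezoid season used for phenology recovery
phenology_test_config <- function(seed) {
  sites <- data.frame(site_id = "s1", lat = -36.456, lon = 148.263,
                      elevation_m = 2100, utc_offset_hours = 11,
                      camera_azimuth_deg = 0, stringsAsFactors = FALSE)
  envs <- list(s1 = list(onset = as.Date("2020-10-15"), rise_days = 14,
                         plateau_rate = 10,
                         fall_start = as.Date("2021-02-01"), fall_days = 14))
  season_config(sites = sites, station_map = c(s1 = "stn_thredbo"),
                envelopes = envs,
                glm_beta = c(tmax = 0, max_gust = 0, rainfall = 0, rh9am = 0),
                seed = seed)
}

# track CSV (location_id, timestamp, dx_px, dy_px) from simulated bearings,
# for a camera pointed north (azimuth 0): dx = sin(dir), dy = -cos(dir)
write_track_csv <- function(path, directions_by_loc,
                            base_time = "2021-02-18T20:35:00+11:00") {
  rows <- do.call(rbind, lapply(names(directions_by_loc), function(l) {
    d <- directions_by_loc[[l]]
    rad <- d * pi / 180
    t0 <- as.POSIXct(sub("\\+11:00$", "", base_time),
                     format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    data.frame(location_id = l,
               timestamp = paste0(format(t0 + seq_along(d) * 5,
                                         "%Y-%m-%dT%H:%M:%S"), "+11:00"),
               dx_px = sin(rad) * 10, dy_px = -cos(rad) * 10,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  path
}
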