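test_that("detection CSV parses fields, zones and missing values", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "site_id,timestamp,score,wingbeat_snr,wingbeat_freq,track_dx,track_dy,source",
    "a,2021-02-18T20:30:00+11:00,0.95,12,44,,,still",
    "a,2021-02-18T20:40:00+11:00,0.85,8,,,,still",
    "b,2021-02-18T21:00:00+10:30,0.99,3,60,4,-3,video"), p)
  d <- read_detections(p, "csv")
  expect_equal(nrow(d), 3)
  # +11:00 local 20:30 is 09:30 UTC
  expect_equal(format(d$timestamp[1], "%H:%M", tz = "UTC"), "09:30")
  expect_equal(d$utc_offset_hours, c(11, 11, 10.5))
  expect_true(is.na(d$wingbeat_freq[2]))   # empty stays missing, not zero
  expect_false(is.na(d$wingbeat_freq[1]))
  expect_equal(d$track_dx[3], 4)
})

test_that("malformed rows are rejected with row context", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "site_id,timestamp,score,wingbeat_snr,wingbeat_freq,track_dx,track_dy,source",
    "a,2021-02-18T20:30:00,0.95,12,44,,,still"), p)   # no UTC offset
  expect_error(read_detections(p, "csv"), "row 1")
  writeLines(c(
    "site_id,timestamp,score,wingbeat_snr,wingbeat_freq,track_dx,track_dy,source",
    "a,2021-02-18T20:30:00+11:00,bad,12,44,,,still"), p)
  expect_error(read_detections(p, "csv"), "score")
  writeLines(c(
    "site_id,timestamp,score,wingbeat_snr,wingbeat_freq,track_dx,track_dy,source",
    "a,2021-02-18T20:30:00+11:00,0.9,12,44,5,,still"), p)  # dx without dy
  expect_error(read_detections(p, "csv"), "track_dx/track_dy")
})

test_that("annotation JSON dialect extracts per-region records", {
  p <- withr::local_tempfile(fileext = ".json")
  ann <- list(
    img1 = list(
      file_attributes = list(site_id = "a",
                             timestamp = "2021-02-18T20:30:00+11:00"),
      regions = list(
        list(region_attributes = list(score = 0.9, snr = 10, wbf = 45)),
        list(region_attributes = list(score = 0.7, snr = 5)))))
  jsonlite::write_json(ann, p, auto_unbox = TRUE)
  d <- read_detections(p, "annotation_json")
  expect_equal(nrow(d), 2)
  expect_equal(d$score, c(0.9, 0.7))
  expect_true(is.na(d$wingbeat_freq[2]))
})

test_that("quality filters implement the closed-interval screen", {
  thr <- filter_thresholds()
  d <- make_detections("a", rep("2021-01-01 10:00:00", 6),
                       score = c(0.79, 0.80, 0.9, 0.9, 0.9, 0.9),
                       snr = c(10, 10, 10, 0.99, 10, NA),
                       freq = c(40, 40, 26.9, 40, 27.0, 40))
  kept <- apply_quality_filters(d, thr)
  # row1: score 0.79 < 0.8 out; row2: retained (0.8 kept exactly)
  # row3: freq 26.9 out; row4: SNR below 1 out; row5: freq 27.0 retained
  # row6: missing SNR out
  expect_equal(nrow(kept), 2)
  expect_equal(kept$score, c(0.80, 0.9))
  expect_equal(kept$wingbeat_freq, c(40, 27))
})

test_that("filtering matches brute-force per-record evaluation and is idempotent", {
  cfg <- small_season_config(seed = 11,
                             qc_fail = c(score = 0.3, snr = 0.2, freq = 0.25))
  sim <- simulate_season(cfg)
  d <- sim$detections[seq_len(min(500, nrow(sim$detections))), ]
  thr <- filter_thresholds()
  kept <- apply_quality_filters(d, thr)
  brute <- vapply(seq_len(nrow(d)), function(i) {
    r <- d[i, ]
    isTRUE(r$score >= 0.8) &&
      !is.na(r$wingbeat_snr) && r$wingbeat_snr >= 1 && r$wingbeat_snr <= 50 &&
      !is.na(r$wingbeat_freq) && r$wingbeat_freq >= 27 && r$wingbeat_freq <= 78
  }, TRUE)
  expect_equal(kept$timestamp, d$timestamp[brute])
  expect_equal(kept$score, d$score[brute])
  expect_identical(apply_quality_filters(kept, thr), kept)
  # generator labels agree with the filter
  expect_equal(nrow(kept), sum(d$passes_qc))
})

test_that("evening counts honour half-open windows and drop zero exposure", {
  w <- make_window("a", "2021-01-01",
                   "2021-01-01 09:00:00", "2021-01-01 10:00:00")
  caps <- make_detections("a", sprintf("2021-01-01 09:%02d:00", seq(0, 55, 5)))
  # no detections: count 0, exposure 12
  ec <- evening_counts(make_detections("a", character(0)), caps, w)
  expect_equal(ec$count, 0L)
  expect_equal(ec$exposure, 12L)
  # a detection exactly at window_end belongs to no window
  det <- make_detections("a", c("2021-01-01 09:30:00", "2021-01-01 10:00:00"))
  expect_warning(ec <- evening_counts(det, caps, w), "outside all")
  expect_equal(ec$count, 1L)
  # zero-exposure evening omitted, not zero-filled
  w2 <- rbind(w, make_window("a", "2021-01-02",
                             "2021-01-02 09:00:00", "2021-01-02 10:00:00"))
  ec2 <- suppressWarnings(evening_counts(det, caps, w2))
  expect_equal(nrow(ec2), 1)
  expect_equal(as.character(ec2$evening_date), "2021-01-01")
})

test_that("counts are order-invariant and bounded by filtered detections", {
  cfg <- small_season_config(seed = 3)
  sim <- simulate_season(cfg)
  d <- apply_quality_filters(sim$detections)
  ec1 <- evening_counts(d, sim$captures, sim$solar)
  perm <- sample(nrow(d))
  ec2 <- evening_counts(d[perm, ], sim$captures, sim$solar)
  expect_equal(ec1, ec2)
  expect_lte(sum(ec1$count), nrow(d))
})

test_that("simulated season round-trips through write and read", {
  sim <- simulate_season(small_season_config(seed = 5))
  dir <- withr::local_tempdir()
  paths <- write_season(sim, dir)
  d <- read_detections(paths["detections"], "csv")
  n <- nrow(sim$detections)
  expect_equal(nrow(d), n)
  expect_equal(as.numeric(d$timestamp), as.numeric(sim$detections$timestamp),
               tolerance = 1e-6)
  expect_equal(d$score, sim$detections$score, tolerance = 1e-12)
  expect_equal(d$wingbeat_freq, sim$detections$wingbeat_freq, tolerance = 1e-12)
  caps <- read_capture_log(paths["captures"])
  expect_equal(nrow(caps), nrow(sim$captures))
  wx <- read_weather(paths["weather"])
  expect_equal(nrow(wx), nrow(sim$weather))
})
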