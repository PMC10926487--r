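eight_day <- function() {
  list(dates = as.Date("2020-11-01") + 0:7,
       rate = c(0, 0.1, 0.3, 0.2, 0.5, 0.4, 0.1, 0))
}

test_that("per-evening rate is count over exposure, gaps stay absent", {
  ev <- data.frame(site_id = "a", evening_date = as.Date("2021-01-01") + c(0, 2),
                   count = c(6, 0), exposure = c(12, 10))
  r <- per_evening_rate(ev)
  expect_equal(r$rate, c(0.5, 0))
  expect_equal(nrow(r), 2)   # the missing middle evening is not zero-filled
})

test_that("cumulative-maximum curves match the hand-computed series", {
  s <- eight_day()
  ph <- build_phenology(s$dates, s$rate)
  expect_equal(ph$arrival$level, c(0, 0.1, 0.3, 0.3, 0.5))
  expect_equal(ph$peak_date, s$dates[5])
  expect_equal(ph$peak_rate, 0.5)
  expect_equal(ph$departure$level, c(0.5, 0.4, 0.1, 0))
  sm <- median_dates(ph)
  expect_equal(sm$half_level, 0.25)
  expect_equal(sm$A_half, s$dates[3])
  expect_equal(sm$D_half, s$dates[6])
})

test_that("degenerate and tied seasons follow the stated conventions", {
  d <- as.Date("2021-01-01") + 0:4
  # monotone increasing: arrival equals rates, departure starts at the peak
  ph <- build_phenology(d, c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(ph$arrival$level, c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(nrow(ph$departure), 1)
  # constant rates: earliest date takes the peak (shortest arrival phase)
  phc <- build_phenology(d, rep(0.3, 5))
  expect_equal(phc$peak_date, d[1])
  expect_equal(phc$arrival$level, 0.3)
  # single-day spike
  phs <- build_phenology(d, c(0, 0, 0.4, 0, 0))
  sms <- median_dates(phs)
  expect_equal(sms$A_half, d[3])
  expect_equal(sms$D_half, d[3])
  # all-zero season: explicit no-occupancy result
  smz <- median_dates(build_phenology(d, rep(0, 5)))
  expect_false(smz$occupied)
  expect_true(is.na(smz$A_half))
})

test_that("median dates are invariant to rate scaling and sub-peak insertions", {
  s <- eight_day()
  ph <- median_dates(build_phenology(s$dates, s$rate))
  ph2 <- median_dates(build_phenology(s$dates, s$rate * 2))
  expect_equal(ph2$half_level, 2 * ph$half_level)
  expect_equal(ph2$A_half, ph$A_half)
  expect_equal(ph2$D_half, ph$D_half)
  # bridging a camera-outage gap with a below-running-max evening changes
  # neither the other curve values nor the median dates
  gap_dates <- s$dates[-4]; gap_rate <- s$rate[-4]
  sm_gap <- median_dates(build_phenology(gap_dates, gap_rate))
  ph_ins <- build_phenology(s$dates, c(s$rate[1:3], 0.05, s$rate[5:8]))
  sm_ins <- median_dates(ph_ins)
  expect_equal(sm_ins$A_half, sm_gap$A_half)
  expect_equal(sm_ins$D_half, sm_gap$D_half)
  expect_equal(sm_ins$peak_rate, sm_gap$peak_rate)
  ph_gap <- build_phenology(gap_dates, gap_rate)
  expect_equal(ph_ins$arrival$level[-4], ph_gap$arrival$level)
})

test_that("arrival curve equals the brute-force prefix maximum everywhere", {
  for (s in 1:5) {
    set.seed(400 + s)
    n <- 30
    dates <- as.Date("2020-10-01") + sort(sample(0:60, n))
    rate <- pmax(rnorm(n, 1, 0.8), 0)
    ph <- build_phenology(dates, rate)
    peak_i <- which.max(rate)
    brute <- vapply(seq_len(peak_i), function(i) max(rate[1:i]), 0)
    expect_equal(ph$arrival$level, brute)
    brute_dep <- vapply(peak_i:n, function(i) max(rate[i:n]), 0)
    expect_equal(ph$departure$level, brute_dep)
    expect_true(all(diff(ph$arrival$level) >= 0))
    expect_true(all(diff(ph$departure$level) <= 0))
  }
})

test_that("phenology temperatures project the 3-day maxima to site elevation", {
  wx <- data.frame(station_id = "s", date = as.Date("2020-11-25") + 0:70,
                   tmax = 17.3)
  s8 <- eight_day()
  sm <- median_dates(build_phenology(as.Date("2020-11-26") + 0:7, s8$rate))
  pt <- phenology_temperatures(sm, wx, station_elevation = 2005,
                               to_elevation = 2152)
  expect_equal(round(pt$tmax_3day, 1), c(16.0, 16.0))
  # projecting to the station's own elevation changes nothing
  pt0 <- phenology_temperatures(sm, wx, station_elevation = 2005)
  expect_equal(pt0$tmax_3day, c(17.3, 17.3))
})

test_that("ledger rates flow through the pipeline unchanged", {
  sim <- simulate_season(small_season_config(seed = 1))
  counts <- evening_counts(apply_quality_filters(sim$detections),
                           sim$captures, sim$solar)
  r <- per_evening_rate(counts)
  tr <- sim$truth
  m <- match(paste(r$site_id, r$date), paste(tr$site_id, tr$date))
  expect_false(anyNA(m))
  expect_equal(r$rate, tr$rate[m])
})
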