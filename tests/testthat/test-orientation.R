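test_that("track directions map image displacements to compass bearings", {
  expect_equal(track_direction(0, -5, 30), 30)     # up the frame = azimuth
  expect_equal(track_direction(5, 0, 0), 90)       # frame-right = +90
  expect_equal(track_direction(3, 3, 45), 180)
  expect_error(track_direction(0, 0, 10), "zero displacement")
  # adding 360 to the azimuth changes nothing
  expect_equal(track_direction(2, -1, 390), track_direction(2, -1, 30))
})

test_that("circular SD follows the Bessel-ratio formula and its limits", {
  expect_equal(circular_sd_from_kappa(2), 48.6, tolerance = 0.05)
  expect_lt(circular_sd_from_kappa(100), 6)
  expect_true(is.infinite(circular_sd_from_kappa(0)))
  expect_true(all(diff(circular_sd_from_kappa(c(0.5, 1, 2, 4, 8))) < 0))
})

test_that("Moore test rejects perfect concentration and respects seeds", {
  d <- rep(123.4, 50)
  t1 <- moore_rayleigh_test(d, mc_reps = 10000, seed = 3)
  expect_lt(t1$p_value, 0.001)
  t2 <- moore_rayleigh_test(d, mc_reps = 10000, seed = 3)
  expect_identical(t1$p_value, t2$p_value)   # deterministic under the seed
  expect_error(moore_rayleigh_test(d[1:4]), "at least 5")
  # concentrated von Mises sample is detected
  set.seed(88)
  vm <- wrap360(rvonmises(100, pi / 3, 2) * 180 / pi)
  expect_lt(moore_rayleigh_test(vm, mc_reps = 999, seed = 4)$p_value, 0.05)
  # magnitudes weight the statistic: large-magnitude aligned tracks dominate
  set.seed(89)
  dirs <- c(rep(90, 30), runif(70, 0, 360))
  mags <- c(rlnorm(30, 3), rlnorm(70, 0))
  expect_lt(moore_rayleigh_test(dirs, mags, mc_reps = 999, seed = 5)$p_value,
            0.05)
})

test_that("MWW test sees identical samples as indistinguishable, different means as distinct", {
  set.seed(21)
  a <- wrap360(rvonmises(50, 0, 2) * 180 / pi)
  expect_warning(t0 <- mww_test(a, a, seed = 2), "tied")
  expect_lt(t0$statistic, 0.05)
  expect_gt(t0$p_value, 0.9)
  b <- wrap360(rvonmises(200, pi / 2, 2) * 180 / pi)
  a2 <- wrap360(rvonmises(200, 0, 2) * 180 / pi)
  tt <- mww_test(a2, b)
  expect_lt(tt$p_value, 0.001)
  # symmetric in its arguments
  expect_equal(mww_test(a2, b)$statistic, mww_test(b, a2)$statistic)
  expect_error(mww_test(a2[1:5], b), "permutation")
  tp <- mww_test(a2[1:8], b[1:8], method = "permutation", perm_reps = 499,
                 seed = 9)
  expect_true(tp$p_value >= 0 && tp$p_value <= 1)
})

test_that("orientation family selection recovers generating structure", {
  u <- simulate_directions(direction_config(model_id = "uniform", n = 1000,
                                            seed = 3))[[1]]
  fu <- fit_orientation_models(u$direction)
  expect_equal(fu$best, "uniform")
  vm <- simulate_directions(direction_config(model_id = "unimodal", mu1 = 45,
                                             kappa1 = 8, n = 1000,
                                             seed = 4))[[1]]
  fv <- fit_orientation_models(vm$direction,
                               models = c("uniform", "unimodal",
                                          "bimodal_shared_free"))
  expect_equal(fv$best, "unimodal")
  expect_lt(abs(wrap180(fv$fits$unimodal$mu1 - 45)), 3)
  # AIC identity and ranking order
  rk <- fv$ranking
  expect_equal(rk$aic, 2 * rk$n_params - 2 * rk$log_likelihood)
  expect_true(!is.unsorted(rk$aic))
})

test_that("angle wrap invariance: adding 360 degrees changes nothing", {
  set.seed(31)
  d <- runif(200, 0, 360)
  f1 <- fit_orientation_models(d, models = c("uniform", "unimodal"))
  f2 <- fit_orientation_models(d + 360, models = c("uniform", "unimodal"))
  expect_equal(f1$ranking$log_likelihood, f2$ranking$log_likelihood,
               tolerance = 1e-6)
  m1 <- moore_rayleigh_test(d, mc_reps = 499, seed = 1)
  m2 <- moore_rayleigh_test(d + 360, mc_reps = 499, seed = 1)
  expect_equal(m1$statistic, m2$statistic)
})

test_that("summit-relative directions use the forward azimuth", {
  # site due south of the summit: azimuth 0 (north); east-bound track = +90
  r <- summit_relative(90, -36.6, 148.263, -36.456, 148.263)
  expect_equal(r$relative, 90, tolerance = 0.01)
  expect_equal(r$summit_azimuth, 0, tolerance = 0.01)
  # a track along the azimuth itself is 0 = toward the summit
  summit <- c(-36.456, 148.263)
  for (b in c(0, 60, 135, 250)) {
    p <- geosphere::destPoint(c(summit[2], summit[1]), b, 800)  # lon/lat
    az <- summit_relative(0, p[2], p[1], summit[1], summit[2])$summit_azimuth
    expect_equal(wrap180(summit_relative(az, p[2], p[1], summit[1],
                                         summit[2])$relative), 0,
                 tolerance = 1e-6)
    # offsets from the azimuth are preserved at any site bearing
    expect_equal(summit_relative(wrap360(az + 30), p[2], p[1], summit[1],
                                 summit[2])$relative, 30, tolerance = 1e-6)
  }
  expect_error(summit_relative(10, -36.456, 148.263, -36.456, 148.263),
               "coincide")
})

test_that("time-elevation regression: exact fit, shift invariance, recovery", {
  t0 <- as.POSIXct("2021-02-18 10:00:00", tz = "UTC")
  elev <- c(2050, 2100, 2150, 2200)
  fit <- suppressWarnings(   # lm flags the essentially perfect fit
    time_elevation_regression(t0 - 5 * (elev - 2000), elev))
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$slope, -5, tolerance = 1e-8)
  set.seed(77)
  n <- 10000
  e <- runif(n, 2046, 2220)
  tt <- as.numeric(t0) - 5 * e + rnorm(n, 0, 600)
  f2 <- time_elevation_regression(tt, e)
  expect_lt(abs(f2$slope + 5), 0.5)
  expect_lt(f2$wald_p, 1e-10)
  f3 <- time_elevation_regression(tt, e + 500)   # translation invariance
  expect_equal(f3$slope, f2$slope, tolerance = 1e-10)
  expect_error(time_elevation_regression(tt[1:5], rep(2100, 5)), "distinct")
})

test_that("elevation delay matches the slope arithmetic", {
  expect_equal(round(delay_between_elevations(-5.59, 2220, 2046), 1), 16.2)
  expect_equal(delay_between_elevations(0, 2220, 2046), 0)
  expect_equal(delay_between_elevations(-6, 2100, 2000), 10)
})

test_that("activity binning conserves counts; lux interpolates log-linearly", {
  set.seed(55)
  times <- as.POSIXct("2021-02-18 09:30:00", tz = "UTC") +
    sort(runif(500, 0, 3600))
  b <- bin_activity(times, 2)
  expect_equal(sum(b$count), 500)
  # brute-force recount of one bin
  i <- 5
  expect_equal(b$count[i], sum(times >= b$bin_start[i] &
                                 times < b$bin_start[i] + 120))
  mt <- as.POSIXct("2021-02-18 09:00:00", tz = "UTC") + c(0, 600, 1200)
  lux <- c(106.5, 10, 0.0132)
  expect_equal(interpolate_lux(mt, lux, mt[2]), 10)
  expect_equal(interpolate_lux(mt, lux, mt[1] + 300), sqrt(106.5 * 10))
  mid <- interpolate_lux(as.POSIXct(c("2021-02-18 09:00:00",
                                      "2021-02-18 09:10:00"), tz = "UTC"),
                         c(10, 0.1),
                         as.POSIXct("2021-02-18 09:05:00", tz = "UTC"))
  expect_equal(mid, 1)
  expect_error(interpolate_lux(mt, lux, mt[3] + 60), "extrapolate")
})
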