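test_that("lapse adjustment is linear, antisymmetric and matches worked values", {
  # station at 2005 m projected to a 2152 m site
  expect_equal(round(lapse_adjust(17.3, 2005, 2152), 1), 16.0)
  expect_equal(round(lapse_adjust(20.7, 2005, 2152), 1), 19.4)
  expect_equal(lapse_adjust(12.3, 1800, 1800), 12.3)
  expect_equal(lapse_adjust(10, 1000, 2000), 0.9)
  # round trip recovers the input exactly
  x <- lapse_adjust(14.2, 1957, 2152)
  expect_equal(lapse_adjust(x, 2152, 1957), 14.2)
})

test_that("3-day average maxima skip missing days and report spread", {
  wx <- data.frame(station_id = "s", date = as.Date("2021-01-01") + 0:2,
                   tmax = c(10, 12, 14))
  r <- rolling_3day_avg_max(wx, as.Date("2021-01-03"))
  expect_equal(r$mean, 12)
  expect_equal(r$sd, 2)
  expect_equal(r$n_days, 3)
  r2 <- rolling_3day_avg_max(data.frame(date = as.Date("2021-01-01") + 0:2,
                                        tmax = c(9, 9, 9)),
                             as.Date("2021-01-03"))
  expect_equal(r2$sd, 0)
  wx$tmax[2] <- NA
  r3 <- rolling_3day_avg_max(wx, as.Date("2021-01-03"))
  expect_equal(r3$mean, 12)
  expect_equal(r3$n_days, 2)
  r4 <- rolling_3day_avg_max(wx, as.Date("2020-06-01"))
  expect_true(is.na(r4$mean))
  expect_equal(r4$n_days, 0)
})

test_that("covariate assembly derives columns, adjusts temperatures and drops gaps", {
  sim <- simulate_season(small_season_config(seed = 21))
  counts <- evening_counts(apply_quality_filters(sim$detections),
                           sim$captures, sim$solar)
  stations <- sim$stations[, c("station_id", "elevation_m")]
  tab <- assemble_covariates(counts, sim$weather, sim$sites, sim$solar,
                             c(s1 = "stn_thredbo"), stations)
  expect_equal(tab$temp_range, tab$tmax - tab$tmin)
  expect_true(all(attr(tab, "covariate_names") %in% names(tab)))
  expect_equal(attr(tab, "dropped"), 0)
  # lapse adjustment: site 2100 m vs station 1957 m
  i <- 1
  wrow <- sim$weather[sim$weather$station_id == "stn_thredbo" &
                        sim$weather$date == tab$evening_date[i], ]
  expect_equal(tab$tmax[i], lapse_adjust(wrow$tmax, 1957, 2100))
  # missing rainfall drops the row and logs it
  wx2 <- sim$weather
  wx2$rainfall_mm[wx2$date == tab$evening_date[1]] <- NA
  tab2 <- assemble_covariates(counts, wx2, sim$sites, sim$solar,
                              c(s1 = "stn_thredbo"), stations)
  expect_equal(nrow(tab2), nrow(tab) - 1)
  expect_equal(attr(tab2, "dropped"), 1)
  # unmapped site errors
  expect_error(assemble_covariates(counts, sim$weather, sim$sites, sim$solar,
                                   c(other = "stn_thredbo"), stations),
               "no station mapped")
})

test_that("greedy pruning reproduces the hand-traced removal", {
  set.seed(42)
  n <- 300
  A <- rnorm(n)
  B <- sqrt(0.6) * A + sqrt(0.4) * rnorm(n)   # corr^2(A,B) ~ 0.6
  C <- 0.3 * A + rnorm(n)                     # corr^2(A,C) ~ 0.1
  resp <- 0.6 * A + rnorm(n)                  # |corr| with A > with B
  tab <- data.frame(count = 1, exposure = 1, A = A, B = B, C = C)
  stopifnot(cor(A, B)^2 > 0.3, cor(A, C)^2 < 0.3, cor(B, C)^2 < 0.3,
            abs(cor(A, resp)) > abs(cor(B, resp)))
  pr <- prune_collinear(tab, response = resp, covariate_names = c("A", "B", "C"))
  expect_equal(pr$retained, c("A", "C"))
  expect_equal(pr$removed$removed, "B")
  expect_equal(pr$removed$reason, "collinear pair")
  expect_gt(pr$removed$r_squared, 0.3)
})

test_that("pruning handles no-op, duplicates and constants", {
  set.seed(7)
  n <- 100
  tab <- data.frame(count = rpois(n, 3), exposure = 10,
                    X = rnorm(n), Y = rnorm(n))
  pr <- prune_collinear(tab, covariate_names = c("X", "Y"))
  expect_equal(pr$retained, c("X", "Y"))   # all pairwise R2 below threshold
  expect_equal(nrow(pr$removed), 0)
  tab$Xdup <- tab$X                         # perfect collinearity
  pr2 <- prune_collinear(tab, covariate_names = c("X", "Xdup", "Y"))
  expect_equal(sum(c("X", "Xdup") %in% pr2$retained), 1)
  tab$Kc <- 5                               # constant: removed first
  pr3 <- prune_collinear(tab, covariate_names = c("X", "Y", "Kc"))
  expect_false("Kc" %in% pr3$retained)
  expect_equal(pr3$removed$reason[1], "zero variance")
})

test_that("no retained pair exceeds the threshold, regardless of input order", {
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 150
    base <- matrix(rnorm(n * 3), n)
    X <- cbind(base,
               base[, 1] * 0.8 + rnorm(n) * 0.4,
               base[, 2] * 0.9 + rnorm(n) * 0.3,
               base[, 1] - base[, 2] + rnorm(n) * 0.5)
    colnames(X) <- paste0("v", 1:6)
    tab <- data.frame(count = rpois(n, 5), exposure = 10, X)
    pr <- prune_collinear(tab, covariate_names = colnames(X))
    cm <- cor(as.matrix(tab[, pr$retained]))^2
    diag(cm) <- 0
    expect_lte(max(cm), 0.3)   # brute-force scan of the retained set
    # order invariance (no exact ties here)
    pr_rev <- prune_collinear(tab, covariate_names = rev(colnames(X)))
    expect_setequal(pr$retained, pr_rev$retained)
  }
})
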