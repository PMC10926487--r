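#' @title Flight-track orientation statistics
#' @description Conversion of tracked image displacements to compass
#'   bearings, circular uniformity and homogeneity tests, von Mises
#'   orientation-model fitting with AIC selection, summit-relative
#'   directions, and the time-by-elevation regression.
#' @name orientation
NULL

#' Wrap angles into \[0, 360)
#' @param deg Angles in degrees.
#' @return Wrapped angles.
#' @export
wrap360 <- function(deg) deg %% 360

#' Wrap angles into (-180, 180]
#' @param deg Angles in degrees.
#' @return Wrapped signed angles.
#' @export
wrap180 <- function(deg) {
  w <- deg %% 360
  ifelse(w > 180, w - 360, w)
}

#' Compass bearing of a tracked displacement
#'
#' Image coordinates have x rightward and y downward; "up the frame"
#' (dy < 0) points along the camera's compass azimuth. The track bearing
#' is therefore `camera_azimuth + atan2(dx, -dy)`, wrapped to \[0, 360).
#'
#' @param dx,dy Net displacement in image pixels.
#' @param camera_azimuth Compass bearing (degrees) of the image's top
#'   edge direction.
#' @return Compass bearing(s) in degrees, \[0, 360).
#' @export
track_direction <- function(dx, dy, camera_azimuth) {
  if (any(dx == 0 & dy == 0)) stop("zero displacement has no direction")
  wrap360(camera_azimuth + atan2(dx, -dy) * 180 / pi)
}

# von Mises density, stable for large kappa (expon.scaled Bessel)
dvonmises <- function(theta, mu, kappa) {
  exp(kappa * (cos(theta - mu) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Sample from a von Mises distribution
#'
#' Best & Fisher (1979) rejection sampler; driven entirely by `runif`,
#' so draws are reproducible under `set.seed`.
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration (0 gives the uniform circle).
#' @return Angles in radians, wrapped to \[0, 2*pi).
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  out %% (2 * pi)
}

#' Circular standard deviation from a von Mises concentration
#'
#' `sqrt(-2 log R(kappa))` in degrees, where `R(kappa) = I1(kappa) /
#' I0(kappa)` is the mean resultant length of the von Mises
#' distribution. `kappa = 0` gives an infinite SD (uniform).
#'
#' @param kappa Concentration parameter(s), >= 0.
#' @return Circular SD in degrees (`Inf` at kappa = 0).
#' @export
circular_sd_from_kappa <- function(kappa) {
  stopifnot(all(kappa >= 0))
  R <- ifelse(kappa == 0, 0,
              besselI(kappa, 1, expon.scaled = TRUE) /
                besselI(kappa, 0, expon.scaled = TRUE))
  ifelse(R == 0, Inf, sqrt(-2 * log(R)) * 180 / pi)
}

# Moore's rank-weighted resultant: directions theta (radians), magnitude
# ranks r (average ranks for ties); R* = |sum r_i e^{i theta_i}| / n^{3/2}
.moore_stat <- function(theta, ranks) {
  n <- length(theta)
  sqrt(sum(ranks * cos(theta))^2 + sum(ranks * sin(theta))^2) / n^1.5
}

#' Moore's modified Rayleigh test of circular uniformity
#'
#' A magnitude-weighted Rayleigh test: track magnitudes are replaced by
#' their ranks (average ranks on ties) and the rank-weighted resultant
#' is compared with its null distribution under uniform directions,
#' estimated by seeded Monte-Carlo with the observed ranks held fixed.
#' With no magnitudes (all ranks tied) the statistic is proportional to
#' the classical Rayleigh resultant.
#'
#' @param directions Compass bearings in degrees.
#' @param magnitudes Optional track magnitudes (lengths); `NULL` means
#'   unit weights.
#' @param mc_reps Monte-Carlo repetitions for the null (default 10000).
#' @param seed Integer seed for the null resampling.
#' @return List of class `circ_test`: `statistic`, `p_value`, `method`,
#'   `n`, `mc_reps`.
#' @export
moore_rayleigh_test <- function(directions, magnitudes = NULL,
                                mc_reps = 10000, seed = 1) {
  n <- length(directions)
  if (n < 5) stop("need at least 5 directions")
  theta <- directions * pi / 180
  ranks <- if (is.null(magnitudes)) rep((n + 1) / 2, n) else {
    stopifnot(length(magnitudes) == n, all(magnitudes >= 0))
    rank(magnitudes, ties.method = "average")
  }
  obs <- .moore_stat(theta, ranks)
  null <- moore_null_stats(ranks, mc_reps = mc_reps, seed = seed)
  p <- (1 + sum(null >= obs)) / (mc_reps + 1)
  structure(list(statistic = obs, p_value = p,
                 method = "Moore's modified Rayleigh (Monte-Carlo)",
                 n = n, mc_reps = mc_reps), class = "circ_test")
}

#' Null distribution of the Moore statistic
#'
#' Monte-Carlo draws of the rank-weighted resultant under uniform
#' directions with the magnitude ranks held fixed. Exposed so calibration
#' studies can reuse one null sample across many observed samples.
#'
#' @param ranks Magnitude ranks (fixed).
#' @param mc_reps Number of null draws.
#' @param seed Integer seed.
#' @return Numeric vector of `mc_reps` null statistics.
#' @export
moore_null_stats <- function(ranks, mc_reps = 10000, seed = 1) {
  n <- length(ranks)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  th <- matrix(stats::runif(n * mc_reps, 0, 2 * pi), nrow = n)
  sqrt(colSums(ranks * cos(th))^2 + colSums(ranks * sin(th))^2) / n^1.5
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.circ_test <- function(x, ...) {
  cat(sprintf("<circ_test> %s\n  statistic %.4g, p = %.4g, n = %d\n",
              x$method, x$statistic, x$p_value, x$n))
  invisible(x)
}

#' Mardia-Watson-Wheeler two-sample test
#'
#' Uniform-scores test that two circular samples share one distribution.
#' Pooled directions are ranked on the circle and mapped to uniform
#' scores `beta = 2 pi rank / N`; the statistic `W = 2 * sum_g (C_g^2 +
#' S_g^2) / n_g` is referred to a chi-square with 2 df (large-sample
#' mode) or to a seeded permutation null. Ties across samples are broken
#' by a tiny seeded jitter, with a warning.
#'
#' @param a,b Compass bearings (degrees) of the two samples.
#' @param method `"chisq"` (default, requires n >= 10 per sample) or
#'   `"permutation"`.
#' @param perm_reps Permutation repetitions.
#' @param seed Seed for jitter/permutation.
#' @return `circ_test` list (statistic `W`, `p_value`, `n` = total).
#' @export
mww_test <- function(a, b, method = c("chisq", "permutation"),
                     perm_reps = 10000, seed = 1) {
  method <- match.arg(method)
  na <- length(a); nb <- length(b); N <- na + nb
  if (method == "chisq" && (na < 10 || nb < 10))
    stop("n < 10 per sample: chi-square approximation unreliable; ",
         "use method = 'permutation'")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  x <- wrap360(c(a, b))
  if (anyDuplicated(x)) {
    warning("tied directions across samples; breaking ties with seeded jitter")
    x <- x + stats::runif(N, -1e-6, 1e-6)
  }
  g <- rep(c(1L, 2L), c(na, nb))
  Wstat <- function(groups) {
    beta <- 2 * pi * rank(x) / N
    w <- 0
    for (k in 1:2) {
      bk <- beta[groups == k]
      w <- w + (sum(cos(bk))^2 + sum(sin(bk))^2) / length(bk)
    }
    2 * w
  }
  W <- Wstat(g)
  p <- if (method == "chisq") {
    stats::pchisq(W, df = 2, lower.tail = FALSE)
  } else {
    null <- replicate(perm_reps, Wstat(sample(g)))
    (1 + sum(null >= W)) / (perm_reps + 1)
  }
  structure(list(statistic = W, p_value = p,
                 method = paste0("Mardia-Watson-Wheeler (", method, ")"),
                 n = N, mc_reps = if (method == "chisq") NA_integer_ else perm_reps),
            class = "circ_test")
}

# ---- orientation model family ------------------------------------------

# Mixture of two von Mises components plus the degenerate cases. The
# family follows the classical orientation-model catalogue: uniform;
# unimodal; unimodal contaminated with a uniform component; axial
# bimodal (modes 180 deg apart, shared concentration); and general
# bimodal with shared or free concentrations, each with the mixing
# weight fixed at 1/2 or free.
.orientation_models <- function() {
  list(
    uniform = list(npar = 0L),
    unimodal = list(npar = 2L),
    unimodal_uniform = list(npar = 3L),
    axial_fixed = list(npar = 2L),
    axial_free = list(npar = 3L),
    bimodal_shared_fixed = list(npar = 3L),
    bimodal_shared_free = list(npar = 4L),
    bimodal_free_fixed = list(npar = 4L),
    bimodal_free_free = list(npar = 5L))
}

.mix_loglik <- function(theta, mu1, kappa1, mu2, kappa2, lambda,
                        uniform2 = FALSE) {
  d1 <- dvonmises(theta, mu1, kappa1)
  d2 <- if (uniform2) 1 / (2 * pi) else dvonmises(theta, mu2, kappa2)
  sum(log(lambda * d1 + (1 - lambda) * d2))
}

#' Fit the orientation-model family and rank by AIC
#'
#' Fits each member of a von Mises orientation-model family to a sample
#' of compass bearings by maximum likelihood (multi-start bounded
#' optimisation over mean directions on a coarse angular grid) and ranks
#' the members by AIC. The family: `uniform`; `unimodal` (mu, kappa);
#' `unimodal_uniform` (unimodal plus uniform contamination, weight
#' free); `axial_fixed`/`axial_free` (modes mu and mu+180 sharing kappa,
#' weight 1/2 or free); `bimodal_shared_*` (independent means, shared
#' kappa); `bimodal_free_*` (independent means and kappas); `_fixed` /
#' `_free` fixing the weight at 1/2 or freeing it.
#'
#' In a bimodal fit the reported first component is the one with the
#' larger weight (ties: the larger kappa).
#'
#' @param directions Compass bearings, degrees.
#' @param models Character vector of family members to fit (default
#'   all).
#' @param mu_grid_step Starting-grid spacing for mean directions,
#'   degrees.
#' @param kappa_max Upper bound on concentration.
#' @return Object of class `orientation_fits`: data frame `ranking`
#'   (model, log_likelihood, n_params, aic, converged) sorted by AIC,
#'   and `fits`, a named list with each member's parameters in degrees
#'   (`mu1`, `kappa1`, `mu2`, `kappa2`, `lambda`).
#' @export
fit_orientation_models <- function(directions, models = names(.orientation_models()),
                                   mu_grid_step = 45, kappa_max = 500) {
  n <- length(directions)
  if (n < 10) stop("need at least 10 directions")
  theta <- wrap360(directions) * pi / 180
  fam <- .orientation_models()
  stopifnot(all(models %in% names(fam)))
  mu_starts <- seq(0, 2 * pi - 1e-9, by = mu_grid_step * pi / 180)
  # moment estimates for informed starts
  C <- mean(cos(theta)); S <- mean(sin(theta))
  mu_hat <- atan2(S, C) %% (2 * pi)
  kap_starts <- c(0.5, 2, 8)

  optimise_model <- function(par0, lower, upper, fn) {
    best <- NULL
    for (i in seq_len(nrow(par0))) {
      res <- tryCatch(
        stats::optim(pmin(pmax(par0[i, ], lower), upper), fn,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(fnscale = -1, maxit = 500)),
        error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$value > best$value)) best <- res
    }
    if (!is.null(best)) best$par <- unname(best$par)
    best
  }

  fits <- list()
  for (m in models) {
    fit <- switch(m,
      uniform = list(loglik = -n * log(2 * pi), pars = c(), conv = TRUE),
      unimodal = {
        fn <- function(p) .mix_loglik(theta, p[1], p[2], 0, 0, 1, uniform2 = TRUE)
        par0 <- as.matrix(expand.grid(mu = c(mu_starts, mu_hat), k = kap_starts))
        b <- optimise_model(par0, c(-pi, 1e-8), c(3 * pi, kappa_max), fn)
        list(loglik = b$value,
             pars = c(mu1 = b$par[1] %% (2 * pi), kappa1 = b$par[2]),
             conv = b$convergence == 0)
      },
      unimodal_uniform = {
        fn <- function(p) .mix_loglik(theta, p[1], p[2], 0, 0, p[3], uniform2 = TRUE)
        par0 <- as.matrix(expand.grid(mu = c(mu_starts, mu_hat), k = kap_starts,
                                      l = c(0.5, 0.9)))
        b <- optimise_model(par0, c(-pi, 1e-8, 1e-3), c(3 * pi, kappa_max, 1), fn)
        list(loglik = b$value,
             pars = c(mu1 = b$par[1] %% (2 * pi), kappa1 = b$par[2],
                      lambda = b$par[3]),
             conv = b$convergence == 0)
      },
      axial_fixed = {
        fn <- function(p) .mix_loglik(theta, p[1], p[2], p[1] + pi, p[2], 0.5)
        par0 <- as.matrix(expand.grid(mu = c(mu_starts, mu_hat), k = kap_starts))
        b <- optimise_model(par0, c(-pi, 1e-8), c(3 * pi, kappa_max), fn)
        list(loglik = b$value,
             pars = c(mu1 = b$par[1] %% (2 * pi), kappa1 = b$par[2],
                      mu2 = (b$par[1] + pi) %% (2 * pi), kappa2 = b$par[2],
                      lambda = 0.5),
             conv = b$convergence == 0)
      },
      axial_free = {
        fn <- function(p) .mix_loglik(theta, p[1], p[2], p[1] + pi, p[2], p[3])
        par0 <- as.matrix(expand.grid(mu = c(mu_starts, mu_hat), k = kap_starts,
                                      l = c(0.3, 0.5, 0.7)))
        b <- optimise_model(par0, c(-pi, 1e-8, 1e-3), c(3 * pi, kappa_max, 1 - 1e-3), fn)
        list(loglik = b$value,
             pars = c(mu1 = b$par[1] %% (2 * pi), kappa1 = b$par[2],
                      mu2 = (b$par[1] + pi) %% (2 * pi), kappa2 = b$par[2],
                      lambda = b$par[3]),
             conv = b$convergence == 0)
      },
      bimodal_shared_fixed = ,
      bimodal_shared_free = ,
      bimodal_free_fixed = ,
      bimodal_free_free = {
        shared <- grepl("shared", m)
        lam_free <- grepl("free$", m)
        fn <- function(p) {
          k2 <- if (shared) p[3] else p[4]
          lam <- if (lam_free) p[length(p)] else 0.5
          .mix_loglik(theta, p[1], p[3], p[2], k2, lam)
        }
        mu_pairs <- expand.grid(mu1 = mu_starts, mu2 = mu_starts)
        mu_pairs <- mu_pairs[mu_pairs$mu1 < mu_pairs$mu2, ]
        par0 <- cbind(mu_pairs$mu1, mu_pairs$mu2, 2,
                      if (!shared) 2 else NULL,
                      if (lam_free) 0.5 else NULL)
        lower <- c(-pi, -pi, 1e-8, if (!shared) 1e-8, if (lam_free) 1e-3)
        upper <- c(3 * pi, 3 * pi, kappa_max, if (!shared) kappa_max,
                   if (lam_free) 1 - 1e-3)
        b <- optimise_model(par0, lower, upper, fn)
        k1 <- b$par[3]; k2 <- if (shared) b$par[3] else b$par[4]
        lam <- if (lam_free) b$par[length(b$par)] else 0.5
        list(loglik = b$value,
             pars = c(mu1 = b$par[1] %% (2 * pi), kappa1 = k1,
                      mu2 = b$par[2] %% (2 * pi), kappa2 = k2, lambda = lam),
             conv = b$convergence == 0)
      })
    fits[[m]] <- fit
  }
  ranking <- data.frame(
    model = names(fits),
    log_likelihood = vapply(fits, function(f) f$loglik, 0),
    n_params = vapply(names(fits), function(m) fam[[m]]$npar, 0L),
    converged = vapply(fits, function(f) isTRUE(f$conv), TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
  ranking$aic <- 2 * ranking$n_params - 2 * ranking$log_likelihood
  ranking <- ranking[ranking$converged, ]
  ranking <- ranking[order(ranking$aic), ]
  rownames(ranking) <- NULL
  # degrees out; first component = larger weight
  fits_deg <- lapply(fits, function(f) {
    p <- as.list(f$pars)
    for (nm in c("mu1", "mu2")) if (!is.null(p[[nm]])) p[[nm]] <- p[[nm]] * 180 / pi
    if (!is.null(p$lambda) && !is.null(p$mu2) && p$lambda < 0.5) {
      p <- list(mu1 = p$mu2, kappa1 = p$kappa2, mu2 = p$mu1,
                kappa2 = p$kappa1, lambda = 1 - p$lambda)
    }
    c(p, list(log_likelihood = f$loglik))
  })
  structure(list(ranking = ranking, fits = fits_deg,
                 best = ranking$model[1], n = n),
            class = "orientation_fits")
}

#' @export
print.orientation_fits <- function(x, ...) {
  cat(sprintf("<orientation_fits> n = %d, best by AIC: %s\n", x$n, x$best))
  print(x$ranking, digits = 5)
  invisible(x)
}

#' Directions relative to the azimuth of a summit
#'
#' Subtracts the great-circle forward azimuth from each site to the
#' summit from the track bearings, wrapping into (-180, 180]. A relative
#' direction of 0 means "straight toward the summit"; absolute values
#' above 90 deg mean motion away from it.
#'
#' @param directions Compass bearings, degrees.
#' @param site_lat,site_lon Site coordinates (degrees).
#' @param summit_lat,summit_lon Summit coordinates (degrees).
#' @return List: `relative` (degrees in (-180, 180]),
#'   `summit_azimuth` (degrees in \[0, 360)).
#' @export
summit_relative <- function(directions, site_lat, site_lon,
                            summit_lat, summit_lon) {
  if (isTRUE(all.equal(c(site_lat, site_lon), c(summit_lat, summit_lon))))
    stop("site and summit coincide: azimuth undefined")
  az <- wrap360(geosphere::bearing(c(site_lon, site_lat),
                                   c(summit_lon, summit_lat)))
  list(relative = wrap180(directions - az), summit_azimuth = az)
}

#' Linear regression of detection time on elevation
#'
#' Ordinary least squares of detection clock time (seconds) on site
#' elevation (metres), with the Wald test of zero slope. A negative
#' slope means detections occur earlier at higher elevations: activity
#' at a lower site lags by `-slope` seconds per metre of elevation
#' difference.
#'
#' @param times POSIXct detection times (or numeric seconds).
#' @param elevations Elevation (m) per detection.
#' @return List of class `time_elev_fit`: `slope` (s/m), `intercept`,
#'   `r_squared`, `wald_p`, `n`.
#' @export
time_elevation_regression <- function(times, elevations) {
  stopifnot(length(times) == length(elevations), length(times) >= 3)
  if (length(unique(elevations)) < 2)
    stop("need at least 2 distinct elevations")
  secs <- as.numeric(times)
  fit <- stats::lm(secs ~ elevations)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 wald_p = sm$coefficients[2, 4],
                 n = length(secs)), class = "time_elev_fit")
}

#' Detection delay implied by a time-elevation slope
#'
#' `slope * (elev_low - elev_high) / 60` minutes: how much later
#' detections occur at the lower of two elevations under the fitted
#' linear trend.
#'
#' @param slope Seconds per metre.
#' @param elev_high,elev_low Elevations (m).
#' @return Delay in minutes.
#' @export
delay_between_elevations <- function(slope, elev_high, elev_low) {
  slope * (elev_low - elev_high) / 60
}

#' Bin detection activity in time
#'
#' Counts detections per half-open time bin of the given width, from the
#' first bin containing `origin` (default: the minute floor of the
#' earliest detection).
#'
#' @param times POSIXct detection times.
#' @param bin_width_min Bin width in minutes (default 2).
#' @param origin Optional POSIXct start of the first bin.
#' @return Data frame `bin_start` (POSIXct), `count`.
#' @export
bin_activity <- function(times, bin_width_min = 2, origin = NULL) {
  stopifnot(length(times) >= 1)
  if (is.null(origin))
    origin <- as.POSIXct(floor(as.numeric(min(times)) / 60) * 60,
                         origin = "1970-01-01", tz = "UTC")
  w <- bin_width_min * 60
  idx <- floor(as.numeric(times - origin, units = "secs") / w)
  stopifnot(all(idx >= 0))
  tab <- table(factor(idx, levels = 0:max(idx)))
  data.frame(bin_start = origin + as.numeric(names(tab)) * w,
             count = as.integer(tab))
}

#' Log-linear interpolation of illuminance
#'
#' Sky illuminance falls roughly geometrically through twilight, so lux
#' is interpolated linearly on the log scale between bracketing
#' measurements: the midpoint of 10 lx and 0.1 lx is 1 lx.
#'
#' @param meas_times POSIXct measurement times, strictly increasing.
#' @param lux Illuminance measurements, strictly positive.
#' @param t Times at which to interpolate (must lie within the measured
#'   span; extrapolation is refused).
#' @return Interpolated lux at `t`.
#' @export
interpolate_lux <- function(meas_times, lux, t) {
  stopifnot(length(meas_times) == length(lux), all(lux > 0),
            !is.unsorted(as.numeric(meas_times), strictly = TRUE))
  tn <- as.numeric(t); mn <- as.numeric(meas_times)
  if (any(tn < mn[1] | tn > mn[length(mn)]))
    stop("time outside the measured illuminance span; refusing to extrapolate")
  exp(stats::approx(mn, log(lux), xout = tn)$y)
}
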