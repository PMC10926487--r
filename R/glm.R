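#' @title Evening-count Poisson regression
#' @description Maximum-likelihood Poisson regression of evening
#'   detection counts on abiotic covariates, with the per-evening image
#'   count as a multiplicative exposure (additive log offset), and
#'   standardized effect sizes with Wald confidence intervals.
#' @name abundance-glm
NULL

#' Fit the evening-count Poisson model with image-count exposure
#'
#' Fits `count ~ covariates` with a Poisson log link and
#' `offset(log(exposure))`, so coefficients act on the detection *rate*
#' per image. Wald 95% intervals accompany each coefficient. An optional
#' quasi-Poisson refit inflates standard errors by the estimated
#' dispersion without changing point estimates.
#'
#' @param table Covariate table (needs `count`, `exposure`, and the
#'   covariate columns).
#' @param covariate_names Covariates to enter jointly; default the
#'   table's `covariate_names` attribute. May be empty for an
#'   intercept-only fit.
#' @param quasi If TRUE, standard errors and CIs use the quasi-Poisson
#'   dispersion estimate.
#' @return Object of class `moth_glm`: list with `coefficients` (data
#'   frame: term, estimate, se, ci_lower, ci_upper), `log_likelihood`,
#'   `deviance`, `null_deviance`, `n_rows`, `converged`, `dispersion`,
#'   and the underlying `glm` fit in `$fit`.
#' @export
fit_poisson_exposure <- function(table, covariate_names =
                                   attr(table, "covariate_names"),
                                 quasi = FALSE) {
  if (is.null(covariate_names)) covariate_names <- character()
  stopifnot(all(table$exposure >= 1), all(table$count >= 0))
  if (nrow(table) <= length(covariate_names) + 1)
    stop("fewer rows than parameters")
  rhs <- if (length(covariate_names))
    paste(covariate_names, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("count ~", rhs))
  fit <- stats::glm(fml, family = stats::poisson(),
                    offset = log(exposure), data = table,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged)
    stop("Poisson fit did not converge after ", fit$iter, " iterations")
  disp <- 1
  if (quasi)
    disp <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  sm <- summary(fit)
  est <- sm$coefficients[, "Estimate"]
  se <- sm$coefficients[, "Std. Error"] * sqrt(disp)
  z <- stats::qnorm(0.975)
  coefs <- data.frame(term = rownames(sm$coefficients), estimate = est,
                      se = se, ci_lower = est - z * se,
                      ci_upper = est + z * se,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 deviance = fit$deviance,
                 null_deviance = fit$null.deviance,
                 n_rows = nrow(table), converged = fit$converged,
                 dispersion = disp, covariate_names = covariate_names,
                 fit = fit),
            class = "moth_glm")
}

#' @export
print.moth_glm <- function(x, ...) {
  cat(sprintf("<moth_glm> Poisson, offset log(exposure), n = %d\n", x$n_rows))
  cat(sprintf("  logLik %.2f, deviance %.2f (null %.2f), dispersion %.2f\n",
              x$log_likelihood, x$deviance, x$null_deviance, x$dispersion))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Standardized effect sizes with raw-unit confidence bounds
#'
#' The standardized effect of a covariate is its coefficient multiplied
#' by the covariate's sample SD over the fitted rows: the change in log
#' detection rate per one-SD increase. The confidence bounds reported in
#' raw units are the unscaled coefficient's Wald interval — the gradient
#' of the regression in that covariate's own dimension.
#'
#' @param fit A `moth_glm` from [fit_poisson_exposure()].
#' @param table The covariate table the model was fitted to.
#' @return Data frame: `covariate`, `estimate` (raw), `sd`,
#'   `std_effect`, `ci_lower_raw`, `ci_upper_raw`, `ci_lower_std`,
#'   `ci_upper_std`.
#' @export
scaled_effects <- function(fit, table) {
  stopifnot(inherits(fit, "moth_glm"), fit$converged)
  cn <- fit$covariate_names
  sds <- vapply(cn, function(nm) stats::sd(table[[nm]]), 0)
  if (any(sds == 0))
    stop("zero-variance covariate: ", cn[which(sds == 0)[1]])
  cf <- fit$coefficients
  i <- match(cn, cf$term)
  data.frame(covariate = cn,
             estimate = cf$estimate[i],
             sd = sds,
             std_effect = cf$estimate[i] * sds,
             ci_lower_raw = cf$ci_lower[i],
             ci_upper_raw = cf$ci_upper[i],
             ci_lower_std = cf$ci_lower[i] * sds,
             ci_upper_std = cf$ci_upper[i] * sds,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Serialize a fit report
#'
#' Writes coefficients, scaled effects and the pruning removal log as a
#' JSON report plus a plain-text summary.
#'
#' @param fit `moth_glm` object.
#' @param effects Data frame from [scaled_effects()].
#' @param removal_log Removal log from [prune_collinear()].
#' @param path Output path for the JSON (text summary goes to
#'   `sub(".json", ".txt", path)`).
#' @return Invisibly, the report list.
#' @export
write_fit_report <- function(fit, effects, removal_log, path) {
  report <- list(model = "poisson_exposure",
                 n_rows = fit$n_rows,
                 log_likelihood = fit$log_likelihood,
                 deviance = fit$deviance,
                 null_deviance = fit$null_deviance,
                 dispersion = fit$dispersion,
                 coefficients = fit$coefficients,
                 scaled_effects = effects,
                 pruning = removal_log)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  txt <- sub("\\.json$", ".txt", path)
  con <- file(txt, "w")
  sink(con); print(fit); print(effects, digits = 4); sink()
  close(con)
  invisible(report)
}
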