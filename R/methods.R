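#' @export
print.foce_fit <- function(x, ...) {
  cat("FOCE-I fit of the one-compartment infusion model\n")
  cat(sprintf("  %d subjects, %d observations; OFV %.3f (AIC %.3f, BIC %.3f)\n",
              x$n_subjects, x$n_obs, x$ofv, x$aic, x$bic))
  if (!x$converged) cat("  WARNING: outer optimiser did not converge;",
                        "best-so-far estimates reported\n")
  print(x$model)
  invisible(x)
}

#' Summarise a FOCE fit
#'
#' Produces a parameter table in the customary population-PK report layout:
#' point estimate, percent relative standard error, and shrinkage for the
#' variability terms (between-subject variability as %CV, proportional error
#' as %CV).
#'
#' @param object A [foce_fit()] object.
#' @param ... Unused.
#' @return An object of class `summary.foce_fit` holding the table.
#' @export
summary.foce_fit <- function(object, ...) {
  co <- object$coefficients
  rse <- object$rse
  n <- length(co)
  tab <- data.frame(
    parameter = names(co),
    estimate = unname(co),
    rse_pct = unname(rse),
    shrinkage_pct = NA_real_,
    stringsAsFactors = FALSE)
  tab$estimate[tab$parameter == "omega_cl"] <-
    omega_to_cv(co[["omega_cl"]])
  tab$parameter[tab$parameter == "omega_cl"] <- "bsv_cl_pct_cv"
  tab$estimate[tab$parameter == "sigma_prop"] <- 100 * co[["sigma_prop"]]
  tab$parameter[tab$parameter == "sigma_prop"] <- "prop_error_pct_cv"
  tab$shrinkage_pct[tab$parameter == "bsv_cl_pct_cv"] <- object$eta_shrinkage
  tab$shrinkage_pct[tab$parameter == "prop_error_pct_cv"] <- object$eps_shrinkage
  structure(list(table = tab, ofv = object$ofv, aic = object$aic,
                 bic = object$bic, converged = object$converged,
                 n_obs = object$n_obs, n_subjects = object$n_subjects),
            class = "summary.foce_fit")
}

#' @export
print.summary.foce_fit <- function(x, ...) {
  cat("Population PK parameter estimates (FOCE-I)\n")
  cat(sprintf("  %d subjects, %d observations; OFV %.3f, AIC %.3f, BIC %.3f\n\n",
              x$n_subjects, x$n_obs, x$ofv, x$aic, x$bic))
  tab <- x$table
  tab$estimate <- signif(tab$estimate, 4)
  tab$rse_pct <- signif(tab$rse_pct, 3)
  tab$shrinkage_pct <- signif(tab$shrinkage_pct, 3)
  print(tab, row.names = FALSE)
  if (!x$converged) cat("\nWARNING: optimiser did not converge\n")
  invisible(x)
}

#' @export
coef.foce_fit <- function(object, ...) object$coefficients

#' @export
vcov.foce_fit <- function(object, ...) object$vcov

#' @export
logLik.foce_fit <- function(object, ...) {
  structure(-(object$ofv + object$n_obs * log(2 * pi)) / 2,
            df = object$n_par, nobs = object$n_obs, class = "logLik")
}

#' Random-effect (empirical Bayes) estimates of a FOCE fit
#'
#' @param object A [foce_fit()].
#' @param ... Unused.
#' @return Named numeric vector of conditional modes of the subject-level
#'   random effect on clearance.
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @rdname ranef
#' @export
ranef.foce_fit <- function(object, ...) object$etas

#' Predictions from a FOCE fit
#'
#' @param object A [foce_fit()].
#' @param newdata A [pk_cohort()]; defaults to the fitting cohort.
#' @param type `"population"` for typical-subject predictions (random effect
#'   zero) or `"individual"` for conditional predictions at the empirical
#'   Bayes estimates (re-estimated for new data).
#' @param ... Unused.
#' @return Data frame with `id`, `time`, `dv`, `pred` (and `ipred` for
#'   `type = "individual"`).
#' @export
predict.foce_fit <- function(object, newdata = NULL,
                             type = c("individual", "population"), ...) {
  type <- match.arg(type)
  cohort <- if (is.null(newdata)) object$cohort else newdata
  tab <- cwres(object$model, cohort)
  out <- tab[, c("id", "time", "tad", "dv", "pred")]
  if (type == "individual") out$ipred <- tab$ipred
  out
}

#' Conditional weighted residuals and companion diagnostics
#'
#' Computes FOCE-linearised conditional weighted residuals: with the model
#' linearised about the conditional modes, each subject's residual vector is
#' decorrelated by the inverse Cholesky factor of its linearised marginal
#' covariance.  Also returns population and individual predictions and
#' individual weighted residuals.
#'
#' @param model A [pop_model()] (typically `fit$model`).
#' @param cohort A [pk_cohort()].
#' @return Data frame with columns `id`, `time`, `tad` (time after last
#'   dose), `dv`, `pred`, `ipred`, `iwres`, `cwres`.
#' @export
cwres <- function(model, cohort) {
  cov_names <- setdiff(names(model$covariates), "crcl")
  des <- .build_design(cohort, cov_names)
  typ <- .typ_cl(des, model$theta_cl, model$covariates, model$refs)
  sig2 <- model$sigma_prop^2; om2 <- model$omega_cl^2
  eta <- .solve_etas(des, typ, model$volume, sig2, om2)
  f0 <- .conc_design(des, typ * exp(eta), model$volume)
  pred <- .conc_design(des, typ, model$volume)
  h <- 1e-4
  G <- (.conc_design(des, typ * exp(eta + h), model$volume) -
        .conc_design(des, typ * exp(eta - h), model$volume)) / (2 * h)
  d <- sig2 * f0 * f0 + 1e-10
  r <- des$y - f0 + G * eta[des$obs_sub]
  cw <- numeric(des$n_obs)
  for (i in seq_len(des$n_sub)) {
    sel <- which(des$obs_sub == i)
    Vi <- diag(d[sel], nrow = length(sel)) + om2 * tcrossprod(G[sel])
    L <- t(chol(Vi))
    cw[sel] <- forwardsolve(L, r[sel])
  }
  tad <- .time_after_last_dose(cohort)
  data.frame(id = des$ids[des$obs_sub],
             time = .obs_times(cohort), tad = tad, dv = des$y,
             pred = pred, ipred = f0,
             iwres = (des$y - f0) / sqrt(d), cwres = cw,
             stringsAsFactors = FALSE)
}

.obs_times <- function(cohort) {
  unlist(lapply(cohort, function(p) p$obs$time[p$obs$mdv == 0 & !p$obs$bql]),
         use.names = FALSE)
}

.time_after_last_dose <- function(cohort) {
  unlist(lapply(cohort, function(p) {
    ot <- p$obs$time[p$obs$mdv == 0 & !p$obs$bql]
    vapply(ot, function(t) t - max(p$doses$time[p$doses$time < t]), numeric(1))
  }), use.names = FALSE)
}

#' @export
residuals.foce_fit <- function(object, type = c("cwres", "iwres"), ...) {
  type <- match.arg(type)
  tab <- cwres(object$model, object$cohort)
  stats::setNames(tab[[type]], tab$id)
}

#' @export
fitted.foce_fit <- function(object, ...) {
  tab <- cwres(object$model, object$cohort)
  stats::setNames(tab$ipred, tab$id)
}

#' Simulate observations from a fitted (or specified) model
#'
#' Draws new subject-level random effects and proportional residual errors
#' at the observation design of the cohort.
#'
#' @param object A [foce_fit()].
#' @param nsim Number of replicate datasets.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A matrix with one column per replicate and one row per usable
#'   observation (order matches [cwres()]).
#' @export
simulate.foce_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  model <- object$model
  cov_names <- setdiff(names(model$covariates), "crcl")
  des <- .build_design(object$cohort, cov_names)
  typ <- .typ_cl(des, model$theta_cl, model$covariates, model$refs)
  out <- matrix(NA_real_, des$n_obs, nsim)
  for (s in seq_len(nsim)) {
    eta <- stats::rnorm(des$n_sub, 0, model$omega_cl)
    f <- .conc_design(des, typ * exp(eta), model$volume)
    out[, s] <- f * (1 + stats::rnorm(des$n_obs, 0, model$sigma_prop))
  }
  out
}

#' Goodness-of-fit plots for a FOCE fit
#'
#' Four customary panels: observed vs individual predictions, observed vs
#' population predictions, conditional weighted residuals vs population
#' predictions, and conditional weighted residuals vs time after last dose.
#'
#' @param x A [foce_fit()].
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.foce_fit <- function(x, ...) {
  tab <- cwres(x$model, x$cohort)
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  lim <- range(c(tab$dv, tab$ipred, tab$pred))
  graphics::plot(tab$ipred, tab$dv, xlab = "Individual prediction (mg/L)",
                 ylab = "Observed (mg/L)", xlim = lim, ylim = lim, ...)
  graphics::abline(0, 1, col = "red")
  graphics::plot(tab$pred, tab$dv, xlab = "Population prediction (mg/L)",
                 ylab = "Observed (mg/L)", xlim = lim, ylim = lim, ...)
  graphics::abline(0, 1, col = "red")
  graphics::plot(tab$pred, tab$cwres, xlab = "Population prediction (mg/L)",
                 ylab = "CWRES", ...)
  graphics::abline(h = c(-2, 0, 2), lty = c(2, 1, 2), col = "red")
  graphics::plot(tab$tad, tab$cwres, xlab = "Time after last dose (h)",
                 ylab = "CWRES", ...)
  graphics::abline(h = c(-2, 0, 2), lty = c(2, 1, 2), col = "red")
  invisible(x)
}

#' Eta and epsilon shrinkage of a FOCE fit
#'
#' Eta shrinkage is `100 * (1 - SD(eta-hat) / omega)`; epsilon shrinkage is
#' `100 * (1 - SD(IWRES))`.
#'
#' @param fit A [foce_fit()].
#' @return Named vector `c(eta = , eps = )`, in percent.
#' @export
shrinkage <- function(fit) {
  if (fit$model$omega_cl <= 0) stop("eta shrinkage undefined for omega = 0")
  c(eta = eta_shrinkage(fit$etas, fit$model$omega_cl),
    eps = fit$eps_shrinkage)
}

#' @rdname shrinkage
#' @param etas Empirical Bayes estimates of the random effect.
#' @param omega Population standard deviation of the random effect
#'   (positive).
#' @export
eta_shrinkage <- function(etas, omega) {
  if (omega <= 0) stop("eta shrinkage undefined for omega = 0")
  100 * (1 - stats::sd(etas) / omega)
}
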