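#' Exposure-toxicity logistic model
#'
#' Container for the logistic model of myelosuppression risk against the
#' steady-state trough concentration, in the convention
#' `P(myelosuppression) = 1 / (1 + exp(beta0 - beta1 * Cmin))`, so `beta0` is
#' the positive magnitude of the intercept on the logit scale.  The
#' published model for critically ill patients has `beta0 = 3.767`,
#' `beta1 = 0.481` per mg/L.
#'
#' @param beta0 Intercept magnitude (logit scale).
#' @param beta1 Slope per mg/L of trough concentration; must be positive for
#'   a finite toxicity threshold.
#' @return An object of class `logistic_td`.
#' @export
logistic_td <- function(beta0 = 3.767, beta1 = 0.481) {
  if (beta1 <= 0) stop("'beta1' must be positive for a toxicity model")
  structure(list(beta0 = beta0, beta1 = beta1), class = "logistic_td")
}

#' @export
print.logistic_td <- function(x, ...) {
  cat(sprintf("P(myelosuppression) = 1 / (1 + exp(%.3f - %.3f * Cmin))\n",
              x$beta0, x$beta1))
  cat(sprintf("  50%% threshold: %.1f mg/L\n", toxicity_threshold(x)))
  invisible(x)
}

#' Fit the exposure-toxicity logistic model
#'
#' Plain maximum-likelihood logistic regression of a binary myelosuppression
#' outcome on the steady-state trough concentration.  Both outcome classes
#' must be present; complete or quasi-complete separation is detected and
#' refused rather than silently returning a diverged fit.
#'
#' @param cmin Steady-state trough concentrations (mg/L).
#' @param outcome Binary outcomes (0/1 or logical).
#' @return A [logistic_td()] with additional fields `glm` (the underlying
#'   fit), `converged` and `se` (coefficient standard errors).
#' @export
fit_logistic <- function(cmin, outcome) {
  outcome <- as.integer(outcome)
  stopifnot(length(cmin) == length(outcome), all(outcome %in% 0:1))
  if (length(unique(outcome)) < 2)
    stop("both outcome classes must be present")
  separated <- FALSE
  g <- withCallingHandlers(
    stats::glm(outcome ~ cmin, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated || !g$converged || any(abs(stats::coef(g)) > 50))
    stop("separation detected in the logistic toxicodynamic fit")
  co <- stats::coef(g)
  out <- logistic_td(beta0 = -unname(co[1]), beta1 = unname(co[2]))
  out$glm <- g
  out$converged <- g$converged
  out$se <- sqrt(diag(stats::vcov(g)))
  out
}

#' Probability of myelosuppression at a trough concentration
#'
#' @param model A [logistic_td()].
#' @param cmin Trough concentration (mg/L), non-negative, vectorised.
#' @return Probability in (0, 1), strictly increasing in `cmin`.
#' @examples
#' prob_myelosuppression(logistic_td(), 7.8)  # ~0.496
#' @export
prob_myelosuppression <- function(model, cmin) {
  if (any(cmin < 0)) stop("'cmin' must be non-negative")
  1 / (1 + exp(model$beta0 - model$beta1 * cmin))
}

#' Trough concentration at a given toxicity probability
#'
#' Closed-form inverse of the logistic model, `(logit(p) + beta0) / beta1`.
#' Reported rounded to one decimal by default (full precision with
#' `digits = NULL`).
#'
#' @param model A [logistic_td()].
#' @param p Target probability in (0, 1); default 0.5.
#' @param digits Decimals for rounding, or `NULL` for full precision.
#' @return Threshold trough concentration (mg/L).
#' @examples
#' toxicity_threshold(logistic_td())  # 7.8
#' @export
toxicity_threshold <- function(model, p = 0.5, digits = 1) {
  stopifnot(p > 0, p < 1)
  if (model$beta1 <= 0) stop("'beta1' must be positive")
  x <- (stats::qlogis(p) + model$beta0) / model$beta1
  if (is.null(digits)) x else round(x, digits)
}

#' Trough-to-AUC surrogate regression
#'
#' Container for the linear regression of the steady-state 24-h AUC on the
#' steady-state trough, `AUC = slope * Cmin + intercept`.  The published fit
#' is `AUC = 26.354 * Cmin + 91.607` with r-squared 0.9969.
#'
#' @param slope Slope (mg*h/L per mg/L), positive.
#' @param intercept Intercept (mg*h/L).
#' @param r2 Coefficient of determination (optional).
#' @return An object of class `exposure_regression`.
#' @export
exposure_regression <- function(slope = 26.354, intercept = 91.607,
                                r2 = NA_real_) {
  if (slope <= 0) stop("'slope' must be positive")
  structure(list(slope = slope, intercept = intercept, r2 = r2),
            class = "exposure_regression")
}

#' @export
print.exposure_regression <- function(x, ...) {
  cat(sprintf("AUC0-24 = %.3f * Cmin + %.3f", x$slope, x$intercept))
  if (!is.na(x$r2)) cat(sprintf("  (r2 = %.4f)", x$r2))
  cat("\n")
  invisible(x)
}

#' Fit the trough-to-AUC regression by ordinary least squares
#'
#' @param cmin Steady-state troughs (mg/L); at least two distinct values.
#' @param auc Steady-state 24-h AUCs (mg*h/L).
#' @return An [exposure_regression()] with field `lm` (the underlying fit).
#' @export
fit_cmin_auc <- function(cmin, auc) {
  stopifnot(length(cmin) == length(auc))
  if (length(unique(cmin)) < 2)
    stop("at least two distinct 'cmin' values are required")
  fit <- stats::lm(auc ~ cmin)
  co <- stats::coef(fit)
  out <- exposure_regression(slope = unname(co[2]), intercept = unname(co[1]),
                             r2 = summary(fit)$r.squared)
  out$lm <- fit
  out
}

#' AUC implied by the surrogate regression at a trough concentration
#'
#' @param reg An [exposure_regression()].
#' @param cmin Trough concentration (mg/L), vectorised.
#' @param digits Decimals for rounding, or `NULL` for full precision.
#' @return AUC0-24 (mg*h/L).
#' @examples
#' predict_auc(exposure_regression(), 7.8)  # 297.2
#' @export
predict_auc <- function(reg, cmin, digits = 1) {
  x <- reg$slope * cmin + reg$intercept
  if (is.null(digits)) x else round(x, digits)
}

#' Efficacy target configuration
#'
#' The efficacy index is the ratio of the 24-h AUC to the pathogen MIC; the
#' target AUC is their product (default 80 x 2 mg/L = 160 mg*h/L, the
#' staphylococcal MIC90).
#'
#' @param auc_mic_target Target AUC0-24/MIC ratio (unitless).
#' @param mic Minimum inhibitory concentration (mg/L).
#' @return An object of class `efficacy_target` with the derived
#'   `auc_target`.
#' @export
efficacy_target <- function(auc_mic_target = 80, mic = 2) {
  stopifnot(auc_mic_target > 0, mic > 0)
  structure(list(auc_mic_target = auc_mic_target, mic = mic,
                 auc_target = auc_mic_target * mic),
            class = "efficacy_target")
}

#' Therapeutic trough window
#'
#' Lower bound: the trough achieving the efficacy AUC target, by inverting
#' the surrogate regression, `(auc_target - intercept) / slope`.  Upper
#' bound: the 50%-probability toxicity threshold.  Both reported to one
#' decimal; an inverted (lower >= upper) window is refused.
#'
#' @param reg An [exposure_regression()].
#' @param eff An [efficacy_target()].
#' @param td A [logistic_td()].
#' @param digits Decimals for rounding, or `NULL` for full precision.
#' @return An object of class `therapeutic_window` with `lower` and `upper`
#'   (mg/L).
#' @examples
#' therapeutic_window()  # 2.6 - 7.8 mg/L
#' @export
therapeutic_window <- function(reg = exposure_regression(),
                               eff = efficacy_target(),
                               td = logistic_td(), digits = 1) {
  lower <- (eff$auc_target - reg$intercept) / reg$slope
  upper <- toxicity_threshold(td, 0.5, digits = NULL)
  if (!is.null(digits)) {
    lower <- round(lower, digits)
    upper <- round(upper, digits)
  }
  if (lower >= upper)
    stop(sprintf("inconsistent window: lower %.3g >= upper %.3g", lower, upper))
  structure(list(lower = lower, upper = upper), class = "therapeutic_window")
}

#' @export
print.therapeutic_window <- function(x, ...) {
  cat(sprintf("Therapeutic trough window: %.1f - %.1f mg/L\n",
              x$lower, x$upper))
  invisible(x)
}

#' Kaplan-Meier estimate of time to myelosuppression
#'
#' Product-limit estimator of the survival (toxicity-free) function, with
#' the median defined as the smallest time at which the estimate drops to
#' 0.5 or below (undefined when never reached).
#'
#' @param event_time Times in days (positive).
#' @param censored Logical/0-1; `TRUE` where no event was observed.
#' @return An object of class `km_curve` with `time`, `surv`, `n_risk`,
#'   `n_event` and `median`.
#' @export
km_estimator <- function(event_time, censored) {
  stopifnot(length(event_time) > 0, length(event_time) == length(censored))
  if (any(event_time <= 0)) stop("'event_time' must be positive")
  event <- 1L - as.integer(censored)
  sf <- survival::survfit(survival::Surv(event_time, event) ~ 1)
  surv <- sf$surv
  med <- if (any(surv <= 0.5)) sf$time[which(surv <= 0.5)[1]] else NA_real_
  structure(list(time = sf$time, surv = surv, n_risk = sf$n.risk,
                 n_event = sf$n.event, median = med,
                 n = length(event_time), events = sum(event)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier time to myelosuppression: %d subjects, %d events\n",
              x$n, x$events))
  cat("  median:", if (is.na(x$median)) "not reached" else
    sprintf("%g days", x$median), "\n")
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 xlab = "Days from start of therapy",
                 ylab = "Myelosuppression-free fraction",
                 main = "", ylim = c(0, 1), ...)
  invisible(x)
}

#' Incidence percentage from event counts
#'
#' @param events Number of events.
#' @param n Number of classified patients.
#' @param digits Decimals (default 2, the customary reporting precision).
#' @return Percentage.
#' @examples
#' incidence(30, 83)  # 36.14
#' @export
incidence <- function(events, n, digits = 2) {
  stopifnot(n > 0, events >= 0, events <= n)
  round(100 * events / n, digits)
}

#' Toxicity analysis report
#'
#' Assembles the toxicity analysis of a classified cohort: incidence rates
#' of myelosuppression, thrombocytopenia and anemia; the logistic
#' exposure-toxicity fit and its 50% threshold; the trough-to-AUC regression
#' and therapeutic window; and the Kaplan-Meier curve.  Each model component
#' can be supplied pre-fitted or is fitted from the supplied data.
#'
#' @param outcome Character outcomes per patient (`"none"`,
#'   `"thrombocytopenia"`, `"anemia"`, `"both"`).
#' @param cmin Per-patient steady-state troughs (mg/L); optional, enables
#'   the logistic fit.
#' @param auc Per-patient steady-state AUCs; optional, enables the surrogate
#'   regression.
#' @param event_time,censored Optional Kaplan-Meier inputs.
#' @param eff An [efficacy_target()].
#' @param file Optional path: the report is also written as JSON.
#' @return A list of class `toxicity_report`.
#' @export
toxicity_report <- function(outcome, cmin = NULL, auc = NULL,
                            event_time = NULL, censored = NULL,
                            eff = efficacy_target(), file = NULL) {
  stopifnot(all(outcome %in% c("none", "thrombocytopenia", "anemia", "both")))
  n <- length(outcome)
  n_myelo <- sum(outcome != "none")
  n_thrombo <- sum(outcome %in% c("thrombocytopenia", "both"))
  n_anemia <- sum(outcome %in% c("anemia", "both"))
  rep <- list(
    n = n,
    myelosuppression = list(events = n_myelo, pct = incidence(n_myelo, n)),
    thrombocytopenia = list(events = n_thrombo, pct = incidence(n_thrombo, n)),
    anemia = list(events = n_anemia, pct = incidence(n_anemia, n)))
  if (!is.null(cmin)) {
    td <- fit_logistic(cmin, outcome != "none")
    rep$logistic <- list(beta0 = td$beta0, beta1 = td$beta1,
                         threshold_50pct = toxicity_threshold(td))
    if (!is.null(auc)) {
      reg <- fit_cmin_auc(cmin, auc)
      win <- therapeutic_window(reg, eff, td)
      rep$regression <- list(slope = reg$slope, intercept = reg$intercept,
                             r2 = reg$r2)
      rep$window <- list(lower = win$lower, upper = win$upper)
    }
  }
  if (!is.null(event_time)) {
    km <- km_estimator(event_time, censored)
    rep$km <- list(median_days = km$median, events = km$events)
  }
  class(rep) <- "toxicity_report"
  if (!is.null(file))
    jsonlite::write_json(unclass(rep), file, auto_unbox = TRUE, digits = NA)
  rep
}

#' @export
print.toxicity_report <- function(x, ...) {
  cat(sprintf("Toxicity report (%d patients)\n", x$n))
  cat(sprintf("  myelosuppression: %d (%.2f%%)\n",
              x$myelosuppression$events, x$myelosuppression$pct))
  cat(sprintf("  thrombocytopenia: %d (%.2f%%)\n",
              x$thrombocytopenia$events, x$thrombocytopenia$pct))
  cat(sprintf("  anemia:           %d (%.2f%%)\n",
              x$anemia$events, x$anemia$pct))
  if (!is.null(x$logistic))
    cat(sprintf("  logistic: beta0 %.3f, beta1 %.3f; 50%% threshold %.1f mg/L\n",
                x$logistic$beta0, x$logistic$beta1,
                x$logistic$threshold_50pct))
  if (!is.null(x$window))
    cat(sprintf("  therapeutic window: %.1f - %.1f mg/L\n",
                x$window$lower, x$window$upper))
  if (!is.null(x$km))
    cat("  KM median:", if (is.na(x$km$median_days)) "not reached" else
      sprintf("%g days", x$km$median_days), "\n")
  invisible(x)
}
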