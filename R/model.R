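#' Population pharmacokinetic model for linezolid
#'
#' Constructs the population model object used throughout the package: a
#' one-compartment model with linear elimination, zero-order (infusion) input,
#' a log-normal between-subject random effect on clearance, no between-subject
#' variability on volume, and a proportional residual-error model.  Typical
#' clearance is an affine function of creatinine clearance,
#' `CL = theta_cl + theta * (cov / ref)` summed over covariate terms; the
#' canonical model carries a single `crcl` term referenced to 65 mL/min.
#'
#' Defaults are the final published estimates for critically ill patients:
#' `CL (L/h) = 3.66 + 2.18 * CrCL/65`, `V = 54 L`, BSV on CL 36.30 %CV,
#' proportional residual error 19.05 %CV.
#'
#' @param theta_cl Typical clearance intercept (L/h).
#' @param volume Apparent volume of distribution (L), no between-subject
#'   variability.
#' @param omega_cl Standard deviation of the log-normal between-subject random
#'   effect on CL (unitless).
#' @param sigma_prop Proportional residual error standard deviation (unitless
#'   fraction, e.g. 0.1905 for 19.05 %CV).
#' @param covariates Named numeric vector of covariate slopes on CL (L/h per
#'   unit of covariate/reference). Use `NULL` for a covariate-free base model.
#' @param refs Named numeric vector of reference values for each covariate,
#'   same names as `covariates`.
#' @return An object of class `pop_model`.
#' @examples
#' m <- pop_model()
#' typical_cl(m, crcl = 65)   # 5.84 L/h
#' @export
pop_model <- function(theta_cl = 3.66,
                      volume = 54,
                      omega_cl = cv_to_omega(36.30),
                      sigma_prop = 0.1905,
                      covariates = c(crcl = 2.18),
                      refs = c(crcl = 65)) {
  if (!is.null(covariates)) {
    if (is.null(names(covariates)) || any(!nzchar(names(covariates))))
      stop("'covariates' must be a named numeric vector")
    if (!all(names(covariates) %in% names(refs)))
      stop("every covariate needs a reference value in 'refs'")
    refs <- refs[names(covariates)]
  } else {
    refs <- NULL
  }
  stopifnot(theta_cl > 0, volume > 0, omega_cl >= 0, sigma_prop >= 0)
  structure(list(theta_cl = theta_cl, volume = volume,
                 omega_cl = omega_cl, sigma_prop = sigma_prop,
                 covariates = covariates, refs = refs),
            class = "pop_model")
}

#' @export
print.pop_model <- function(x, ...) {
  cat("One-compartment IV-infusion population PK model\n")
  cov_str <- if (is.null(x$covariates)) "" else
    paste0(" + ", paste(sprintf("%.4g*(%s/%.4g)", x$covariates,
                                names(x$covariates), x$refs), collapse = " + "))
  cat(sprintf("  CL (L/h) = %.4g%s\n", x$theta_cl, cov_str))
  cat(sprintf("  V  (L)   = %.4g\n", x$volume))
  cat(sprintf("  BSV on CL: omega = %.4g (%.2f %%CV)\n",
              x$omega_cl, omega_to_cv(x$omega_cl)))
  cat(sprintf("  Proportional error: sigma = %.4g (%.2f %%CV)\n",
              x$sigma_prop, 100 * x$sigma_prop))
  invisible(x)
}

#' Typical (population) clearance at a given creatinine clearance
#'
#' Evaluates the covariate model for clearance at a creatinine clearance
#' value: `theta_cl + theta_crcl * (crcl / crcl_ref)`. Covariate terms other
#' than `crcl` (if present) are evaluated at their reference value, i.e.
#' contribute their slope.
#'
#' @param model A [pop_model()].
#' @param crcl Creatinine clearance (mL/min), non-negative, vectorised.
#' @return Typical clearance (L/h).
#' @export
typical_cl <- function(model, crcl) {
  stopifnot(inherits(model, "pop_model"))
  if (any(crcl < 0)) stop("'crcl' must be non-negative")
  cl <- rep_len(model$theta_cl, length(crcl))
  cv <- model$covariates
  if (!is.null(cv)) {
    for (nm in names(cv)) {
      cl <- cl + if (nm == "crcl") cv[[nm]] * crcl / model$refs[[nm]]
                 else cv[[nm]]
    }
  }
  cl
}

#' Individual pharmacokinetic parameters
#'
#' Builds individual parameters from the population model, a creatinine
#' clearance and a random-effect value: `CL = typical_cl * exp(eta)`, volume
#' taken from the model (no between-subject variability on V).
#'
#' @inheritParams typical_cl
#' @param eta_cl Individual log-scale random effect on clearance.
#' @return A list of class `individual_params` with elements `cl`, `volume`,
#'   `eta_cl`.
#' @export
individual_params <- function(model, crcl, eta_cl = 0) {
  if (any(crcl < 0)) stop("'crcl' must be non-negative")
  cl <- typical_cl(model, crcl) * exp(eta_cl)
  structure(list(cl = cl, volume = model$volume, eta_cl = eta_cl),
            class = "individual_params")
}

#' Dosing regimen
#'
#' @param dose Dose amount per administration (mg).
#' @param interval Dosing interval tau (h).
#' @param tinf Infusion duration (h); default 1 h.
#' @return An object of class `regimen`.
#' @export
regimen <- function(dose, interval, tinf = 1) {
  stopifnot(dose >= 0, interval > 0, tinf > 0, tinf < interval)
  structure(list(dose = dose, interval = interval, tinf = tinf),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("%g mg q%gh (%g-h infusion)\n", x$dose, x$interval, x$tinf))
  invisible(x)
}

#' Concentration-time profile under superposition of infusions
#'
#' Exact closed-form one-compartment solution with zero-order input and
#' first-order elimination, superposed over a dose history.  During an
#' infusion the contribution is `(R0/CL) * (1 - exp(-k t'))`; after its end it
#' decays mono-exponentially, with `k = CL/V`.
#'
#' @param t Times since first dose (h), vectorised.
#' @param doses Data frame with columns `time` (h), `amount` (mg), `duration`
#'   (h), as built by [dose_events()].
#' @param params An [individual_params()] object (or any list with `cl` and
#'   `volume`).
#' @return Concentrations (mg/L) at `t`.
#' @export
conc_profile <- function(t, doses, params) {
  stopifnot(all(t >= 0), all(doses$amount > 0), all(doses$duration > 0))
  cl <- params$cl
  k <- cl / params$volume
  out <- numeric(length(t))
  rate <- doses$amount / doses$duration
  for (d in seq_len(nrow(doses))) {
    dt <- t - doses$time[d]
    on <- dt > 0
    te <- pmin(dt[on], doses$duration[d])
    tp <- pmax(dt[on] - doses$duration[d], 0)
    out[on] <- out[on] + (rate[d] / cl) * (1 - exp(-k * te)) * exp(-k * tp)
  }
  out
}

#' Helper to build a dose-event table
#'
#' @param time Start times of each infusion (h since first dose).
#' @param amount Dose amounts (mg).
#' @param duration Infusion durations (h).
#' @return Data frame with columns `time`, `amount`, `duration`.
#' @export
dose_events <- function(time, amount, duration = 1) {
  d <- data.frame(time = time, amount = amount, duration = duration)
  if (any(d$amount <= 0)) stop("dose 'amount' must be positive")
  if (any(d$duration <= 0)) stop("infusion 'duration' must be positive")
  if (any(d$time < 0)) stop("dose 'time' must be non-negative")
  d
}

#' Dose history implied by a regimen
#'
#' Expands a [regimen()] into explicit dose events.  By default enough doses
#' are laid down to reach steady state: at least 10 doses or 7 elimination
#' half-lives, whichever is longer.
#'
#' @param reg A [regimen()].
#' @param params Individual parameters (needed to judge the half-life when
#'   `n_doses` is not given).
#' @param n_doses Number of doses; if `NULL`, chosen for steady state.
#' @return Dose-event data frame.
#' @export
regimen_doses <- function(reg, params = NULL, n_doses = NULL) {
  if (is.null(n_doses)) {
    stopifnot(!is.null(params))
    t_half <- log(2) * params$volume / params$cl
    n_doses <- max(10, ceiling(7 * t_half / reg$interval))
  }
  dose_events(time = (seq_len(n_doses) - 1) * reg$interval,
              amount = reg$dose, duration = reg$tinf)
}

#' Steady-state trough concentration (closed form)
#'
#' Trough at the end of the dosing interval at steady state for repeated
#' zero-order infusions:
#' `Cmin = (D/(Tinf*CL)) * (1-exp(-k*Tinf)) * exp(-k*(tau-Tinf)) / (1-exp(-k*tau))`.
#' Equals the limit of dose superposition.
#'
#' @param reg A [regimen()].
#' @param params An [individual_params()] object; vectorised over `cl`.
#' @return Steady-state trough (mg/L).
#' @export
steady_state_cmin <- function(reg, params) {
  stopifnot(reg$tinf < reg$interval)
  cl <- params$cl
  if (any(cl <= 0)) stop("clearance must be positive")
  k <- cl / params$volume
  if (any(k <= 0)) stop("elimination rate constant must be positive")
  if (reg$dose == 0) return(rep_len(0, length(cl)))
  (reg$dose / (reg$tinf * cl)) * (1 - exp(-k * reg$tinf)) *
    exp(-k * (reg$interval - reg$tinf)) / (1 - exp(-k * reg$interval))
}

#' Steady-state 24-h AUC by the clearance identity
#'
#' At steady state the 24-h area under the curve equals daily dose divided by
#' clearance.
#'
#' @inheritParams steady_state_cmin
#' @return AUC over 24 h at steady state (mg*h/L).
#' @export
steady_state_auc24 <- function(reg, params) {
  if (any(params$cl <= 0)) stop("clearance must be positive")
  daily <- reg$dose * 24 / reg$interval
  daily / params$cl
}

#' Linear-up / log-down trapezoidal AUC
#'
#' Per segment: the linear trapezoid when the concentration is rising (or
#' either endpoint is zero, or the two are equal), and the log-trapezoid
#' `(C1 - C2) * dt / log(C1/C2)` when it is falling.  The guard against zero
#' or equal endpoints avoids log-of-zero and 0/0, standard pharmacokinetic
#' practice.
#'
#' @param times Strictly increasing times (h).
#' @param concs Non-negative concentrations (mg/L), same length.
#' @return AUC (mg*h/L).
#' @export
auc_linlog <- function(times, concs) {
  stopifnot(length(times) == length(concs), length(times) >= 2)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (any(concs < 0)) stop("'concs' must be non-negative")
  c1 <- concs[-length(concs)]
  c2 <- concs[-1]
  dt <- diff(times)
  lin <- (c1 + c2) / 2 * dt
  use_log <- c2 < c1 & c2 > 0 & c1 > 0
  seg <- lin
  seg[use_log] <- (c1[use_log] - c2[use_log]) * dt[use_log] /
    log(c1[use_log] / c2[use_log])
  sum(seg)
}

#' Convert between the BSV standard deviation and percent CV
#'
#' For a log-normal random effect with standard deviation `omega`, the
#' coefficient of variation is `100 * sqrt(exp(omega^2) - 1)`; the inverse is
#' exact.
#'
#' @param omega Log-scale standard deviation (non-negative).
#' @param cv Percent coefficient of variation (non-negative).
#' @return `omega_to_cv`: %CV; `cv_to_omega`: omega.
#' @export
omega_to_cv <- function(omega) {
  if (any(omega < 0)) stop("'omega' must be non-negative")
  100 * sqrt(exp(omega^2) - 1)
}

#' @rdname omega_to_cv
#' @export
cv_to_omega <- function(cv) {
  if (any(cv < 0)) stop("'cv' must be non-negative")
  sqrt(log(1 + (cv / 100)^2))
}
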