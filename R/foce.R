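# FOCE-I engine: design flattening, vectorised inner eta solve, linearised
# marginal objective.  All hot paths are plain vector arithmetic over a
# flattened (observation x dose) contribution table so one objective
# evaluation costs a handful of exp() calls.

# Flatten a cohort into the structures the objective needs.
# Every usable observation (EVID=0, MDV=0, not BQL) contributes one entry per
# dose administered before it.
.build_design <- function(cohort, covariate_names = NULL, drop_empty = TRUE) {
  usable <- vapply(cohort, function(p) sum(p$obs$mdv == 0 & !p$obs$bql),
                   integer(1))
  dropped <- character(0)
  if (any(usable == 0)) {
    if (!drop_empty)
      stop("subject ", cohort[[which(usable == 0)[1]]]$id,
           " has no usable observation")
    dropped <- vapply(cohort[usable == 0], function(p) as.character(p$id),
                      character(1))
    cohort <- cohort[usable > 0]
  }
  n_sub <- length(cohort)
  if (!n_sub) stop("no subject has a usable observation")
  y <- list(); obs_sub <- list()
  row_obs <- list(); row_te <- list(); row_tp <- list(); row_rate <- list()
  obs_count <- 0L
  for (i in seq_len(n_sub)) {
    p <- cohort[[i]]
    use <- p$obs$mdv == 0 & !p$obs$bql
    ot <- p$obs$time[use]
    oy <- p$obs$conc[use]
    if (all(oy == 0))
      stop("subject ", p$id, " has all-zero concentrations")
    d <- p$doses
    for (j in seq_along(ot)) {
      obs_count <- obs_count + 1L
      sel <- d$time < ot[j]
      if (!any(sel)) stop("observation before first dose for subject ", p$id)
      dt <- ot[j] - d$time[sel]
      row_obs[[obs_count]] <- rep.int(obs_count, sum(sel))
      row_te[[obs_count]] <- pmin(dt, d$duration[sel])
      row_tp[[obs_count]] <- pmax(dt - d$duration[sel], 0)
      row_rate[[obs_count]] <- d$amount[sel] / d$duration[sel]
      y[[obs_count]] <- oy[j]
      obs_sub[[obs_count]] <- i
    }
  }
  X <- NULL
  if (length(covariate_names)) {
    X <- vapply(covariate_names, function(nm)
      vapply(cohort, patient_covariate, numeric(1), name = nm), numeric(n_sub))
    X <- matrix(X, nrow = n_sub,
                dimnames = list(NULL, covariate_names))
  }
  crcl <- vapply(cohort, function(p) p$crcl, numeric(1))
  list(n_sub = n_sub, n_obs = obs_count,
       y = unlist(y), obs_sub = unlist(obs_sub),
       row_obs = unlist(row_obs), row_te = unlist(row_te),
       row_tp = unlist(row_tp), row_rate = unlist(row_rate),
       row_sub = unlist(obs_sub)[unlist(row_obs)],
       X = X, crcl = crcl, dropped = dropped,
       ids = vapply(cohort, function(p) as.character(p$id), character(1)))
}

# Per-observation model prediction for subject clearances cl_sub and volume v.
.conc_design <- function(des, cl_sub, v) {
  cl_row <- cl_sub[des$row_sub]
  k_row <- cl_row / v
  contrib <- (des$row_rate / cl_row) * (1 - exp(-k_row * des$row_te)) *
    exp(-k_row * des$row_tp)
  as.vector(rowsum(contrib, des$row_obs, reorder = TRUE))
}

# Per-subject conditional -2ll + prior ("inner" objective), vectorised over
# subjects; returns the vector of per-subject values.
.inner_obj <- function(des, eta, typ_cl, v, sig2, om2) {
  f <- .conc_design(des, typ_cl * exp(eta), v)
  r <- des$y - f
  d <- sig2 * f * f + 1e-10
  per_obs <- r * r / d + log(d)
  per <- as.vector(rowsum(per_obs, des$obs_sub, reorder = TRUE))
  if (om2 > 0) per <- per + eta^2 / om2
  per
}

# Vectorised safeguarded Newton solve for the conditional modes eta-hat.
.solve_etas <- function(des, typ_cl, v, sig2, om2, eta_start = NULL,
                        tol = 1e-6, max_iter = 40L) {
  if (om2 <= 0) return(numeric(des$n_sub))
  eta <- if (is.null(eta_start)) numeric(des$n_sub) else eta_start
  h <- 1e-3
  for (it in seq_len(max_iter)) {
    l0 <- .inner_obj(des, eta, typ_cl, v, sig2, om2)
    lp <- .inner_obj(des, eta + h, typ_cl, v, sig2, om2)
    lm <- .inner_obj(des, eta - h, typ_cl, v, sig2, om2)
    g <- (lp - lm) / (2 * h)
    H <- pmax((lp + lm - 2 * l0) / h^2, 1e-4)
    step <- -g / H
    step <- pmin(pmax(step, -1.5), 1.5)
    # backtracking where the full step does not decrease the objective
    for (bt in 1:6) {
      l1 <- .inner_obj(des, eta + step, typ_cl, v, sig2, om2)
      worse <- l1 > l0 + 1e-10
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    improved <- l1 <= l0 + 1e-10
    step[!improved] <- 0
    eta <- eta + step
    if (max(abs(step)) < tol) break
  }
  pmin(pmax(eta, -5 * sqrt(om2) - 1e-9), 5 * sqrt(om2) + 1e-9)
}

# FOCE-I linearised marginal objective given solved eta-hat.  Returns the
# per-subject OFV contributions (NONMEM scale: -2LL minus n*log(2*pi)).
.foce_ofv_terms <- function(des, eta, typ_cl, v, sig2, om2) {
  cl0 <- typ_cl * exp(eta)
  f0 <- .conc_design(des, cl0, v)
  h <- 1e-4
  fp <- .conc_design(des, typ_cl * exp(eta + h), v)
  fm <- .conc_design(des, typ_cl * exp(eta - h), v)
  G <- (fp - fm) / (2 * h)
  d <- sig2 * f0 * f0 + 1e-10
  r <- des$y - f0 + G * eta[des$obs_sub]
  S <- function(x) as.vector(rowsum(x, des$obs_sub, reorder = TRUE))
  Sld <- S(log(d)); Sgg <- S(G * G / d); Srr <- S(r * r / d); Srg <- S(r * G / d)
  A <- 1 + om2 * Sgg
  Sld + log(A) + Srr - om2 * Srg^2 / A
}

# Typical clearances per subject from intercept + covariate slopes.
.typ_cl <- function(des, theta_cl, slopes, refs) {
  typ <- rep_len(theta_cl, des$n_sub)
  if (length(slopes)) {
    for (j in seq_along(slopes)) {
      nm <- names(slopes)[j]
      covv <- if (nm == "crcl") des$crcl else des$X[, nm]
      typ <- typ + slopes[j] * covv / refs[j]
    }
  }
  typ
}

#' Evaluate the FOCE-I objective function of a population model on a cohort
#'
#' Solves the conditional modes of the subject-level random effects and
#' returns the first-order-conditional (with interaction) approximation to
#' the -2 log marginal likelihood, on the customary scale that omits the
#' `n*log(2*pi)` constant.
#'
#' @param model A [pop_model()].
#' @param cohort A [pk_cohort()].
#' @return OFV (numeric scalar) with attribute `etas` (conditional modes).
#' @export
foce_ofv <- function(model, cohort) {
  cov_names <- setdiff(names(model$covariates), "crcl")
  des <- .build_design(cohort, cov_names)
  typ <- .typ_cl(des, model$theta_cl, model$covariates, model$refs)
  sig2 <- model$sigma_prop^2
  om2 <- model$omega_cl^2
  eta <- .solve_etas(des, typ, model$volume, sig2, om2)
  ofv <- sum(.foce_ofv_terms(des, eta, typ, model$volume, sig2, om2))
  attr(ofv, "etas") <- stats::setNames(eta, des$ids)
  ofv
}

#' Control settings for [foce_fit()]
#'
#' @param maxit Maximum Nelder-Mead iterations for the outer search.
#' @param reltol Relative tolerance on the outer objective.
#' @param inner_tol Tolerance on the conditional-mode solve.
#' @param restart Number of perturbed restarts attempted when the outer
#'   optimiser reports non-convergence.
#' @return List of control settings.
#' @export
foce_control <- function(maxit = 3000L, reltol = 1e-8, inner_tol = 1e-6,
                         restart = 1L) {
  list(maxit = maxit, reltol = reltol, inner_tol = inner_tol,
       restart = restart)
}

#' Fit the population PK model by FOCE with interaction
#'
#' Maximum-likelihood estimation of the one-compartment infusion model with a
#' log-normal random effect on clearance and proportional residual error,
#' using the first-order conditional approximation with interaction: the
#' subject-level random effects are set to their conditional modes and the
#' model is linearised about them, the residual variance being evaluated at
#' the conditional (not population) prediction.  Structural parameters
#' (clearance intercept, volume, omega, sigma) are estimated on the log scale
#' to keep them positive; covariate slopes are unconstrained with a
#' positivity guard on each subject's typical clearance.
#'
#' @param cohort A [pk_cohort()]; every subject needs at least one usable
#'   observation.
#' @param init A [pop_model()] holding positive initial estimates; its
#'   covariate terms define the covariate structure of the fit (use
#'   `covariates = NULL` for the base model).
#' @param covariates Optional character vector naming covariates on CL to fit
#'   (overrides the structure in `init`); slopes are initialised at a small
#'   positive value when `init` carries no matching term.  References default
#'   to 65 mL/min for `crcl` and to the cohort median otherwise.
#' @param control A [foce_control()] list.
#' @return An object of class `foce_fit`; see [summary.foce_fit()].  Fields
#'   include the fitted `model`, `coefficients`, `rse` (percent relative
#'   standard errors by the sandwich estimator), `ofv`, `aic`, `bic`, `etas`,
#'   `eta_shrinkage`, `eps_shrinkage` and `converged`.
#' @examples
#' \donttest{
#' cfg <- cohort_config(n_patients = 40, seed = 7)
#' coh <- generate_cohort(cfg)
#' fit <- foce_fit(coh, init = pop_model())
#' summary(fit)
#' }
#' @export
foce_fit <- function(cohort, init = pop_model(), covariates = NULL,
                     control = foce_control()) {
  stopifnot(inherits(init, "pop_model"))
  if (is.null(covariates)) {
    covariates <- names(init$covariates)
  }
  slopes0 <- numeric(0); refs <- numeric(0)
  if (length(covariates)) {
    des_tmp <- .build_design(cohort, setdiff(covariates, "crcl"))
    for (nm in covariates) {
      s0 <- if (!is.null(init$covariates) && nm %in% names(init$covariates))
        init$covariates[[nm]] else 0.1
      r0 <- if (!is.null(init$refs) && nm %in% names(init$refs))
        init$refs[[nm]] else if (nm == "crcl") 65 else
          stats::median(if (nm == "crcl") des_tmp$crcl else des_tmp$X[, nm])
      slopes0 <- c(slopes0, stats::setNames(s0, nm))
      refs <- c(refs, stats::setNames(r0, nm))
    }
  }
  des <- .build_design(cohort, setdiff(covariates, "crcl"))
  if (length(des$dropped))
    warning("dropping subject(s) without usable observations: ",
            paste(des$dropped, collapse = ", "))
  sig0 <- max(init$sigma_prop, 1e-4)
  om0 <- max(init$omega_cl, 1e-4)
  # parameter vector: log(theta_cl), slopes (natural), log(V), log(omega), log(sigma)
  p_names <- c("theta_cl", names(slopes0), "volume", "omega_cl", "sigma_prop")
  t0 <- c(log(init$theta_cl), slopes0, log(init$volume), log(om0), log(sig0))
  n_slope <- length(slopes0)
  idx_slope <- if (n_slope) 1 + seq_len(n_slope) else integer(0)
  untransform <- function(t) {
    th <- exp(t[1]); sl <- t[idx_slope]
    v <- exp(t[2 + n_slope]); om <- exp(t[3 + n_slope]); sg <- exp(t[4 + n_slope])
    list(theta_cl = th, slopes = stats::setNames(sl, names(slopes0)),
         volume = v, omega = om, sigma = sg)
  }
  eta_env <- new.env(parent = emptyenv())
  eta_env$eta <- numeric(des$n_sub)
  obj_terms <- function(t, warm = TRUE) {
    p <- untransform(t)
    typ <- .typ_cl(des, p$theta_cl, p$slopes, refs)
    if (any(typ < 0.01))
      return(rep(1e7 * (1 + sum(pmax(0.01 - typ, 0))), des$n_sub))
    sig2 <- p$sigma^2; om2 <- p$omega^2
    eta <- .solve_etas(des, typ, p$volume, sig2, om2,
                       eta_start = if (warm) eta_env$eta else NULL,
                       tol = control$inner_tol)
    terms <- .foce_ofv_terms(des, eta, typ, p$volume, sig2, om2)
    if (any(!is.finite(terms))) return(rep(1e7, des$n_sub))
    eta_env$eta <- eta
    attr(terms, "etas") <- eta
    terms
  }
  obj <- function(t) sum(obj_terms(t))
  opt <- stats::optim(t0, obj, method = "Nelder-Mead",
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))
  # polish: restart the simplex at the solution; convergence is declared
  # when the restart cannot improve the OFV beyond numerical noise
  polish <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                         control = list(maxit = control$maxit,
                                        reltol = control$reltol))
  improve <- opt$value - polish$value
  if (polish$value <= opt$value) opt <- polish
  converged <- polish$convergence == 0 || improve < 0.01
  tries <- 0
  while (!converged && tries < control$restart) {
    tries <- tries + 1
    t_re <- opt$par * (1 + 0.05 * rep_len(c(1, -1), length(opt$par)))
    opt2 <- stats::optim(t_re, obj, method = "Nelder-Mead",
                         control = list(maxit = control$maxit,
                                        reltol = control$reltol))
    if (opt2$value <= opt$value - 0.01) {
      opt <- opt2
    } else {
      converged <- TRUE
      if (opt2$value < opt$value) opt <- opt2
    }
  }
  t_hat <- opt$par
  terms <- obj_terms(t_hat, warm = FALSE)
  ofv <- sum(terms)
  etas <- stats::setNames(attr(terms, "etas"), des$ids)
  p <- untransform(t_hat)
  model <- pop_model(theta_cl = p$theta_cl, volume = p$volume,
                     omega_cl = p$omega, sigma_prop = p$sigma,
                     covariates = if (n_slope) p$slopes else NULL,
                     refs = if (n_slope) refs else NULL)
  n_par <- length(t_hat)
  aic <- ofv + 2 * n_par
  bic <- ofv + n_par * log(des$n_obs)
  ses <- .foce_se(t_hat, obj, obj_terms, untransform, idx_slope, n_slope)
  coefs <- c(p$theta_cl, p$slopes, p$volume, p$omega, p$sigma)
  names(coefs) <- p_names
  # shrinkage
  iwres <- .iwres(des, etas, .typ_cl(des, p$theta_cl, p$slopes, refs),
                  p$volume, p$sigma)
  eta_shr <- if (p$omega > 0) 100 * (1 - stats::sd(etas) / p$omega) else NA_real_
  eps_shr <- 100 * (1 - stats::sd(iwres))
  structure(list(model = model, coefficients = coefs, se = ses$se,
                 rse = ses$rse, vcov = ses$vcov, ofv = ofv, aic = aic,
                 bic = bic, etas = etas, eta_shrinkage = eta_shr,
                 eps_shrinkage = eps_shr, converged = converged,
                 n_obs = des$n_obs, n_subjects = des$n_sub,
                 n_par = n_par, cohort = cohort,
                 covariate_names = covariates, refs = refs,
                 optim = opt[c("convergence", "counts", "message")],
                 call = match.call()),
            class = "foce_fit")
}

.iwres <- function(des, etas, typ, v, sigma) {
  f <- .conc_design(des, typ * exp(etas), v)
  (des$y - f) / (sigma * f + 1e-12)
}

# Sandwich standard errors on the transformed scale; RSE in percent on the
# natural scale (for log-parameters the transformed SE is already the
# relative SE).
.foce_se <- function(t_hat, obj, obj_terms, untransform, idx_slope, n_slope) {
  n_par <- length(t_hat)
  res <- list(se = rep(NA_real_, n_par), rse = rep(NA_real_, n_par),
              vcov = matrix(NA_real_, n_par, n_par))
  H <- try(stats::optimHess(t_hat, obj), silent = TRUE)
  if (inherits(H, "try-error")) return(res)
  h <- 1e-4
  Sc <- matrix(0, length(obj_terms(t_hat)), n_par)
  for (j in seq_len(n_par)) {
    tp <- t_hat; tp[j] <- tp[j] + h
    tm <- t_hat; tm[j] <- tm[j] - h
    Sc[, j] <- (obj_terms(tp) - obj_terms(tm)) / (2 * h)
  }
  A <- H / 2                      # -(Hessian of ll)
  B <- crossprod(Sc / 2)          # sum of per-subject ll score outer products
  cov_t <- try(solve(A) %*% B %*% solve(A), silent = TRUE)
  if (inherits(cov_t, "try-error") || any(!is.finite(diag(cov_t))) ||
      any(diag(cov_t) < 0))
    cov_t <- try(2 * solve(H), silent = TRUE)
  if (inherits(cov_t, "try-error") || any(diag(cov_t) < 0)) return(res)
  se_t <- sqrt(diag(cov_t))
  p <- untransform(t_hat)
  nat <- c(p$theta_cl, p$slopes, p$volume, p$omega, p$sigma)
  jac <- nat
  if (n_slope) jac[idx_slope] <- 1
  se_nat <- se_t * abs(jac)
  res$se <- se_nat
  res$rse <- 100 * se_nat / abs(nat)
  res$vcov <- cov_t * tcrossprod(jac)
  res
}
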