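#' Configuration of the synthetic ICU cohort generator
#'
#' The defaults emulate the modelled cohort of 83 critically ill patients:
#' covariate distributions matching the reported demographics (age 60.57 +/-
#' 14.64 years in 16-99, weight 64.11 +/- 11.21 kg in 40-110, 65.06% male,
#' serum creatinine log-normal around a median of 81 umol/L spanning 33-687,
#' creatinine clearance constrained to the observed 9.99-195.60 mL/min),
#' dosing of 600 mg every 12 h as 1-h infusions, sparse opportunistic
#' sampling averaging about 1.5 concentrations per patient with 80% troughs,
#' the published population PK model as the data-generating truth, the
#' published logistic model for toxicity outcomes, and a Weibull
#' time-to-myelosuppression distribution whose median onset day among cases
#' is about 12 days.
#'
#' @param n_patients Cohort size.
#' @param age_mean,age_sd,age_range Age distribution (years), truncated
#'   normal.
#' @param weight_mean,weight_sd,weight_range Weight (kg), truncated normal.
#' @param prop_male Probability of male sex.
#' @param height_mean,height_sd,height_range Height (cm), truncated normal.
#' @param scr_meanlog,scr_sdlog,scr_range Serum creatinine (umol/L),
#'   truncated log-normal.
#' @param crcl_range Admissible creatinine clearance (mL/min); covariate
#'   sets outside it are redrawn so the Cockcroft-Gault value stays
#'   internally consistent.
#' @param dose,interval,tinf Regimen policy (mg, h, h).
#' @param duration_meanlog,duration_sdlog,duration_range Treatment duration
#'   (days), rounded truncated log-normal.
#' @param mean_obs Average concentrations per patient (between 1 and 2: each
#'   patient gets one, plus a second with the excess probability).
#' @param trough_fraction Probability that an observation is a pre-dose
#'   trough (the remainder are end-of-infusion peaks).
#' @param jitter_h Uniform sampling-time jitter (h) mimicking opportunistic
#'   drawing, at most 15 min by default.
#' @param model The data-generating [pop_model()].
#' @param td The data-generating [logistic_td()] for outcomes.
#' @param event_shape,event_scale Weibull parameters of the day of
#'   myelosuppression onset among cases.
#' @param frac_thrombo_only,frac_both Split of myelosuppression cases into
#'   thrombocytopenia-only / both (remainder anemia-only), matching the
#'   reported 30 thrombocytopenia and 14 anemia among 34 cases.
#' @param lloq Assay lower limit of quantification (mg/L).
#' @param seed Master seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 83,
                          age_mean = 60.57, age_sd = 14.64,
                          age_range = c(16, 99),
                          weight_mean = 64.11, weight_sd = 11.21,
                          weight_range = c(40, 110),
                          prop_male = 0.6506,
                          height_mean = 165, height_sd = 7,
                          height_range = c(143, 181),
                          scr_meanlog = log(81), scr_sdlog = 0.55,
                          scr_range = c(33, 687),
                          crcl_range = c(9.99, 195.60),
                          dose = 600, interval = 12, tinf = 1,
                          duration_meanlog = log(8), duration_sdlog = 0.45,
                          duration_range = c(4, 58),
                          mean_obs = 127 / 83,
                          trough_fraction = 0.8,
                          jitter_h = 0.25,
                          model = pop_model(),
                          td = logistic_td(),
                          event_shape = 1.8, event_scale = 14,
                          frac_thrombo_only = 20 / 34, frac_both = 10 / 34,
                          lloq = 0.1,
                          seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_patients >= 0, mean_obs >= 1, mean_obs <= 2,
            trough_fraction >= 0, trough_fraction <= 1,
            prop_male >= 0, prop_male <= 1,
            event_shape > 0, event_scale > 0,
            frac_thrombo_only + frac_both <= 1,
            all(is.finite(unlist(cfg[vapply(cfg, is.numeric, logical(1))]))))
  structure(cfg, class = "cohort_config")
}

rtrunc <- function(n, draw, lo, hi) {
  out <- draw(n)
  bad <- which(out < lo | out > hi)
  it <- 0
  while (length(bad)) {
    out[bad] <- draw(length(bad))
    bad <- bad[out[bad] < lo | out[bad] > hi]
    it <- it + 1
    if (it > 1000) stop("infeasible truncation bounds")
  }
  out
}

#' Sample internally consistent covariate sets
#'
#' Draws age, sex, weight, height and serum creatinine from the configured
#' truncated distributions and recomputes creatinine clearance by
#' Cockcroft-Gault; covariate sets whose clearance falls outside the
#' admissible range are redrawn, so the covariates remain mutually
#' consistent.
#'
#' @param config A [cohort_config()].
#' @param seed RNG seed (default: the config's master seed).
#' @return Data frame with `id`, `sex`, `age`, `weight`, `height`, `scr`,
#'   `crcl`.
#' @export
sample_covariates <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_patients
  if (n == 0)
    return(data.frame(id = integer(), sex = character(), age = numeric(),
                      weight = numeric(), height = numeric(), scr = numeric(),
                      crcl = numeric()))
  draw_one <- function(m) {
    age <- rtrunc(m, function(k) stats::rnorm(k, config$age_mean, config$age_sd),
                  config$age_range[1], config$age_range[2])
    wt <- rtrunc(m, function(k) stats::rnorm(k, config$weight_mean, config$weight_sd),
                 config$weight_range[1], config$weight_range[2])
    ht <- rtrunc(m, function(k) stats::rnorm(k, config$height_mean, config$height_sd),
                 config$height_range[1], config$height_range[2])
    sex <- ifelse(stats::runif(m) < config$prop_male, "male", "female")
    scr <- rtrunc(m, function(k) stats::rlnorm(k, config$scr_meanlog, config$scr_sdlog),
                  config$scr_range[1], config$scr_range[2])
    data.frame(sex = sex, age = age, weight = wt, height = ht, scr = scr,
               crcl = cockcroft_gault(age, wt, scr, sex),
               stringsAsFactors = FALSE)
  }
  out <- draw_one(n)
  bad <- which(out$crcl < config$crcl_range[1] | out$crcl > config$crcl_range[2])
  it <- 0
  while (length(bad)) {
    out[bad, ] <- draw_one(length(bad))
    bad <- bad[out$crcl[bad] < config$crcl_range[1] |
               out$crcl[bad] > config$crcl_range[2]]
    it <- it + 1
    if (it > 1000) stop("infeasible truncation bounds")
  }
  cbind(id = seq_len(n), out)
}

#' Generate a synthetic cohort
#'
#' Builds a complete cohort with the statistical structure the analysis
#' assumes: consistent covariates; a 600 mg q12h 1-h-infusion dose history
#' over the drawn treatment duration; sparse opportunistic observation
#' times (mostly steady-state pre-dose troughs, some end-of-infusion peaks,
#' both jittered); concentrations from the data-generating model with
#' log-normal between-subject variability on clearance and proportional
#' residual error, left-censored at the assay quantification limit;
#' myelosuppression outcomes drawn from the logistic toxicity model at each
#' subject's true steady-state trough; onset days from the Weibull
#' event-time model for cases (therapy extended to cover the event, as
#' clinicians treat until toxicity emerges) and censoring at end of therapy
#' otherwise; and hematology baselines/nadirs constructed to be consistent
#' with the outcome labels.
#'
#' @param config A [cohort_config()].
#' @param seed RNG seed (default: the config's master seed).
#' @return A [pk_cohort()].
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  covs <- sample_covariates(config, seed)
  # continue the RNG stream started by sample_covariates
  model <- config$model
  td <- config$td
  reg <- regimen(config$dose, config$interval, config$tinf)
  patients <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    cv <- covs[i, ]
    eta <- stats::rnorm(1, 0, model$omega_cl)
    params <- individual_params(model, cv$crcl, eta)
    duration <- round(rtrunc(1, function(k)
      stats::rlnorm(k, config$duration_meanlog, config$duration_sdlog),
      config$duration_range[1], config$duration_range[2]))
    cmin_true <- steady_state_cmin(reg, params)
    case <- stats::runif(1) < prob_myelosuppression(td, cmin_true)
    event_day <- NA_real_
    if (case) {
      event_day <- max(1, round(stats::rweibull(1, config$event_shape,
                                                config$event_scale)))
      event_day <- min(event_day, config$duration_range[2])
      duration <- max(duration, event_day)
    }
    n_dose <- duration * 24 / config$interval
    doses <- dose_events(time = (seq_len(n_dose) - 1) * config$interval,
                         amount = config$dose, duration = config$tinf)
    obs <- .sample_observations(config, doses, params)
    outcome <- if (!case) "none" else {
      u <- stats::runif(1)
      if (u < config$frac_thrombo_only) "thrombocytopenia"
      else if (u < config$frac_thrombo_only + config$frac_both) "both"
      else "anemia"
    }
    hema <- .sample_hematology(outcome)
    patients[[i]] <- pk_patient(
      id = cv$id, sex = cv$sex, age = cv$age, weight = cv$weight,
      height = cv$height, scr = cv$scr, crcl = cv$crcl,
      doses = doses, obs = obs, hematology = hema, outcome = outcome,
      event_time = if (case) event_day else duration,
      censored = !case, duration_days = duration)
    patients[[i]]$eta_true <- eta
    patients[[i]]$cmin_true <- cmin_true
  }
  pk_cohort(patients)
}

# Sparse opportunistic TDM design: steady state is assumed from day 3
# (dose 7 onward); troughs are drawn just before a dose, peaks just after
# the end of an infusion.
.sample_observations <- function(config, doses, params) {
  n_obs <- 1L + stats::rbinom(1, 1, config$mean_obs - 1)
  n_dose <- nrow(doses)
  first_ss <- min(ceiling(72 / config$interval) + 1, n_dose)
  pool <- seq(first_ss, n_dose)
  occasions <- sort(pool[sample.int(length(pool), n_obs,
                                    replace = length(pool) < n_obs)])
  t_obs <- numeric(n_obs); kind <- character(n_obs)
  for (j in seq_len(n_obs)) {
    dtime <- doses$time[occasions[j]]
    if (stats::runif(1) < config$trough_fraction) {
      t_obs[j] <- dtime - stats::runif(1, 0, config$jitter_h)
      kind[j] <- "trough"
    } else {
      t_obs[j] <- dtime + doses$duration[occasions[j]] +
        stats::runif(1, 0, config$jitter_h)
      kind[j] <- "peak"
    }
  }
  ord <- order(t_obs)
  t_obs <- t_obs[ord]; kind <- kind[ord]
  f <- conc_profile(t_obs, doses, params)
  conc <- f * (1 + stats::rnorm(n_obs, 0, config$model$sigma_prop))
  conc <- pmax(conc, 0)
  bql <- conc < config$lloq
  conc[bql] <- config$lloq
  data.frame(time = t_obs, conc = conc, mdv = 0L, bql = bql, kind = kind,
             stringsAsFactors = FALSE)
}

# Hematology consistent with the outcome label.  Baselines respect the
# eligibility screen (platelets >= 75e9/L etc.); nadirs below 75e9/L can
# occur.  For a thrombocytopenia label the nadir satisfies both the < 125
# and the >= 25% drop rule by construction; for "none"/anemia-only the
# platelet drop stays under 25%.
.sample_hematology <- function(outcome) {
  plt0 <- rtrunc(1, function(k) stats::rlnorm(k, log(232), 0.35), 75, 658)
  hb0 <- rtrunc(1, function(k) stats::rnorm(k, 99, 18), 68, 170)
  anc0 <- rtrunc(1, function(k) stats::rlnorm(k, log(4000), 0.5), 500, 30000)
  tbil0 <- rtrunc(1, function(k) stats::rlnorm(k, log(0.6), 0.6), 0.05, 5)
  thrombo <- outcome %in% c("thrombocytopenia", "both")
  anemia <- outcome %in% c("anemia", "both")
  nadir_plt <- if (thrombo) {
    min(plt0 * (1 - stats::runif(1, 0.30, 0.75)), stats::runif(1, 60, 124))
  } else plt0 * (1 - stats::runif(1, 0, 0.20))
  nadir_hb <- if (anemia) hb0 * (1 - stats::runif(1, 0.25, 0.45))
              else hb0 * (1 - stats::runif(1, 0, 0.20))
  hematology(baseline_plt = plt0, nadir_plt = nadir_plt,
             baseline_hb = hb0, nadir_hb = nadir_hb,
             baseline_anc = anc0, baseline_tbil_xuln = tbil0)
}
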