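#' Cockcroft-Gault creatinine clearance
#'
#' `CrCL (mL/min) = (140 - age) * weight / (72 * SCr_mg/dL)`, multiplied by
#' 0.85 for females.  Serum creatinine is taken in umol/L and converted to
#' mg/dL by dividing by 88.4.
#'
#' @param age Age (years), must be below 140.
#' @param weight Total body weight (kg), positive.
#' @param scr Serum creatinine (umol/L), positive.
#' @param sex `"male"`/`"female"` (or 0/1 file coding).
#' @return Creatinine clearance (mL/min). Vectorised.
#' @examples
#' cockcroft_gault(40, 70, 88.4, "male")    # 97.22
#' cockcroft_gault(40, 70, 88.4, "female")  # 82.64
#' @export
cockcroft_gault <- function(age, weight, scr, sex) {
  if (any(weight <= 0)) stop("'weight' must be positive")
  if (any(scr <= 0)) stop("'scr' must be positive")
  if (any(age >= 140)) {
    if (any(age > 140)) stop("'age' must be below 140 years")
  }
  sex <- decode_sex(sex)
  crcl <- (140 - age) * weight / (72 * scr / 88.4)
  crcl * ifelse(sex == "female", 0.85, 1)
}

decode_sex <- function(sex) {
  if (is.numeric(sex)) {
    if (any(!sex %in% c(0, 1))) stop("numeric sex coding must be 0 (male) or 1 (female)")
    return(ifelse(sex == 1, "female", "male"))
  }
  sex <- as.character(sex)
  if (any(!sex %in% c("male", "female")))
    stop("'sex' must be \"male\" or \"female\"")
  sex
}

#' Hematology record
#'
#' Baseline and nadir hematological parameters for one patient.  Baselines
#' are the values at initiation of therapy; nadirs are the lowest values
#' observed at or after the start of therapy.
#'
#' @param baseline_plt,nadir_plt Platelet count (1e9 cells/L).
#' @param baseline_hb,nadir_hb Hemoglobin (g/L).
#' @param baseline_anc Absolute neutrophil count (cells/uL).
#' @param baseline_tbil_xuln Total bilirubin as a multiple of the upper limit
#'   of normal.
#' @return A list of class `hematology`.
#' @export
hematology <- function(baseline_plt, nadir_plt = NA_real_,
                       baseline_hb = NA_real_, nadir_hb = NA_real_,
                       baseline_anc = NA_real_, baseline_tbil_xuln = NA_real_) {
  vals <- c(baseline_plt, nadir_plt, baseline_hb, nadir_hb,
            baseline_anc, baseline_tbil_xuln)
  if (any(vals < 0, na.rm = TRUE)) stop("hematology values must be non-negative")
  structure(list(baseline_plt = baseline_plt, nadir_plt = nadir_plt,
                 baseline_hb = baseline_hb, nadir_hb = nadir_hb,
                 baseline_anc = baseline_anc,
                 baseline_tbil_xuln = baseline_tbil_xuln),
            class = "hematology")
}

#' Patient record
#'
#' One subject's covariates, dose history, concentration observations,
#' hematology and toxicity outcome.  `crcl` defaults to the Cockcroft-Gault
#' value computed from the other covariates.
#'
#' @param id Subject identifier (unique within a cohort).
#' @param sex `"male"` or `"female"`.
#' @param age,weight,height,scr Covariates (years, kg, cm, umol/L).
#' @param doses Dose-event data frame ([dose_events()]).
#' @param obs Observation data frame with columns `time` (h), `conc` (mg/L),
#'   `mdv` (0/1), `bql` (logical, below 0.1 mg/L), `kind`
#'   (`"trough"`/`"peak"`/`"other"`).
#' @param crcl Creatinine clearance (mL/min); computed if `NULL`.
#' @param hematology A [hematology()] record or `NULL`.
#' @param outcome `"none"`, `"thrombocytopenia"`, `"anemia"` or `"both"`,
#'   or `NA`.
#' @param event_time Days from start of therapy to myelosuppression (or
#'   censoring).
#' @param censored Logical; `TRUE` when no event was observed.
#' @param duration_days Treatment duration (days).
#' @param covariates Optional named list of additional covariates (used by
#'   covariate screening).
#' @return A list of class `pk_patient`.
#' @export
pk_patient <- function(id, sex, age, weight, height = NA_real_, scr,
                       doses, obs = NULL, crcl = NULL, hematology = NULL,
                       outcome = NA_character_, event_time = NA_real_,
                       censored = NA, duration_days = NA_real_,
                       covariates = list()) {
  sex <- decode_sex(sex)
  if (is.null(crcl)) crcl <- cockcroft_gault(age, weight, scr, sex)
  if (crcl <= 0) stop("'crcl' must be positive")
  if (is.null(obs)) {
    obs <- data.frame(time = numeric(), conc = numeric(), mdv = integer(),
                      bql = logical(), kind = character())
  }
  if (nrow(obs) && nrow(doses) && min(obs$time) < min(doses$time))
    stop("at least one dose must precede every observation")
  if (is.na(duration_days) && nrow(doses))
    duration_days <- (max(doses$time) + doses$duration[which.max(doses$time)]) / 24
  structure(list(id = id, sex = sex, age = age, weight = weight,
                 height = height, scr = scr, crcl = crcl, doses = doses,
                 obs = obs, hematology = hematology, outcome = outcome,
                 event_time = event_time, censored = censored,
                 duration_days = duration_days, covariates = covariates),
            class = "pk_patient")
}

#' Cohort of patient records
#'
#' @param patients List of [pk_patient()] records with unique ids.
#' @return A list of class `pk_cohort`.
#' @export
pk_cohort <- function(patients) {
  ids <- vapply(patients, function(p) as.character(p$id), character(1))
  if (anyDuplicated(ids)) stop("patient ids must be unique")
  structure(patients, class = "pk_cohort", names = ids)
}

#' @export
print.pk_cohort <- function(x, ...) {
  n_obs <- sum(vapply(x, function(p) sum(p$obs$mdv == 0), integer(1)))
  cat(sprintf("PK cohort: %d patients, %d observations\n", length(x), n_obs))
  invisible(x)
}

#' @export
`[.pk_cohort` <- function(x, i) {
  pk_cohort(unclass(x)[i])
}

.nm_required <- c("ID", "TIME", "AMT", "RATE", "DV", "EVID", "MDV")
.nm_covs <- c("AGE", "SEX", "WT", "HT", "SCR", "CRCL")
LLOQ <- 0.1

#' Read a longitudinal PK dataset in NONMEM column conventions
#'
#' Expects a CSV with columns `ID, TIME, AMT, RATE, DV, EVID, MDV` plus
#' covariate columns `AGE, SEX, WT, HT, SCR` (`CRCL` optional; recomputed by
#' Cockcroft-Gault when absent).  Missing values are coded `"."`.  `EVID = 1`
#' rows become dose events with infusion duration `AMT/RATE` (1 h when RATE
#' is missing); `EVID = 0` rows become observations, those with `MDV = 1`
#' carried but ignored in fitting.  Concentrations below 0.1 mg/L (the assay
#' lower limit of quantification) are flagged below-quantification.
#'
#' @param path CSV file path.
#' @return A [pk_cohort()].
#' @export
read_pk_dataset <- function(path) {
  df <- utils::read.csv(path, na.strings = c(".", "NA"), stringsAsFactors = FALSE)
  missing_cols <- setdiff(.nm_required, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  patients <- lapply(split(df, factor(df$ID, levels = unique(df$ID))), .parse_subject)
  pk_cohort(patients)
}

.parse_subject <- function(d) {
  if (any(diff(d$TIME) < 0))
    stop("non-monotone TIME within ID ", d$ID[1])
  is_dose <- d$EVID == 1
  is_obs <- d$EVID == 0
  if (any(is_obs & d$MDV == 0 & is.na(d$DV)))
    stop("observation row with missing DV and MDV=0 for ID ", d$ID[1])
  dd <- d[is_dose, , drop = FALSE]
  dur <- ifelse(!is.na(dd$RATE) & dd$RATE > 0, dd$AMT / dd$RATE, 1)
  doses <- dose_events(time = dd$TIME, amount = dd$AMT, duration = dur)
  od <- d[is_obs, , drop = FALSE]
  conc <- od$DV
  obs <- data.frame(time = od$TIME, conc = conc, mdv = od$MDV,
                    bql = !is.na(conc) & conc < LLOQ,
                    kind = .infer_kind(od$TIME, doses),
                    stringsAsFactors = FALSE)
  cov1 <- function(nm, default = NA_real_) {
    if (!nm %in% names(d)) return(default)
    v <- d[[nm]][!is.na(d[[nm]])]
    if (!length(v)) return(default)
    if (length(unique(v)) > 1)
      stop("covariate ", nm, " not constant within ID ", d$ID[1])
    v[1]
  }
  crcl <- cov1("CRCL")
  pk_patient(id = d$ID[1], sex = decode_sex(cov1("SEX", 0)),
             age = cov1("AGE"), weight = cov1("WT"), height = cov1("HT"),
             scr = cov1("SCR"), doses = doses, obs = obs,
             crcl = if (is.na(crcl)) NULL else crcl)
}

.infer_kind <- function(times, doses) {
  if (!length(times)) return(character())
  vapply(times, function(t) {
    prev <- doses[doses$time <= t, , drop = FALSE]
    nxt <- doses$time[doses$time > t]
    if (nrow(prev)) {
      last <- prev[which.max(prev$time), ]
      if (t >= last$time + last$duration && t <= last$time + last$duration + 0.5)
        return("peak")
    }
    if (length(nxt) && (min(nxt) - t) <= 0.5) return("trough")
    "other"
  }, character(1))
}

#' Write a cohort back to the NONMEM CSV dialect
#'
#' Inverse of [read_pk_dataset()]: emits `ID, TIME, AMT, RATE, DV, EVID, MDV`
#' plus covariate columns, missing values as `"."`, numeric fields at full
#' precision so that read/write round-trips.
#'
#' @param cohort A [pk_cohort()].
#' @param path Output CSV file path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(cohort, path) {
  rows <- lapply(cohort, function(p) {
    drows <- data.frame(ID = p$id, TIME = p$doses$time, AMT = p$doses$amount,
                        RATE = p$doses$amount / p$doses$duration,
                        DV = NA_real_, EVID = 1L, MDV = 1L)
    orows <- if (nrow(p$obs)) {
      data.frame(ID = p$id, TIME = p$obs$time, AMT = NA_real_,
                 RATE = NA_real_, DV = p$obs$conc, EVID = 0L, MDV = p$obs$mdv)
    } else NULL
    out <- rbind(drows, orows)
    out <- out[order(out$TIME, -out$EVID), ]
    out$AGE <- p$age; out$SEX <- if (p$sex == "female") 1L else 0L
    out$WT <- p$weight; out$HT <- p$height; out$SCR <- p$scr
    out$CRCL <- p$crcl
    out
  })
  df <- do.call(rbind, rows)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    out <- vapply(x, function(v)
      if (is.na(v)) "." else format(v, digits = 17, scientific = FALSE),
      character(1))
    out
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-patient outcome table
#'
#' Companion export for toxicity analyses: `ID, OUTCOME, EVENT_DAY, CENSORED`.
#'
#' @inheritParams write_pk_dataset
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(cohort, path) {
  df <- data.frame(
    ID = vapply(cohort, function(p) p$id, vector(mode = mode(cohort[[1]]$id), 1)),
    OUTCOME = vapply(cohort, function(p) p$outcome, character(1)),
    EVENT_DAY = vapply(cohort, function(p) p$event_time, numeric(1)),
    CENSORED = vapply(cohort, function(p) as.integer(p$censored), integer(1)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export one patient record as JSON
#'
#' @param patient A [pk_patient()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
patient_to_json <- function(patient, path = NULL) {
  p <- unclass(patient)
  if (!is.null(p$hematology)) p$hematology <- unclass(p$hematology)
  js <- jsonlite::toJSON(p, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Screen a patient against the study eligibility criteria
#'
#' Exclusions: baseline platelets below 75e9/L; baseline hemoglobin below
#' 6.8 g/dL for males or 6 g/dL for females; baseline absolute neutrophil
#' count below 500 cells/uL; baseline total bilirubin above 5 times the upper
#' limit of normal; treatment duration under 3 days.  All failed criteria are
#' reported.  Missing baselines make the record unassessable rather than
#' silently eligible.
#'
#' @param patient A [pk_patient()] with a [hematology()] record.
#' @return List with `eligible` (logical, `NA` when unassessable) and
#'   `reasons` (character vector of failed criteria).
#' @export
screen_eligibility <- function(patient) {
  h <- patient$hematology
  need <- c(plt = h$baseline_plt, hb = h$baseline_hb, anc = h$baseline_anc,
            tbil = h$baseline_tbil_xuln, dur = patient$duration_days)
  if (is.null(h) || any(is.na(need)))
    return(list(eligible = NA,
                reasons = paste0("unassessable: missing ",
                                 paste(names(need)[is.na(need)], collapse = ", "))))
  reasons <- character()
  if (h$baseline_plt < 75) reasons <- c(reasons, "PLT")
  hb_dl <- h$baseline_hb / 10  # g/L -> g/dL
  if ((patient$sex == "male" && hb_dl < 6.8) ||
      (patient$sex == "female" && hb_dl < 6)) reasons <- c(reasons, "Hb")
  if (h$baseline_anc < 500) reasons <- c(reasons, "ANC")
  if (h$baseline_tbil_xuln > 5) reasons <- c(reasons, "TBIL")
  if (patient$duration_days < 3) reasons <- c(reasons, "duration")
  list(eligible = length(reasons) == 0, reasons = reasons)
}

#' Classify hematological toxicity
#'
#' Thrombocytopenia: nadir platelets below 125e9/L *and* a relative drop of
#' at least 25% from baseline.  Anemia: a relative hemoglobin drop of at
#' least 25% from baseline.  The two calls are independent; both together
#' yield `"both"`.
#'
#' @param h A [hematology()] record with positive baselines.
#' @return One of `"none"`, `"thrombocytopenia"`, `"anemia"`, `"both"`.
#' @export
classify_myelosuppression <- function(h) {
  if (is.na(h$baseline_plt) || h$baseline_plt <= 0)
    stop("baseline platelet count must be positive")
  thrombo <- !is.na(h$nadir_plt) && h$nadir_plt < 125 &&
    (h$baseline_plt - h$nadir_plt) / h$baseline_plt >= 0.25
  anemia <- FALSE
  if (!is.na(h$baseline_hb) && !is.na(h$nadir_hb)) {
    if (h$baseline_hb <= 0) stop("baseline hemoglobin must be positive")
    anemia <- (h$baseline_hb - h$nadir_hb) / h$baseline_hb >= 0.25
  }
  if (thrombo && anemia) "both"
  else if (thrombo) "thrombocytopenia"
  else if (anemia) "anemia"
  else "none"
}

#' Attach an extra covariate to every patient in a cohort
#'
#' Convenience used by covariate screening (e.g. to add a candidate
#' covariate).
#'
#' @param cohort A [pk_cohort()].
#' @param name Covariate name.
#' @param values Numeric vector, one value per patient, cohort order.
#' @return The modified cohort.
#' @export
set_covariate <- function(cohort, name, values) {
  stopifnot(length(values) == length(cohort))
  for (i in seq_along(cohort)) cohort[[i]]$covariates[[name]] <- values[i]
  pk_cohort(unclass(cohort))
}

patient_covariate <- function(patient, name) {
  if (name %in% c("crcl", "age", "weight", "height", "scr"))
    return(patient[[name]])
  v <- patient$covariates[[name]]
  if (is.null(v)) stop("covariate '", name, "' not found for patient ", patient$id)
  v
}
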