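# Small cohorts and fixture files built in code for the tests.

# A deterministic q12h dosing history of n_doses 600-mg 1-h infusions.
toy_doses <- function(n_doses = 12, dose = 600, interval = 12, tinf = 1) {
  dose_events(time = (seq_len(n_doses) - 1) * interval, amount = dose,
              duration = tinf)
}

# One subject with observations simulated from the model at given times.
toy_patient <- function(id, crcl, eta, model = pop_model(),
                        t_obs = c(133.1, 143.9), noise_sd = model$sigma_prop,
                        n_doses = 12, scr = 80) {
  par <- individual_params(model, crcl, eta)
  doses <- toy_doses(n_doses)
  f <- conc_profile(t_obs, doses, par)
  conc <- f * (1 + stats::rnorm(length(f), 0, noise_sd))
  pk_patient(id = id, sex = "male", age = 60, weight = 65, scr = scr,
             crcl = crcl, doses = doses,
             obs = data.frame(time = t_obs, conc = conc, mdv = 0L,
                              bql = conc < 0.1,
                              kind = rep("other", length(t_obs))))
}

# A cohort of n such subjects with CrCL spread over the cohort range.
toy_cohort <- function(n = 20, model = pop_model(), seed = 1,
                       t_obs = c(133.1, 143.9), noise_sd = model$sigma_prop) {
  set.seed(seed)
  crcl <- stats::runif(n, 20, 150)
  eta <- stats::rnorm(n, 0, model$omega_cl)
  pk_cohort(lapply(seq_len(n), function(i)
    toy_patient(i, crcl[i], eta[i], model, t_obs, noise_sd)))
}

# A two-patient NONMEM-convention CSV fixture.
write_nm_fixture <- function(path) {
  lines <- c(
    "ID,TIME,AMT,RATE,DV,EVID,MDV,AGE,SEX,WT,HT,SCR,CRCL",
    "1,0,600,600,.,1,1,60,0,65,170,80,75.5",
    "1,12,600,600,.,1,1,60,0,65,170,80,75.5",
    "1,23.75,.,.,4.21,0,0,60,0,65,170,80,75.5",
    "1,24,600,600,.,1,1,60,0,65,170,80,75.5",
    "2,0,600,300,.,1,1,70,1,55,160,120,30.25",
    "2,12,600,300,.,1,1,70,1,55,160,120,30.25",
    "2,14.5,.,.,12.5,0,0,70,1,55,160,120,30.25",
    "2,23.8,.,.,6.25,0,0,70,1,55,160,120,30.25",
    "2,24,600,300,.,1,1,70,1,55,160,120,30.25")
  writeLines(lines, path)
  path
}
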