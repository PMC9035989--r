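test_that("NONMEM CSV parsing builds dose events and observations", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_nm_fixture(f)
  coh <- read_pk_dataset(f)
  expect_length(coh, 2)
  p1 <- coh[["1"]]
  expect_equal(p1$doses$amount, c(600, 600, 600))
  expect_equal(p1$doses$duration, c(1, 1, 1))  # duration = AMT/RATE
  p2 <- coh[["2"]]
  expect_equal(p2$doses$duration, c(2, 2, 2))  # 600/300
  expect_equal(p1$obs$conc, 4.21)
  expect_equal(p1$obs$kind, "trough")          # 15 min before the 24-h dose
  expect_equal(p2$obs$kind, c("peak", "trough"))
  expect_equal(p2$sex, "female")
  expect_equal(p2$crcl, 30.25)
})

test_that("dataset validation errors name the problem", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,AMT,RATE,EVID,MDV", "1,0,600,600,1,1"), f)
  expect_error(read_pk_dataset(f), "DV")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,AMT,RATE,DV,EVID,MDV",
               "1,0,600,600,.,1,1", "1,10,.,.,.,0,0"), f2)
  expect_error(read_pk_dataset(f2), "missing DV")
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,AMT,RATE,DV,EVID,MDV",
               "1,12,600,600,.,1,1", "1,0,600,600,.,1,1"), f3)
  expect_error(read_pk_dataset(f3), "non-monotone")
})

test_that("write/read round-trips a cohort exactly", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_nm_fixture(f)
  coh <- read_pk_dataset(f)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(coh, f2)
  coh2 <- read_pk_dataset(f2)
  for (i in seq_along(coh)) {
    for (field in c("age", "weight", "height", "scr", "crcl", "sex"))
      expect_identical(coh2[[i]][[field]], coh[[i]][[field]])
    expect_identical(coh2[[i]]$doses, coh[[i]]$doses)
    expect_identical(coh2[[i]]$obs$time, coh[[i]]$obs$time)
    expect_identical(coh2[[i]]$obs$conc, coh[[i]]$obs$conc)
  }
  # and the emitted CSV is itself stable under a second round trip
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(coh2, f3)
  expect_identical(readLines(f3), readLines(f2))
})

test_that("Cockcroft-Gault matches hand evaluation and guards inputs", {
  expect_equal(cockcroft_gault(40, 70, 88.4, "male"), 7000 / 72, tolerance = 1e-10)
  expect_equal(cockcroft_gault(40, 70, 88.4, "female"), 7000 / 72 * 0.85,
               tolerance = 1e-10)
  expect_equal(cockcroft_gault(140, 70, 88.4, "male"), 0)
  expect_equal(cockcroft_gault(40, 70, 88.4, 1),
               cockcroft_gault(40, 70, 88.4, "female"))
  expect_error(cockcroft_gault(40, 0, 88.4, "male"), "weight")
  expect_error(cockcroft_gault(40, 70, -1, "male"), "scr")
})

eligible_patient <- function(sex = "male", plt = 232, hb = 99, anc = 4000,
                             tbil = 1, duration = 8) {
  pk_patient(id = 1, sex = sex, age = 60, weight = 65, scr = 80,
             doses = toy_doses(duration * 2),
             hematology = hematology(baseline_plt = plt, baseline_hb = hb,
                                     baseline_anc = anc,
                                     baseline_tbil_xuln = tbil),
             duration_days = duration)
}

test_that("eligibility screen applies every exclusion and reports reasons", {
  expect_true(screen_eligibility(eligible_patient())$eligible)
  low_plt <- screen_eligibility(eligible_patient(plt = 74))
  expect_false(low_plt$eligible)
  expect_equal(low_plt$reasons, "PLT")
  low_hb <- screen_eligibility(eligible_patient(hb = 67))  # 6.7 g/dL, male
  expect_false(low_hb$eligible)
  expect_equal(low_hb$reasons, "Hb")
  # 6.7 g/dL is acceptable for females (threshold 6 g/dL)
  expect_true(screen_eligibility(eligible_patient(sex = "female", hb = 67))$eligible)
  multi <- screen_eligibility(eligible_patient(plt = 60, anc = 400,
                                               tbil = 6, duration = 2))
  expect_setequal(multi$reasons, c("PLT", "ANC", "TBIL", "duration"))
  unk <- screen_eligibility(eligible_patient(hb = NA))
  expect_true(is.na(unk$eligible))
  expect_match(unk$reasons, "unassessable")
})

test_that("the screen agrees with a literal re-reading on randomized inputs", {
  # oracle: an independent restatement of the five exclusion rules
  screen_oracle <- function(sex, plt, hb, anc, tbil, dur) {
    r <- character(0)
    if (plt < 75) r <- c(r, "PLT")
    if (hb / 10 < if (sex == "male") 6.8 else 6) r <- c(r, "Hb")
    if (anc < 500) r <- c(r, "ANC")
    if (tbil > 5) r <- c(r, "TBIL")
    if (dur < 3) r <- c(r, "duration")
    r
  }
  set.seed(6)
  for (i in 1:100) {
    sex <- sample(c("male", "female"), 1)
    plt <- runif(1, 40, 300); hb <- runif(1, 50, 150)
    anc <- runif(1, 200, 8000); tbil <- runif(1, 0.1, 8)
    dur <- sample(2:12, 1)
    got <- screen_eligibility(eligible_patient(sex = sex, plt = plt, hb = hb,
                                               anc = anc, tbil = tbil,
                                               duration = dur))
    want <- screen_oracle(sex, plt, hb, anc, tbil, dur)
    expect_identical(got$reasons, want)
    expect_identical(got$eligible, length(want) == 0)
  }
})

test_that("myelosuppression classification follows the literal rules", {
  expect_equal(classify_myelosuppression(
    hematology(baseline_plt = 232, nadir_plt = 120)), "thrombocytopenia")
  expect_equal(classify_myelosuppression(
    hematology(baseline_plt = 150, nadir_plt = 120)), "none")  # 20% drop
  expect_equal(classify_myelosuppression(
    hematology(baseline_plt = 232, nadir_plt = 200,
               baseline_hb = 99, nadir_hb = 70)), "anemia")    # 29.3% Hb drop
  # exactly 25% platelet drop but nadir >= 125: not thrombocytopenia
  expect_equal(classify_myelosuppression(
    hematology(baseline_plt = 232, nadir_plt = 174)), "none")
  expect_equal(classify_myelosuppression(
    hematology(baseline_plt = 300, nadir_plt = 100,
               baseline_hb = 100, nadir_hb = 70)), "both")
  expect_error(classify_myelosuppression(
    hematology(baseline_plt = 0, nadir_plt = 0)), "baseline")
})

test_that("classification agrees with an independent literal re-reading", {
  # oracle: a from-scratch restatement of the two rules
  oracle <- function(p0, p1, h0, h1) {
    t <- (p1 < 125) && ((p0 - p1) / p0 >= 0.25)
    a <- (h0 - h1) / h0 >= 0.25
    if (t && a) "both" else if (t) "thrombocytopenia" else if (a) "anemia" else "none"
  }
  set.seed(4)
  for (i in 1:200) {
    p0 <- runif(1, 75, 500); p1 <- runif(1, 20, p0)
    h0 <- runif(1, 68, 170); h1 <- runif(1, 40, h0)
    expect_identical(
      classify_myelosuppression(hematology(p0, p1, h0, h1)),
      oracle(p0, p1, h0, h1))
  }
})

test_that("lowering the platelet nadir never removes a thrombocytopenia call", {
  set.seed(5)
  for (i in 1:100) {
    p0 <- runif(1, 75, 500)
    nadirs <- sort(runif(5, 10, p0), decreasing = TRUE)
    calls <- vapply(nadirs, function(p1)
      classify_myelosuppression(hematology(p0, p1)) != "none", logical(1))
    expect_true(all(diff(calls) >= 0))  # once called, stays called
  }
})

test_that("patient JSON export carries the record", {
  p <- eligible_patient()
  js <- patient_to_json(p)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$crcl, p$crcl)
  expect_equal(back$hematology$baseline_plt, 232)
})
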