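test_that("noise-free data reproduce the generating structural parameters", {
  truem <- pop_model(omega_cl = 0, sigma_prop = 1e-6)
  coh <- generate_cohort(cohort_config(n_patients = 30, model = truem,
                                       seed = 21))
  fit <- suppressWarnings(foce_fit(coh, init = pop_model()))
  co <- coef(fit)
  expect_lt(abs(co[["theta_cl"]] - 3.66) / 3.66, 0.005)
  expect_lt(abs(co[["crcl"]] - 2.18) / 2.18, 0.005)
  expect_lt(abs(co[["volume"]] - 54) / 54, 0.005)
})

test_that("information criteria follow their definitions", {
  coh <- toy_cohort(12, seed = 2)
  fit <- suppressWarnings(foce_fit(coh, init = pop_model(),
                                   control = foce_control(maxit = 400)))
  expect_equal(fit$aic, fit$ofv + 2 * fit$n_par)
  expect_equal(fit$bic, fit$ofv + fit$n_par * log(fit$n_obs))
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), -(fit$ofv + fit$n_obs * log(2 * pi)) / 2)
  expect_equal(attr(ll, "df"), 5)
})

test_that("FOCE objective matches a brute-force quadrature marginal likelihood", {
  set.seed(42)
  m <- pop_model()
  pats <- lapply(1:5, function(i) {
    crcl <- runif(1, 30, 120)
    toy_patient(i, crcl, rnorm(1, 0, m$omega_cl), m,
                t_obs = c(11 * 12 + 1.1, 12 * 12 - 0.1))
  })
  coh <- pk_cohort(pats)
  ofv <- foce_ofv(m, coh)
  # oracle: one-dimensional quadrature of the exact marginal likelihood
  neg2ll <- 0
  for (p in coh) {
    typ <- typical_cl(m, p$crcl)
    lik <- integrate(function(etas) sapply(etas, function(eta) {
      f <- conc_profile(p$obs$time, p$doses,
                        list(cl = typ * exp(eta), volume = m$volume))
      prod(dnorm(p$obs$conc, f, m$sigma_prop * f)) *
        dnorm(eta, 0, m$omega_cl)
    }), lower = -2.5, upper = 2.5, rel.tol = 1e-10)$value
    neg2ll <- neg2ll - 2 * log(lik)
  }
  n_obs <- sum(vapply(coh, function(p) nrow(p$obs), integer(1)))
  expect_lt(abs(as.numeric(ofv) - (neg2ll - n_obs * log(2 * pi))), 2)
})

test_that("estimates are invariant to subject ordering", {
  coh <- toy_cohort(15, seed = 3)
  fit1 <- suppressWarnings(foce_fit(coh, init = pop_model()))
  fit2 <- suppressWarnings(foce_fit(coh[rev(seq_along(coh))],
                                    init = pop_model()))
  expect_equal(coef(fit1), coef(fit2), tolerance = 5e-3)
  expect_equal(fit1$ofv, fit2$ofv, tolerance = 1e-4)
})

test_that("the covariate model never fits worse than the nested base model", {
  coh <- toy_cohort(15, seed = 6)
  base <- suppressWarnings(foce_fit(coh, init = pop_model(covariates = NULL)))
  full <- suppressWarnings(foce_fit(coh, init = pop_model()))
  expect_lte(full$ofv, base$ofv + 1e-3)
})

test_that("degenerate inputs are rejected", {
  p <- toy_patient(1, 70, 0)
  p$obs$conc <- 0
  p$obs$bql <- FALSE
  expect_error(foce_fit(pk_cohort(list(p)), init = pop_model()),
               "all-zero")
  expect_error(foce_fit(pk_cohort(list()), init = pop_model()))
})

test_that("random-effect and residual methods are coherent", {
  coh <- toy_cohort(12, seed = 9)
  fit <- suppressWarnings(foce_fit(coh, init = pop_model()))
  et <- ranef(fit)
  expect_length(et, 12)
  shr <- shrinkage(fit)
  expect_equal(unname(shr["eta"]),
               100 * (1 - sd(et) / coef(fit)[["omega_cl"]]),
               tolerance = 1e-8)
  r <- residuals(fit, type = "cwres")
  expect_length(r, fit$n_obs)
  expect_true(all(is.finite(r)))
  pr <- predict(fit)
  expect_named(pr, c("id", "time", "tad", "dv", "pred", "ipred"))
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(fit$n_obs, 3))
  expect_identical(simulate(fit, nsim = 2, seed = 5),
                   simulate(fit, nsim = 2, seed = 5))
})

test_that("stepwise search returns the base model for no candidates", {
  coh <- toy_cohort(10, seed = 11)
  sw <- suppressWarnings(stepwise_covariates(coh, candidates = character(0),
                                             control = foce_control(maxit = 400)))
  expect_identical(sw$selected, character(0))
  expect_null(sw$final_fit$model$covariates)
})

test_that("collinear candidates are flagged, not silently fit", {
  coh <- toy_cohort(10, seed = 12)
  crcl <- vapply(coh, function(p) p$crcl, numeric(1))
  coh <- set_covariate(coh, "crcl_copy", crcl * 1.0001)
  expect_error(stepwise_covariates(coh, candidates = c("crcl", "crcl_copy")),
               "collinear")
})

test_that("model config round-trips through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("init:",
               "  theta_cl: 3.66", "  volume: 54",
               "  bsv_cl_cv: 36.30", "  prop_error_cv: 19.05",
               "  covariates: {crcl: 2.18}", "  refs: {crcl: 65}",
               "candidates: [crcl, age]",
               "forward_dofv: 3.84", "backward_dofv: 6.63"), f)
  cfg <- read_model_config(f)
  expect_equal(cfg$init$theta_cl, 3.66)
  expect_equal(cfg$init$covariates[["crcl"]], 2.18)
  expect_equal(cfg$init$omega_cl, cv_to_omega(36.30))
  expect_equal(cfg$init$sigma_prop, 0.1905)
  expect_equal(cfg$candidates, c("crcl", "age"))
  expect_equal(cfg$forward_dofv, 3.84)
})

test_that("fit reports are written as JSON and text", {
  coh <- toy_cohort(10, seed = 13)
  fit <- suppressWarnings(foce_fit(coh, init = pop_model(),
                                   control = foce_control(maxit = 400)))
  jf <- withr::local_tempfile(fileext = ".json")
  tf <- withr::local_tempfile(fileext = ".txt")
  write_fit_report(fit, json_path = jf, txt_path = tf)
  rep <- jsonlite::fromJSON(jf)
  expect_equal(rep$ofv, fit$ofv)
  expect_true(any(grepl("theta_cl", readLines(tf))))
})
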