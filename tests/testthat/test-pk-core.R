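test_that("typical clearance follows the covariate model", {
  m <- pop_model()
  expect_equal(typical_cl(m, 65), 5.84)
  expect_equal(typical_cl(m, 0), 3.66)
  expect_equal(typical_cl(m, 130), 8.02)
  expect_error(typical_cl(m, -1), "non-negative")
  # affine and strictly increasing in CrCL
  crcl <- seq(0, 200, by = 5)
  cl <- typical_cl(m, crcl)
  expect_true(all(diff(cl) > 0))
  expect_equal(max(abs(diff(diff(cl)))), 0, tolerance = 1e-12)
})

test_that("individual parameters apply the exponential random effect", {
  m <- pop_model()
  expect_equal(individual_params(m, 65, 0)$cl, typical_cl(m, 65))
  expect_equal(individual_params(m, 65, 0.3519)$cl, 5.84 * exp(0.3519),
               tolerance = 1e-10)
  expect_equal(individual_params(m, 65, 0.3519)$volume, 54)
  expect_error(individual_params(m, -1, 0), "non-negative")
})

test_that("closed-form infusion kinetics match a numerical ODE solution", {
  par <- list(cl = 5.84, volume = 54)
  d <- dose_events(0, 600, 1)
  expect_equal(conc_profile(1, d, par), (600 / 5.84) * (1 - exp(-5.84 / 54)),
               tolerance = 1e-10)
  expect_equal(conc_profile(0, d, par), 0)
  expect_equal(conc_profile(13, d, par),
               conc_profile(1, d, par) * exp(-5.84 / 54 * 12),
               tolerance = 1e-10)
  # oracle: numeric integration of dA/dt = rate(t) - k A over three doses
  d3 <- toy_doses(3)
  rate_fun <- function(t) sum(d3$amount[d3$time <= t & t < d3$time + d3$duration])
  deriv <- function(t, y, parms) list(rate_fun(t) - par$cl / par$volume * y)
  times <- seq(0, 36, by = 0.05)
  ode <- deSolve::lsoda(y = 0, times = times, func = deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-10)
  expect_equal(conc_profile(times, d3, par), ode[, 2] / par$volume,
               tolerance = 1e-6)
})

test_that("steady-state trough equals the superposition limit", {
  par <- list(cl = 6.175, volume = 54)
  reg <- regimen(600, 12, 1)
  expect_equal(steady_state_cmin(reg, par), 4.00, tolerance = 1e-3)
  # oracle: explicit superposition of 20 doses
  sup <- conc_profile(20 * 12, toy_doses(20), par)
  expect_equal(steady_state_cmin(reg, par), sup, tolerance = 1e-6)
  # bolus limit
  k <- par$cl / par$volume
  bolus <- (600 / 54) * exp(-k * 12) / (1 - exp(-k * 12))
  expect_equal(steady_state_cmin(regimen(600, 12, 1e-4), par), bolus,
               tolerance = 1e-3)
  # washout: the trough vanishes as the interval grows
  expect_lt(steady_state_cmin(regimen(600, 2000, 1), par), 1e-12)
  expect_error(steady_state_cmin(reg, list(cl = -1, volume = 54)), "positive")
})

test_that("superposition approaches the steady-state trough", {
  par <- list(cl = 6.175, volume = 54)
  t_half <- log(2) * par$volume / par$cl
  n <- ceiling(10 * t_half / 12) + 1
  sup <- conc_profile(n * 12, toy_doses(n), par)
  expect_equal(sup, steady_state_cmin(regimen(600, 12, 1), par),
               tolerance = 5e-3)
  # concentrations are non-negative everywhere
  tt <- seq(0, n * 12, by = 0.25)
  expect_true(all(conc_profile(tt, toy_doses(n), par) >= 0))
})

test_that("steady-state AUC24 is daily dose over clearance", {
  expect_equal(steady_state_auc24(regimen(600, 12, 1), list(cl = 6, volume = 54)),
               200)
  expect_equal(steady_state_auc24(regimen(0, 12, 1), list(cl = 6, volume = 54)),
               0)
  # agreement with the trapezoid on a fine steady-state grid
  par <- list(cl = 6.175, volume = 54)
  doses <- toy_doses(20)
  grid <- seq(19 * 12 - 12, 19 * 12 + 12, by = 1 / 6)
  auc_grid <- auc_linlog(grid, conc_profile(grid, doses, par))
  expect_equal(auc_grid, steady_state_auc24(regimen(600, 12, 1), par),
               tolerance = 5e-3)
})

test_that("linear-up/log-down trapezoid handles each segment type", {
  expect_equal(auc_linlog(c(0, 1), c(10, 5)), 5 / log(2))
  expect_equal(auc_linlog(c(0, 1), c(5, 10)), 7.5)
  expect_equal(auc_linlog(c(0, 1, 2), c(10, 10, 10)), 20)
  expect_equal(auc_linlog(c(0, 1), c(10, 0)), 5)    # zero endpoint: linear guard
  expect_error(auc_linlog(c(1, 0), c(1, 2)), "increasing")
  expect_error(auc_linlog(c(0, 1), c(-1, 2)), "non-negative")
})

test_that("log-down trapezoid is near-exact on an exponential decay", {
  k <- 0.108
  tt <- seq(0, 24, by = 1 / 6)
  cc <- 12 * exp(-k * tt)
  exact <- 12 / k * (1 - exp(-k * 24))
  expect_equal(auc_linlog(tt, cc), exact, tolerance = 1e-4)
})

test_that("omega/%CV conversion matches the reported variability", {
  expect_equal(omega_to_cv(0.3519), 36.30, tolerance = 5e-4)
  expect_equal(omega_to_cv(0), 0)
  expect_equal(cv_to_omega(36.30), 0.3519, tolerance = 5e-4)
  expect_equal(cv_to_omega(omega_to_cv(0.77)), 0.77, tolerance = 1e-9)
  expect_error(omega_to_cv(-1), "non-negative")
})

test_that("regimen construction guards its invariants", {
  expect_error(regimen(600, 12, 13), "tinf < interval")
  expect_error(regimen(-1, 12, 1))
  expect_s3_class(regimen(600, 8), "regimen")
})
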