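test_that("the published logistic model evaluates as printed", {
  td <- logistic_td()
  expect_equal(prob_myelosuppression(td, 7.8), 0.496, tolerance = 1e-3)
  expect_equal(prob_myelosuppression(td, 0), 1 / (1 + exp(3.767)),
               tolerance = 1e-10)
  expect_equal(prob_myelosuppression(td, 12), 0.881, tolerance = 1e-3)
  expect_error(prob_myelosuppression(td, -1), "non-negative")
  cc <- seq(0, 25, by = 0.5)
  expect_true(all(diff(prob_myelosuppression(td, cc)) > 0))
})

test_that("the toxicity threshold inverts the logistic model", {
  td <- logistic_td()
  expect_identical(toxicity_threshold(td), 7.8)
  expect_equal(toxicity_threshold(td, digits = NULL), 3.767 / 0.481,
               tolerance = 1e-12)
  expect_equal(toxicity_threshold(logistic_td(0.7, 0.7)), 1.0)
  # oracle: numerical root of prob() - p
  for (p in c(0.2, 0.5, 0.9)) {
    root <- uniroot(function(x) prob_myelosuppression(td, x) - p,
                    c(0, 40), tol = 1e-10)$root
    expect_equal(toxicity_threshold(td, p, digits = NULL), root,
                 tolerance = 1e-6)
  }
  # identity prob(threshold(p)) = p across the unit interval
  for (p in seq(0.05, 0.95, by = 0.15))
    expect_equal(prob_myelosuppression(td, toxicity_threshold(td, p, NULL)),
                 p, tolerance = 1e-6)
  expect_error(toxicity_threshold(logistic_td(3, 1), p = 0))
})

test_that("logistic fitting is maximum likelihood with guards", {
  set.seed(51)
  cmin <- runif(300, 1, 15)
  y <- rbinom(300, 1, prob_myelosuppression(logistic_td(), cmin))
  fit <- fit_logistic(cmin, y)
  # score equation: mean fitted probability equals the event fraction
  expect_equal(mean(prob_myelosuppression(fit, cmin)), mean(y),
               tolerance = 1e-6)
  expect_error(fit_logistic(cmin, rep(0, 300)), "both outcome classes")
  sep_y <- as.integer(cmin > 5)
  expect_error(fit_logistic(cmin, sep_y), "separation")
})

test_that("the trough-AUC regression is ordinary least squares", {
  cmin <- c(1, 3, 5, 8, 12)
  auc <- 26.354 * cmin + 91.607
  # exact points: lm warns about the perfect fit, which is the point here
  fit <- suppressWarnings(fit_cmin_auc(cmin, auc))
  expect_equal(fit$slope, 26.354, tolerance = 1e-10)
  expect_equal(fit$intercept, 91.607, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  two <- fit_cmin_auc(c(2, 6), c(100, 300))
  expect_equal(two$r2, 1)
  expect_equal(predict_auc(two, 4, digits = NULL), 200)
  expect_error(fit_cmin_auc(c(3, 3), c(1, 2)), "distinct")
})

test_that("the therapeutic window matches the published bounds", {
  win <- therapeutic_window()
  expect_identical(win$lower, 2.6)
  expect_identical(win$upper, 7.8)
  expect_equal(predict_auc(exposure_regression(), 7.8), 297.2)
  # raising the AUC target raises the lower bound
  lows <- vapply(c(120, 160, 200, 240), function(a)
    therapeutic_window(eff = efficacy_target(auc_mic_target = a / 2, mic = 2),
                       digits = NULL)$lower, numeric(1))
  expect_true(all(diff(lows) > 0))
  expect_error(therapeutic_window(eff = efficacy_target(auc_mic_target = 150,
                                                        mic = 2)),
               "inconsistent")
  expect_equal(efficacy_target()$auc_target, 160)
})

test_that("the product-limit estimator matches hand computation", {
  km <- km_estimator(c(3, 12, 15), c(FALSE, FALSE, FALSE))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 12)
  cens <- km_estimator(c(5, 8, 11), c(TRUE, TRUE, TRUE))
  expect_true(all(cens$surv == 1))
  expect_true(is.na(cens$median))
  expect_error(km_estimator(numeric(0), logical(0)))
  expect_error(km_estimator(c(0, 3), c(FALSE, FALSE)), "positive")
})

test_that("the estimator agrees with a brute-force risk-set recomputation", {
  # oracle: direct product over event times of (1 - d_i / n_i)
  km_oracle <- function(time, censored) {
    ev <- sort(unique(time[!censored]))
    s <- 1
    out <- numeric(length(ev))
    for (i in seq_along(ev)) {
      n_i <- sum(time >= ev[i])
      d_i <- sum(time == ev[i] & !censored)
      s <- s * (1 - d_i / n_i)
      out[i] <- s
    }
    list(time = ev, surv = out,
         median = if (any(out <= 0.5)) ev[which(out <= 0.5)[1]] else NA_real_)
  }
  set.seed(52)
  for (r in 1:50) {
    n <- sample(5:40, 1)
    time <- sample(1:30, n, replace = TRUE)
    censored <- runif(n) < 0.4
    if (!any(!censored)) censored[1] <- FALSE
    km <- km_estimator(time, censored)
    or <- km_oracle(time, censored)
    at_events <- km$surv[match(or$time, km$time)]
    expect_equal(at_events, or$surv, tolerance = 1e-12)
    expect_equal(km$median, or$median)
  }
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(53)
  time <- sample(1:20, 30, replace = TRUE)
  km <- km_estimator(time, rep(FALSE, 30))
  emp <- vapply(km$time, function(t) mean(time > t), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("the toxicity report assembles counts, rates and models", {
  outcome <- c(rep("thrombocytopenia", 20), rep("both", 10),
               rep("anemia", 4), rep("none", 49))
  expect_equal(incidence(sum(outcome != "none"), length(outcome)), 40.96)
  expect_equal(incidence(30, 83), 36.14)
  expect_equal(incidence(14, 83), 16.87)
  f <- withr::local_tempfile(fileext = ".json")
  rep <- toxicity_report(outcome, cmin = NULL, auc = NULL,
                         event_time = c(rep(5, 34), rep(10, 49)),
                         censored = c(rep(FALSE, 34), rep(TRUE, 49)),
                         file = f)
  expect_equal(rep$myelosuppression$events, 34)
  expect_equal(rep$myelosuppression$pct, 40.96)
  expect_equal(rep$thrombocytopenia$pct, 36.14)
  expect_equal(rep$anemia$pct, 16.87)
  js <- jsonlite::fromJSON(f)
  expect_equal(js$myelosuppression$events, 34)
})
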