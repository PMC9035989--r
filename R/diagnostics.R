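#' Nonparametric bootstrap of a FOCE fit
#'
#' Resamples subjects with replacement to the original cohort size, refits
#' each replicate (warm-started at the original estimates), and summarises
#' per-parameter medians, percentile confidence intervals and the percent
#' bias of the bootstrap median against the original point estimate.
#' Replicates whose outer optimisation fails to converge are excluded and
#' counted.
#'
#' @param fit A converged [foce_fit()].
#' @param n_replicates Number of bootstrap replicates (the full analysis uses
#'   1000; scaled-down runs are fine for checking stability).
#' @param seed RNG seed; per-replicate resampling is derived from it.
#' @param level Confidence level for the percentile interval.
#' @param control A [foce_control()] for the replicate refits.
#' @return An object of class `pk_bootstrap` with `estimates` (replicate x
#'   parameter matrix), `median`, `ci`, `bias_pct`, `n_failed`.
#' @export
pk_bootstrap <- function(fit, n_replicates = 1000, seed = NULL, level = 0.95,
                         control = foce_control(maxit = 800)) {
  stopifnot(n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  cohort <- fit$cohort
  n <- length(cohort)
  p_names <- names(fit$coefficients)
  est <- matrix(NA_real_, n_replicates, length(p_names),
                dimnames = list(NULL, p_names))
  n_failed <- 0L
  for (b in seq_len(n_replicates)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot_pat <- unclass(cohort)[idx]
    for (j in seq_along(boot_pat)) boot_pat[[j]]$id <- j
    boot_cohort <- pk_cohort(boot_pat)
    bf <- try(foce_fit(boot_cohort, init = fit$model,
                       covariates = fit$covariate_names, control = control),
              silent = TRUE)
    if (inherits(bf, "try-error") || !bf$converged) {
      n_failed <- n_failed + 1L
      next
    }
    est[b, ] <- bf$coefficients
  }
  ok <- stats::complete.cases(est)
  a <- (1 - level) / 2
  med <- apply(est[ok, , drop = FALSE], 2, stats::median)
  ci <- apply(est[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(a, 1 - a))
  structure(list(estimates = est[ok, , drop = FALSE],
                 median = med,
                 ci = ci,
                 bias_pct = 100 * (med - fit$coefficients) / fit$coefficients,
                 original = fit$coefficients,
                 n_replicates = n_replicates, n_failed = n_failed,
                 level = level),
            class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat(sprintf("Nonparametric bootstrap: %d replicates (%d failed)\n",
              x$n_replicates, x$n_failed))
  tab <- data.frame(estimate = signif(x$original, 4),
                    median = signif(x$median, 4),
                    ci_lo = signif(x$ci[1, ], 4),
                    ci_hi = signif(x$ci[2, ], 4),
                    bias_pct = signif(x$bias_pct, 3))
  print(tab)
  invisible(x)
}

#' Prediction- and variability-corrected visual predictive check
#'
#' Observations are binned on time after last dose (quantile bins; sparse
#' bins merged with a neighbour).  Within each bin, observed and simulated
#' concentrations are prediction-corrected by the ratio of the bin-median
#' population prediction to each point's own population prediction, and
#' variability-corrected by scaling each point's deviation from the bin
#' median prediction by the square root of the ratio of the bin-median to
#' the point-wise linearised variance.  Percentiles (5th/50th/95th by
#' default) of the corrected observations are compared with the simulated
#' confidence bands of the same percentiles.
#'
#' @param fit A [foce_fit()].
#' @param n_sim Number of simulation replicates (the full analysis uses
#'   1000).
#' @param bins Target number of quantile bins on time after last dose.
#' @param seed RNG seed for the simulations.
#' @param probs Percentiles to track.
#' @param ci Width of the simulated confidence interval for each percentile.
#' @return An object of class `pvc_vpc` with a per-bin `table` of observed
#'   percentiles and simulated interval bounds.
#' @export
pvc_vpc <- function(fit, n_sim = 1000, bins = 6, seed = NULL,
                    probs = c(0.05, 0.5, 0.95), ci = 0.9) {
  model <- fit$model
  cohort <- fit$cohort
  cov_names <- setdiff(names(model$covariates), "crcl")
  des <- .build_design(cohort, cov_names)
  typ <- .typ_cl(des, model$theta_cl, model$covariates, model$refs)
  pred <- .conc_design(des, typ, model$volume)
  h <- 1e-4
  G0 <- (.conc_design(des, typ * exp(h), model$volume) -
         .conc_design(des, typ * exp(-h), model$volume)) / (2 * h)
  v0 <- model$omega_cl^2 * G0^2 + model$sigma_prop^2 * pred^2 + 1e-10
  tad <- .time_after_last_dose(cohort)
  bin_id <- .tad_bins(tad, bins)
  n_bin <- max(bin_id)
  bin_f <- factor(bin_id, levels = seq_len(n_bin))
  bin_pred <- unname(tapply(pred, bin_f, stats::median))
  bin_v <- unname(tapply(v0 * (bin_pred[bin_id] / pred)^2, bin_f, stats::median))
  correct <- function(y) {
    pc <- y * bin_pred[bin_id] / pred
    w <- sqrt(bin_v[bin_id] / (v0 * (bin_pred[bin_id] / pred)^2))
    bin_pred[bin_id] + (pc - bin_pred[bin_id]) * w
  }
  obs_c <- correct(des$y)
  obs_pct <- t(vapply(seq_len(n_bin), function(b)
    stats::quantile(obs_c[bin_id == b], probs), numeric(length(probs))))
  sims <- simulate(fit, nsim = n_sim, seed = seed)
  sim_pct <- array(NA_real_, c(n_bin, length(probs), n_sim))
  for (s in seq_len(n_sim)) {
    yc <- correct(sims[, s])
    sim_pct[, , s] <- t(vapply(seq_len(n_bin), function(b)
      stats::quantile(yc[bin_id == b], probs), numeric(length(probs))))
  }
  a <- (1 - ci) / 2
  lo <- apply(sim_pct, c(1, 2), stats::quantile, probs = a)
  hi <- apply(sim_pct, c(1, 2), stats::quantile, probs = 1 - a)
  tab <- data.frame(bin = seq_len(n_bin),
                    tad_lo = unname(tapply(tad, bin_f, min)),
                    tad_hi = unname(tapply(tad, bin_f, max)),
                    tad_mid = unname(tapply(tad, bin_f, stats::median)),
                    n = tabulate(bin_id, n_bin))
  for (j in seq_along(probs)) {
    pn <- paste0("p", round(100 * probs[j]))
    tab[[paste0("obs_", pn)]] <- obs_pct[, j]
    tab[[paste0("sim_", pn, "_lo")]] <- lo[, j]
    tab[[paste0("sim_", pn, "_hi")]] <- hi[, j]
  }
  structure(list(table = tab, probs = probs, ci = ci, n_sim = n_sim),
            class = "pvc_vpc")
}

# Quantile bins on time after last dose; bins holding fewer than 2
# observations are merged with their left neighbour (with a warning).
.tad_bins <- function(tad, bins) {
  edges <- unique(stats::quantile(tad, probs = seq(0, 1, length.out = bins + 1)))
  if (length(edges) < 2) return(rep(1L, length(tad)))
  id <- cut(tad, breaks = edges, include.lowest = TRUE, labels = FALSE)
  repeat {
    counts <- tabulate(id)
    small <- which(counts < 2)
    if (!length(small) || max(id) == 1) break
    b <- small[1]
    warning("merging sparse VPC bin with neighbour")
    id[id == b] <- if (b == 1) 2L else b - 1L
    id <- as.integer(factor(id))
  }
  id
}

#' @export
print.pvc_vpc <- function(x, ...) {
  cat(sprintf("pvcVPC: %d bins, %d simulations, %.0f%% CI\n",
              nrow(x$table), x$n_sim, 100 * x$ci))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.pvc_vpc <- function(x, ...) {
  tab <- x$table
  pr <- round(100 * x$probs)
  ylim <- range(unlist(tab[grep("^(obs|sim)_", names(tab))]))
  graphics::plot(NA, xlim = range(c(tab$tad_lo, tab$tad_hi)), ylim = ylim,
                 xlab = "Time after last dose (h)",
                 ylab = "Prediction/variability-corrected conc (mg/L)", ...)
  for (j in seq_along(pr)) {
    lo <- tab[[paste0("sim_p", pr[j], "_lo")]]
    hi <- tab[[paste0("sim_p", pr[j], "_hi")]]
    graphics::polygon(c(tab$tad_mid, rev(tab$tad_mid)), c(lo, rev(hi)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(tab$tad_mid, tab[[paste0("obs_p", pr[j])]],
                    type = "b", pch = 16)
  }
  invisible(x)
}
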