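#' Read a model specification from a YAML config file
#'
#' The config mirrors the estimation setup: initial structural estimates,
#' the between-subject-variability and residual-error terms, candidate
#' covariates and the stepwise selection thresholds.  Example:
#'
#' ```yaml
#' init:
#'   theta_cl: 3.66
#'   volume: 54
#'   bsv_cl_cv: 36.30
#'   prop_error_cv: 19.05
#'   covariates: {crcl: 2.18}
#'   refs: {crcl: 65}
#' candidates: [crcl, age, weight]
#' forward_dofv: 3.84
#' backward_dofv: 6.63
#' ```
#'
#' @param path YAML file path.
#' @return List with `init` (a [pop_model()]), `candidates`,
#'   `forward_dofv`, `backward_dofv`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ini <- cfg$init
  if (is.null(ini)) stop("config must contain an 'init' block")
  covs <- if (!is.null(ini$covariates)) unlist(ini$covariates) else NULL
  refs <- if (!is.null(ini$refs)) unlist(ini$refs) else
    if (!is.null(covs)) stats::setNames(rep(65, length(covs)), names(covs))
    else NULL
  init <- pop_model(
    theta_cl = ini$theta_cl %||% 3.66,
    volume = ini$volume %||% 54,
    omega_cl = if (!is.null(ini$bsv_cl_cv)) cv_to_omega(ini$bsv_cl_cv)
               else ini$omega_cl %||% cv_to_omega(36.30),
    sigma_prop = if (!is.null(ini$prop_error_cv)) ini$prop_error_cv / 100
                 else ini$sigma_prop %||% 0.1905,
    covariates = covs, refs = refs)
  list(init = init,
       candidates = cfg$candidates %||% character(0),
       forward_dofv = cfg$forward_dofv %||% 3.84,
       backward_dofv = cfg$backward_dofv %||% 6.63)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a fit report as JSON plus a readable text table
#'
#' @param fit A [foce_fit()].
#' @param json_path Optional JSON output path.
#' @param txt_path Optional text output path.
#' @return The report list, invisibly.
#' @export
write_fit_report <- function(fit, json_path = NULL, txt_path = NULL) {
  s <- summary(fit)
  rep <- list(parameters = s$table, ofv = fit$ofv, aic = fit$aic,
              bic = fit$bic, n_subjects = fit$n_subjects,
              n_obs = fit$n_obs, converged = fit$converged,
              eta_shrinkage_pct = fit$eta_shrinkage,
              eps_shrinkage_pct = fit$eps_shrinkage)
  if (!is.null(json_path))
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    sink(con); print(s); sink()
    close(con)
  }
  invisible(rep)
}
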