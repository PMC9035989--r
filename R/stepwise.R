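#' Stepwise covariate selection on clearance
#'
#' Forward selection followed by backward elimination of covariate terms on
#' clearance, each term linear in covariate/reference.  Forward: at each
#' step the candidate giving the largest drop in OFV is added if the drop is
#' at least `forward_dofv` (3.84, chi-square p < 0.05 at 1 df); ties go to
#' the earlier-listed candidate.  Backward: from the full model, any term
#' whose removal raises the OFV by less than `backward_dofv` (6.63, p < 0.01)
#' is dropped, least-supported first.  Deterministic given the data.
#' Candidate covariates with pairwise correlation above 0.95 are rejected
#' rather than silently fit.
#'
#' @param cohort A [pk_cohort()].
#' @param base A [pop_model()] giving the covariate-free initial estimates.
#' @param candidates Character vector of candidate covariate names (standard
#'   patient fields or extras attached via [set_covariate()]).
#' @param forward_dofv,backward_dofv Selection thresholds on the OFV drop /
#'   rise.
#' @param control A [foce_control()].
#' @return An object of class `covariate_search` with elements `selected`
#'   (character), `trace` (data frame of per-step decisions) and `final_fit`
#'   (a [foce_fit()]).
#' @export
stepwise_covariates <- function(cohort, base = pop_model(covariates = NULL),
                                candidates, forward_dofv = 3.84,
                                backward_dofv = 6.63,
                                control = foce_control()) {
  candidates <- as.character(candidates)
  if (length(candidates) > 1) {
    covmat <- vapply(candidates, function(nm)
      vapply(cohort, patient_covariate, numeric(1), name = nm),
      numeric(length(cohort)))
    cc <- stats::cor(covmat)
    diag(cc) <- 0
    if (any(abs(cc) > 0.95)) {
      bad <- which(abs(cc) > 0.95, arr.ind = TRUE)[1, ]
      stop("collinear candidate covariates: ",
           candidates[bad[1]], " and ", candidates[bad[2]],
           " (|r| > 0.95)")
    }
  }
  base_init <- pop_model(theta_cl = base$theta_cl, volume = base$volume,
                         omega_cl = base$omega_cl,
                         sigma_prop = base$sigma_prop, covariates = NULL)
  fit_with <- function(sel, init) {
    foce_fit(cohort, init = init,
             covariates = if (length(sel)) sel else character(0),
             control = control)
  }
  current <- fit_with(character(0), base_init)
  selected <- character(0)
  remaining <- candidates
  trace <- list()
  step <- 0L
  # forward
  repeat {
    if (!length(remaining)) break
    dofvs <- numeric(length(remaining))
    fits <- vector("list", length(remaining))
    for (j in seq_along(remaining)) {
      fits[[j]] <- fit_with(c(selected, remaining[j]), current$model)
      dofvs[j] <- current$ofv - fits[[j]]$ofv
    }
    best <- which.max(dofvs)   # which.max takes the first on ties
    step <- step + 1L
    accept <- dofvs[best] >= forward_dofv
    trace[[length(trace) + 1L]] <- data.frame(
      step = step, phase = "forward", covariate = remaining[best],
      dofv = dofvs[best], decision = if (accept) "added" else "stop")
    if (!accept) break
    selected <- c(selected, remaining[best])
    current <- fits[[best]]
    remaining <- setdiff(remaining, remaining[best])
  }
  # backward
  repeat {
    if (!length(selected)) break
    rises <- numeric(length(selected))
    fits <- vector("list", length(selected))
    for (j in seq_along(selected)) {
      fits[[j]] <- fit_with(setdiff(selected, selected[j]), current$model)
      rises[j] <- fits[[j]]$ofv - current$ofv
    }
    worst <- which.min(rises)
    step <- step + 1L
    drop <- rises[worst] < backward_dofv
    trace[[length(trace) + 1L]] <- data.frame(
      step = step, phase = "backward", covariate = selected[worst],
      dofv = rises[worst], decision = if (drop) "dropped" else "retained")
    if (!drop) break
    current <- fits[[worst]]
    selected <- setdiff(selected, selected[worst])
  }
  structure(list(selected = selected,
                 trace = do.call(rbind, trace),
                 final_fit = current),
            class = "covariate_search")
}

#' @export
print.covariate_search <- function(x, ...) {
  cat("Stepwise covariate search on CL\n")
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n\n")
  if (!is.null(x$trace)) print(x$trace, row.names = FALSE)
  invisible(x)
}
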