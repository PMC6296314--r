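#' Weighted log-likelihood of the censored ordinal outcomes
#'
#' Each patient contributes the factor
#' `[1 - w F1]^{I(Y=0)} [w F1 - w F2]^{I(Y=1)} [w F2]^{I(Y=2)}`
#' evaluated at their assigned skeleton value, with the time-to-event
#' weight `w = weight_fn(c, M)` applied to both arms (weight 1 at complete
#' follow-up).  Returns `-Inf` when an observed outcome has probability
#' zero under the parameters.
#'
#' @param patients a [patient_records()] data frame (nonempty, with current
#'   `c` and `y`).
#' @param params a [model_params()] object.
#' @param grid a [dose_grid()].
#' @param M assessment window in cycles.
#' @param weight_fn weight function `function(c, M)`; default
#'   [linear_weight()].
#' @return the log-likelihood value.
#' @export
weighted_log_likelihood <- function(patients, params, grid, M = 6,
                                    weight_fn = linear_weight) {
  if (nrow(patients) == 0L) stop("no patient records")
  if (any(is.na(patients$c)) || any(is.na(patients$y)))
    stop("patient records lack current follow-up/outcome; see update_followups()")
  x <- grid$skeleton[patients$dose_index]
  w <- weight_fn(patients$c, M)
  logx <- log(x)
  F1 <- exp(params$beta1 * logx)
  F2 <- exp((params$beta1 + params$beta2) * logx)
  p <- ifelse(patients$y == 0L, 1 - w * F1,
       ifelse(patients$y == 1L, w * (F1 - F2), w * F2))
  if (any(p <= 0)) return(-Inf)
  sum(log(p))
}

#' Heterogeneity status of the observed outcomes
#'
#' The two-parameter MLE exists only once all three outcome categories have
#' been observed ("full heterogeneity").  Qualification is strict:
#' a DLT counts as soon as it occurs; a moderate-only outcome counts only
#' for a patient who completed the `M`-cycle window with a moderate toxicity
#' and no DLT; a toxicity-free outcome counts only for a patient who
#' completed the window event-free (partially followed patients could still
#' change category).  Short of full heterogeneity, the status reports which
#' single-constraint model the staged design should use: `"moderate_only"`
#' when grade >= 2 events have occurred without any DLT, and
#' `"dlt_without_moderate"` whenever a DLT has occurred (this branch also
#' absorbs the case of DLTs alongside not-yet-qualifying moderate events).
#'
#' @param patients a [patient_records()] data frame.
#' @param M assessment window in cycles.
#' @return one of `"no_grade2_yet"`, `"moderate_only"`,
#'   `"dlt_without_moderate"`, `"full"`.
#' @export
heterogeneity_status <- function(patients, M = 6) {
  if (nrow(patients) == 0L) return("no_grade2_yet")
  dlt_seen <- !is.na(patients$t_dlt) & patients$t_dlt <= patients$c
  mod_seen <- !is.na(patients$t_mt) & patients$t_mt <= patients$c &
    (is.na(patients$t_dlt) | patients$t_mt < patients$t_dlt)
  done <- patients$c >= M
  q2 <- any(dlt_seen)
  q1 <- any(done & patients$y == 1L)
  q0 <- any(done & patients$y == 0L)
  if (q0 && q1 && q2) return("full")
  if (!q2 && !any(mod_seen)) return("no_grade2_yet")
  if (!q2) return("moderate_only")
  "dlt_without_moderate"
}

loglik_gamma <- function(gamma, patients, grid, M, weight_fn) {
  ll <- weighted_log_likelihood(patients, model_params_from_gamma(gamma),
                                grid, M, weight_fn)
  if (!is.finite(ll)) -1e10 else ll
}

#' Maximum-likelihood fit of the two-parameter working model
#'
#' Maximises the weighted log-likelihood over the log-scale parameters
#' `(gamma1, gamma2)` by quasi-Newton iterations with three deterministic
#' restarts from (0,0), (1,-1) and (-1,1); among restarts whose maxima tie
#' within tolerance the one with the smallest `||gamma||` is kept.  If the
#' outcomes are not fully heterogeneous the MLE does not exist and a typed
#' `not_estimable` result is returned (the staged design consumes this
#' routinely); optimiser non-convergence in every restart is instead an
#' error.
#'
#' @inheritParams weighted_log_likelihood
#' @return an object of class `crmmc_fit`: a list with `status` ("ok" or
#'   "not_estimable"), and for successful fits `params`, `gamma`, `loglik`.
#' @export
fit_mle <- function(patients, grid, M = 6, weight_fn = linear_weight) {
  status <- heterogeneity_status(patients, M)
  if (status != "full")
    return(structure(list(status = "not_estimable", reason = status),
                     class = "crmmc_fit"))
  starts <- list(c(0, 0), c(1, -1), c(-1, 1))
  fits <- lapply(starts, function(s) {
    tryCatch(
      stats::optim(s, loglik_gamma, patients = patients, grid = grid,
                   M = M, weight_fn = weight_fn, method = "BFGS",
                   control = list(fnscale = -1, maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && f$convergence == 0L, fits)
  if (length(fits) == 0L)
    stop("MLE optimiser failed to converge from every restart")
  vals <- vapply(fits, function(f) f$value, numeric(1))
  best <- max(vals)
  tied <- which(vals >= best - 1e-6)
  norms <- vapply(fits[tied], function(f) sum(f$par^2), numeric(1))
  f <- fits[[tied[which.min(norms)]]]
  structure(list(status = "ok", params = model_params_from_gamma(f$par),
                 gamma = f$par, loglik = f$value),
            class = "crmmc_fit")
}

#' @export
print.crmmc_fit <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("two-parameter MLE: beta1 = %.4f, beta2 = %.4f (loglik %.4f)\n",
                x$params$beta1, x$params$beta2, x$loglik))
  } else {
    cat("MLE not estimable; heterogeneity status:", x$reason, "\n")
  }
  invisible(x)
}

# One-parameter TITE-CRM likelihood fit on a binary endpoint
# (grade >= 2 toxicity or DLT), used by stage 2 of the staged design and by
# the likelihood variant of the single-constraint comparator.
# Returns the MLE of beta in F(x) = x^beta, or NA when the weighted binary
# data are degenerate (no event, or no non-event with positive weight).
fit_tite1 <- function(events, x, w) {
  if (!any(events) || sum(w[!events]) <= 0) return(NA_real_)
  logx <- log(x)
  nll <- function(gamma) {
    F <- exp(exp(gamma) * logx)
    p <- ifelse(events, w * F, 1 - w * F)
    if (any(p <= 0)) return(1e10)
    -sum(log(p))
  }
  opt <- stats::optimize(nll, interval = c(-12, 12), tol = 1e-9)
  exp(opt$minimum)
}
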