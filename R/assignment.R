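#' Next-dose recommendation from a maximum-likelihood fit
#'
#' Under likelihood estimation the next dose is the minimum of the two
#' per-constraint distance-minimising dose levels:
#' `min{ argmin_k |F1(x_k) - p_mt|, argmin_k |F2(x_k) - p_dlt| }`,
#' with distance ties broken to the lower dose.
#'
#' @param params a [model_params()] object (a successful MLE).
#' @param grid a [dose_grid()].
#' @param constraints a [toxicity_constraints()].
#' @return the recommended dose index.
#' @export
recommend_mle <- function(params, grid, constraints) {
  d <- constraint_doses(params$beta1, params$beta1 + params$beta2,
                        grid, constraints, rule = "distance")
  min(d$mt, d$dlt)
}

#' Next-dose recommendation from a Bayesian dose summary
#'
#' The minimum of the two marginal posterior median dose levels,
#' `min(x_mt, x_dlt)` (the nearest grid dose to an index is the index
#' itself).
#'
#' @param summary a `constraint_dose_summary` from
#'   [constraint_dose_distribution()] or [posterior_dose_quadrature()].
#' @return the recommended dose index.
#' @export
recommend_bayes <- function(summary) {
  min(summary$median_mt, summary$median_dlt)
}

#' No-skipping restriction on escalation
#'
#' Escalation is limited to one level above the highest dose administered so
#' far (the standard CRM untried-dose cap); de-escalation is never
#' restricted.
#'
#' @param proposed proposed dose index.
#' @param highest_tried highest dose index administered so far.
#' @return the restricted dose index, `min(proposed, highest_tried + 1)`.
#' @export
restrict_no_skip <- function(proposed, highest_tried) {
  min(proposed, highest_tried + 1L)
}
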