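#' Dose grid with a working-model skeleton
#'
#' The skeleton is the fixed prior guess of per-dose DLT probabilities used
#' as the dose metric of the empiric working model.  Values must be strictly
#' increasing and lie in the open unit interval.
#'
#' @param skeleton numeric vector of K skeleton values in (0,1), strictly
#'   increasing.
#' @param prior_mtd integer position of the prior guess of the MTD
#'   (defaults to the middle dose).
#' @param delta optional indifference half-width the skeleton was generated
#'   with; retained for provenance only.
#' @param labels optional dose labels (defaults to `"d1".."dK"`).
#' @return an object of class `dose_grid`.
#' @seealso [indifference_skeleton()]
#' @export
dose_grid <- function(skeleton, prior_mtd = NULL, delta = NULL, labels = NULL) {
  skeleton <- as.numeric(skeleton)
  K <- length(skeleton)
  if (K < 2) stop("need at least two dose levels")
  if (any(!is.finite(skeleton)) || any(skeleton <= 0) || any(skeleton >= 1))
    stop("skeleton values must lie in the open interval (0, 1)")
  if (any(diff(skeleton) <= 0)) stop("skeleton must be strictly increasing")
  if (is.null(prior_mtd)) prior_mtd <- ceiling(K / 2)
  prior_mtd <- as.integer(prior_mtd)
  if (prior_mtd < 1L || prior_mtd > K) stop("prior_mtd must be in 1..K")
  if (is.null(labels)) labels <- paste0("d", seq_len(K))
  structure(list(skeleton = skeleton, prior_mtd = prior_mtd, K = K,
                 delta = delta, labels = labels),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("Dose grid with", x$K, "levels (prior MTD at level", x$prior_mtd, ")\n")
  v <- round(x$skeleton, 2)
  names(v) <- x$labels
  print(v)
  if (!is.null(x$delta)) cat("indifference half-width delta =", x$delta, "\n")
  invisible(x)
}

#' Toxicity constraints defining the MTD
#'
#' The MTD is the maximum dose satisfying both tail constraints on the
#' ordinal toxicity outcome Z: `Pr(Z >= 1 | x) <= p_mt` (moderate, grade 2
#' or higher toxicity) and `Pr(Z >= 2 | x) <= p_dlt` (DLT).  The ordinal
#' thresholds are fixed at 1 and 2.
#'
#' @param p_mt target probability of grade >= 2 toxicity.
#' @param p_dlt target probability of DLT; must satisfy
#'   `0 < p_dlt < p_mt < 1`.
#' @return an object of class `toxicity_constraints`.
#' @export
toxicity_constraints <- function(p_mt = 0.50, p_dlt = 0.25) {
  if (!(p_dlt > 0 && p_dlt < p_mt && p_mt < 1))
    stop("constraints must satisfy 0 < p_dlt < p_mt < 1")
  structure(list(p_mt = p_mt, p_dlt = p_dlt, t1 = 1L, t2 = 2L),
            class = "toxicity_constraints")
}

#' Parameters of the two-parameter empiric working model
#'
#' The working model is `F1(x) = x^beta1` for grade >= 2 toxicity and
#' `F2(x) = x^(beta1 + beta2)` for DLT, with `beta1 > 0` and `beta2 >= 0`
#' so that `F2 <= F1` on (0,1).  Parameters are carried on both the natural
#' and the log (gamma) scale, `beta_l = exp(gamma_l)`; all optimisation is
#' done on the gamma scale so positivity is structural.
#'
#' @param beta1 exponent of the grade >= 2 arm, `> 0`.
#' @param beta2 increment of the DLT arm, `>= 0`.
#' @return an object of class `model_params`.
#' @export
model_params <- function(beta1, beta2 = 0) {
  if (!is.finite(beta1) || beta1 <= 0) stop("beta1 must be > 0")
  if (!is.finite(beta2) || beta2 < 0) stop("beta2 must be >= 0")
  structure(list(beta1 = beta1, beta2 = beta2,
                 gamma = c(log(beta1), if (beta2 > 0) log(beta2) else -Inf)),
            class = "model_params")
}

#' @rdname model_params
#' @param gamma length-2 numeric, log-scale parameters `(gamma1, gamma2)`.
#' @export
model_params_from_gamma <- function(gamma) {
  model_params(exp(gamma[1]), exp(gamma[2]))
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("empiric model parameters: beta1 = %.4f, beta2 = %.4f\n",
              x$beta1, x$beta2))
  invisible(x)
}

check_x <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
    stop("dose metric x must lie in (0, 1)")
  x
}

#' Working-model tail probabilities
#'
#' `f1` is the modelled probability of grade >= 2 toxicity, `x^beta1`;
#' `f2` the modelled probability of DLT, `x^(beta1 + beta2)`.  Both are
#' computed as `exp(beta * log x)` for stability near `x = 0` and are
#' vectorised over `x`.
#'
#' @param x skeleton value(s) in (0,1).
#' @param params a [model_params()] object.
#' @return probability vector of the same length as `x`.
#' @export
f1 <- function(x, params) {
  check_x(x)
  exp(params$beta1 * log(x))
}

#' @rdname f1
#' @export
f2 <- function(x, params) {
  check_x(x)
  exp((params$beta1 + params$beta2) * log(x))
}

#' Linear time-to-event weight
#'
#' The TITE weight of a partially followed patient: follow-up divided by the
#' assessment window, `min(c, M) / M`.  With the six-cycle window this is
#' the `c/6` weight used for both the moderate-toxicity and the DLT arm.
#'
#' @param c follow-up time in cycles, `>= 0`; vectorised.
#' @param M assessment window in cycles.
#' @return weight(s) in \[0, 1\].
#' @export
linear_weight <- function(c, M = 6) {
  if (any(c < 0)) stop("follow-up time must be nonnegative")
  if (M <= 0) stop("assessment window must be positive")
  pmin(c, M) / M
}

#' Censored outcome probabilities of the weighted model
#'
#' Probabilities of the censored ordinal outcome `Y` at follow-up weights
#' `w_mt`, `w_dlt`:
#' `P(Y=0) = 1 - w_mt F1(x)`, `P(Y=1) = w_mt F1(x) - w_dlt F2(x)`,
#' `P(Y=2) = w_dlt F2(x)`.  With equal weights and `beta2 >= 0` the middle
#' probability is guaranteed nonnegative; with unequal weights a negative
#' middle probability is a model violation and raises an error.
#'
#' At full follow-up (`w_mt = w_dlt = 1`) this collapses to the
#' complete-observation model `(1 - F1, F1 - F2, F2)`.
#'
#' @param x skeleton value(s) in (0,1).
#' @param params a [model_params()] object.
#' @param w_mt weight for the moderate-toxicity arm, in \[0,1\].
#' @param w_dlt weight for the DLT arm; defaults to `w_mt`.
#' @return for scalar `x` a named numeric of length 3 `(p0, p1, p2)`;
#'   for vector `x` a matrix with one row per dose.
#' @export
censored_outcome_probs <- function(x, params, w_mt = 1, w_dlt = w_mt) {
  if (any(w_mt < 0 | w_mt > 1) || any(w_dlt < 0 | w_dlt > 1))
    stop("weights must lie in [0, 1]")
  F1 <- f1(x, params)
  F2 <- f2(x, params)
  p1 <- w_mt * F1 - w_dlt * F2
  if (any(p1 < -1e-12))
    stop("model violation: w_mt * F1 < w_dlt * F2 (negative P(Y = 1))")
  p1 <- pmax(p1, 0)
  out <- cbind(p0 = 1 - w_mt * F1, p1 = p1, p2 = w_dlt * F2)
  if (length(x) == 1L && length(w_mt) == 1L) out[1, ] else out
}
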