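#' Indifference-interval skeleton for the empiric model
#'
#' Generates the skeleton of per-dose DLT probabilities by the
#' indifference-interval calibration for the one-parameter empiric model
#' `F(x) = x^beta`.  The value at the prior MTD position `nu` is anchored at
#' the target; neighbours are defined step by step so that at the parameter
#' for which dose `i` sits at the lower indifference bound `target - delta`,
#' dose `i+1` sits at the upper bound `target + delta`:
#'
#' moving up,   `x[i+1] = (target + delta) ^ (log x[i] / log(target - delta))`;
#' moving down, `x[i-1] = (target - delta) ^ (log x[i] / log(target + delta))`.
#'
#' With `target = 0.25`, `nu = 3`, `K = 5`, `delta = 0.06` this yields the
#' grid that rounds to 0.06, 0.14, 0.25, 0.38, 0.50.  Full-precision values
#' are kept internally; rounding is display-only.
#'
#' @param target target DLT probability anchoring the skeleton.
#' @param nu prior MTD position, in `1..K`.
#' @param K number of dose levels.
#' @param delta indifference half-width, `0 < delta < min(target, 1 - target)`.
#' @param labels optional dose labels.
#' @return a [dose_grid()] carrying the skeleton, `nu` and `delta`.
#' @export
indifference_skeleton <- function(target, nu, K, delta, labels = NULL) {
  if (!(target > 0 && target < 1)) stop("target must be in (0, 1)")
  if (!(delta > 0 && delta < min(target, 1 - target)))
    stop("delta must satisfy 0 < delta < min(target, 1 - target)")
  nu <- as.integer(nu); K <- as.integer(K)
  if (K < 2) stop("need at least two dose levels")
  if (nu < 1L || nu > K) stop("nu must be in 1..K")
  lo <- log(target - delta)
  hi <- log(target + delta)
  x <- numeric(K)
  x[nu] <- target
  if (nu < K) for (i in nu:(K - 1L)) x[i + 1L] <- exp(hi * log(x[i]) / lo)
  if (nu > 1L) for (i in nu:2L) x[i - 1L] <- exp(lo * log(x[i]) / hi)
  if (any(x <= 0) || any(x >= 1) || any(diff(x) <= 0))
    stop("delta too large: skeleton leaves (0, 1) or is not increasing")
  dose_grid(x, prior_mtd = nu, delta = delta, labels = labels)
}
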