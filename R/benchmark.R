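#' Complete toxicity profiles for the nonparametric benchmark
#'
#' The benchmark assumes each patient's ordinal outcome `Z` is known at
#' every dose level.  A single latent uniform per patient, shared across
#' doses and both thresholds, is compared with the scenario's true tail
#' probabilities: at dose k, `Z = 2` if `u <= P(Z >= 2 | d_k)`, else
#' `Z = 1` if `u <= P(Z >= 1 | d_k)`, else 0.  Sharing one uniform makes
#' the profile monotone in dose whenever the scenario's tail probabilities
#' are.
#'
#' @param scenario a [scenario_spec()].
#' @param n number of patients.
#' @return an `n x K` integer matrix of outcomes.
#' @export
complete_profiles <- function(scenario, n) {
  q1 <- 1 - scenario$probs[, 1]
  q2 <- scenario$probs[, 3]
  u <- stats::runif(n)
  Z <- matrix(0L, n, scenario$K)
  for (k in seq_len(scenario$K)) {
    Z[, k] <- ifelse(u <= q2[k], 2L, ifelse(u <= q1[k], 1L, 0L))
  }
  Z
}

#' Benchmark dose selection from complete profiles
#'
#' Computes per-dose sample proportions of grade >= 2 toxicity and of DLT
#' from the complete profiles, finds for each constraint the dose whose
#' proportion is closest to the target (ties to the lower dose), and
#' returns the minimum of the two — the complete-observation analogue of
#' the multiple-constraint assignment rule.  It is an accuracy upper bound:
#' complete profiles are never observed in a real trial.
#'
#' @param profiles matrix from [complete_profiles()].
#' @param constraints a [toxicity_constraints()].
#' @return the selected dose index.
#' @export
benchmark_select <- function(profiles, constraints) {
  if (nrow(profiles) < 1L) stop("need at least one profile")
  p1 <- colMeans(profiles >= 1L)
  p2 <- colMeans(profiles == 2L)
  min(which.min(abs(p1 - constraints$p_mt)),
      which.min(abs(p2 - constraints$p_dlt)))
}

#' Benchmark operating characteristics
#'
#' Repeats profile simulation and benchmark selection.
#'
#' @inheritParams complete_profiles
#' @param reps number of replicates.
#' @param constraints a [toxicity_constraints()].
#' @param seed optional seed.
#' @return integer vector of `reps` selected dose indices.
#' @export
benchmark_selections <- function(scenario, n, reps,
                                 constraints = toxicity_constraints(),
                                 seed = NULL) {
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
  }
  vapply(seq_len(reps), function(r)
    benchmark_select(complete_profiles(scenario, n), constraints),
    integer(1))
}
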