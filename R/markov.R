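#' Validate a per-cycle toxicity transition matrix
#'
#' A scenario transition matrix acts on the maximal toxicity state
#' {0 none, 1 moderate, 2 DLT} at end-of-cycle assessment visits.  Because
#' the maximal grade can only worsen, a valid matrix is upper triangular
#' with rows summing to one, entries in \[0,1\], and the DLT state
#' absorbing.
#'
#' @param P a 3x3 numeric matrix.
#' @return character vector of violations; empty when the matrix is valid.
#' @export
validate_matrix <- function(P) {
  v <- character(0)
  if (!is.matrix(P) || !all(dim(P) == c(3, 3)) || !is.numeric(P))
    return("not a 3x3 numeric matrix")
  if (any(P < -1e-12) || any(P > 1 + 1e-12))
    v <- c(v, "entries outside [0, 1]")
  if (any(abs(rowSums(P) - 1) > 1e-8))
    v <- c(v, "row sums differ from 1")
  if (any(abs(P[lower.tri(P)]) > 1e-12))
    v <- c(v, "not upper triangular (toxicity grade cannot improve)")
  if (any(abs(P[3, ] - c(0, 0, 1)) > 1e-12))
    v <- c(v, "DLT state is not absorbing")
  v
}

#' Toxicity transition matrix from per-cycle hazards
#'
#' Convenience constructor: from the no-toxicity state a patient moves to
#' moderate toxicity with per-cycle probability `p01` and directly to DLT
#' with `p02`; from moderate toxicity to DLT with `p12`; the DLT state is
#' absorbing.
#'
#' @param p01,p02,p12 per-cycle transition probabilities.
#' @return a valid 3x3 transition matrix.
#' @export
cumulative_tox_matrix <- function(p01, p02, p12) {
  if (p01 + p02 > 1 || p12 > 1 || any(c(p01, p02, p12) < 0))
    stop("per-cycle probabilities must be nonnegative with p01 + p02 <= 1")
  matrix(c(1 - p01 - p02, p01, p02,
           0, 1 - p12, p12,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Outcome distribution after M cycles
#'
#' The distribution of the maximal toxicity grade `Z` at the end of the
#' assessment window is the first row of the M-th matrix power, `P^M`
#' (patients start toxicity-free).
#'
#' @param P a valid 3x3 transition matrix.
#' @param M number of cycles.
#' @return named numeric `(p0, p1, p2) = (P(Z=0), P(Z=1), P(Z=2))`.
#' @export
outcome_distribution <- function(P, M = 6) {
  v <- validate_matrix(P)
  if (length(v)) stop("invalid transition matrix: ", paste(v, collapse = "; "))
  if (M < 1) stop("M must be >= 1")
  Q <- diag(3)
  for (i in seq_len(M)) Q <- Q %*% P
  stats::setNames(Q[1, ], c("p0", "p1", "p2"))
}

#' Toxicity scenario: one transition matrix per dose
#'
#' Bundles the per-dose transition matrices with the assessment window and
#' derives each dose's true outcome distribution (first row of `P^M`).  The
#' DLT state is forced absorbing (with a warning) if a supplied matrix says
#' otherwise, since `Z` is the maximal grade.
#'
#' @param matrices list of K 3x3 transition matrices, ordered by dose.
#' @param M assessment window in cycles.
#' @param name optional scenario name.
#' @return an object of class `scenario_spec` with elements `matrices`,
#'   `M`, `K`, `probs` (K x 3 matrix of `P(Z=0), P(Z=1), P(Z=2)`), `name`.
#' @export
scenario_spec <- function(matrices, M = 6, name = NULL) {
  if (!length(matrices)) stop("no transition matrices supplied")
  matrices <- lapply(matrices, function(P) {
    P <- as.matrix(P)
    if (any(abs(P[3, ] - c(0, 0, 1)) > 1e-12)) {
      warning("forcing the DLT state to be absorbing")
      P[3, ] <- c(0, 0, 1)
    }
    v <- validate_matrix(P)
    if (length(v)) stop("invalid transition matrix: ", paste(v, collapse = "; "))
    P
  })
  probs <- t(vapply(matrices, outcome_distribution, numeric(3), M = M))
  colnames(probs) <- c("p0", "p1", "p2")
  structure(list(matrices = matrices, M = M, K = length(matrices),
                 probs = probs, name = name),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("toxicity scenario", if (!is.null(x$name)) x$name else "",
      "with", x$K, "doses, M =", x$M, "cycles\n")
  tab <- cbind(`P(Z>=1)` = 1 - x$probs[, 1], `P(Z=2)` = x$probs[, 3])
  rownames(tab) <- paste0("d", seq_len(x$K))
  print(round(tab, 3))
  invisible(x)
}

#' True MTD of a scenario
#'
#' The largest dose whose true outcome probabilities satisfy both
#' constraints, `P(Z >= 1) <= p_mt` and `P(Z >= 2) <= p_dlt` (boundary
#' equality counts as satisfied); `NA` if dose 1 already violates one.
#'
#' @param scenario a [scenario_spec()].
#' @param constraints a [toxicity_constraints()].
#' @return the true MTD index, or `NA_integer_` when no dose is tolerable.
#' @export
true_mtd <- function(scenario, constraints) {
  q1 <- 1 - scenario$probs[, 1]
  q2 <- scenario$probs[, 3]
  ok <- q1 <= constraints$p_mt + 1e-12 & q2 <= constraints$p_dlt + 1e-12
  if (!any(ok)) NA_integer_ else max(which(ok))
}

# deterministic path through the chain given per-cycle uniforms; the engine
# pre-draws uniforms per patient so that responses do not depend on entry
# times or on the estimation method sharing the stream
trajectory_from_uniforms <- function(P, M, u) {
  s <- 1L  # states 1..3 internally = grades 0..2
  path <- integer(M)
  for (m in seq_len(M)) {
    cum <- cumsum(P[s, ])
    s <- which(u[m] <= cum + 1e-15)[1]
    path[m] <- s
  }
  grades <- path - 1L
  t_mt <- which(grades >= 1L)[1]
  t_dlt <- which(grades == 2L)[1]
  list(path = grades,
       t_mt = if (is.na(t_mt)) NA_real_ else as.numeric(t_mt),
       t_dlt = if (is.na(t_dlt)) NA_real_ else as.numeric(t_dlt),
       z = grades[M])
}

#' Simulate one patient trajectory
#'
#' Samples the maximal-toxicity path cycle by cycle from the transition
#' matrix, starting toxicity-free.  Event times are first-passage cycle
#' indices (1-based end-of-cycle visits); `z` is the grade at the end of
#' the window.  Uses the current R random stream.
#'
#' @param P a valid 3x3 transition matrix.
#' @param M number of cycles.
#' @return list with `path` (grades at cycles `1..M`), `t_mt`, `t_dlt`
#'   (`NA` if the event never occurs) and `z`.
#' @export
simulate_trajectory <- function(P, M = 6) {
  v <- validate_matrix(P)
  if (length(v)) stop("invalid transition matrix: ", paste(v, collapse = "; "))
  trajectory_from_uniforms(P, M, stats::runif(M))
}

#' Patient arrival times
#'
#' Fixed accrual enters patient i at `(i - 1) / rate`; Poisson-process
#' accrual draws exponential inter-arrival gaps with the same rate (one
#' patient per cycle by default, i.e. six patients in six cycles).
#'
#' @param n number of patients.
#' @param model `"fixed"` or `"poisson"`.
#' @param rate patients per cycle.
#' @return nondecreasing vector of entry times in cycles.
#' @export
accrual_times <- function(n, model = c("fixed", "poisson"), rate = 1) {
  model <- match.arg(model)
  if (n < 1) stop("n must be >= 1")
  if (rate <= 0) stop("rate must be positive")
  if (model == "fixed") (seq_len(n) - 1) / rate
  else cumsum(stats::rexp(n, rate))
}

#' Read a toxicity scenario from YAML or CSV
#'
#' YAML schema: top-level `M` (optional, default 6), `name` (optional) and
#' `doses`, a sequence of 3x3 row-major matrices.  CSV schema (wide): one
#' row per dose and matrix row, columns `dose`, `row` (0..2), `to0`, `to1`,
#' `to2`.  See `inst/extdata/scenario_coincide_mtd1.yaml` for an example.
#'
#' @param path file path ending in `.yaml`/`.yml` or `.csv`.
#' @return a [scenario_spec()].
#' @export
read_scenario <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    mats <- lapply(y$doses, function(m) {
      do.call(rbind, lapply(m, as.numeric))
    })
    scenario_spec(mats, M = if (is.null(y$M)) 6 else y$M, name = y$name)
  } else if (grepl("\\.csv$", path)) {
    df <- utils::read.csv(path)
    need <- c("dose", "row", "to0", "to1", "to2")
    if (!all(need %in% names(df)))
      stop("CSV scenario must have columns: ", paste(need, collapse = ", "))
    mats <- lapply(sort(unique(df$dose)), function(k) {
      sub <- df[df$dose == k, ]
      sub <- sub[order(sub$row), ]
      as.matrix(sub[, c("to0", "to1", "to2")])
    })
    mats <- lapply(mats, function(m) { dimnames(m) <- NULL; m })
    scenario_spec(mats)
  } else stop("unsupported scenario file format: ", path)
}

#' Built-in example scenarios
#'
#' Three five-dose scenarios with a six-cycle window and analytically known
#' truth (derived from `P^6`), covering the design's main regimes under the
#' default targets (0.50, 0.25):
#'
#' * `coincide_mtd1`: both single-constraint MTDs equal dose 1
#'   (dose 1 true probabilities about (0.50, 0.23), steeply rising above);
#' * `coincide_mtd3`: both single-constraint MTDs equal dose 3;
#' * `grade2_limiting_mtd2`: the moderate-toxicity constraint is the
#'   limiting one — MTD by grade >= 2 toxicity alone is dose 2 while by DLT
#'   alone it is dose 3, so the true MTD is dose 2.
#'
#' @return named list of [scenario_spec()] objects.
#' @export
example_scenarios <- function() {
  mk <- function(v) cumulative_tox_matrix(v[1], v[2], v[3])
  list(
    coincide_mtd1 = scenario_spec(lapply(list(
      c(0.089, 0.020, 0.15), c(0.13, 0.05, 0.25), c(0.16, 0.10, 0.35),
      c(0.18, 0.16, 0.45), c(0.18, 0.25, 0.55)), mk),
      name = "coincide_mtd1"),
    coincide_mtd3 = scenario_spec(lapply(list(
      c(0.030, 0.004, 0.05), c(0.055, 0.010, 0.10), c(0.089, 0.020, 0.15),
      c(0.14, 0.06, 0.30), c(0.17, 0.12, 0.45)), mk),
      name = "coincide_mtd3"),
    grade2_limiting_mtd2 = scenario_spec(lapply(list(
      c(0.070, 0.003, 0.04), c(0.098, 0.006, 0.06), c(0.145, 0.012, 0.08),
      c(0.185, 0.025, 0.12), c(0.22, 0.06, 0.20)), mk),
      name = "grade2_limiting_mtd2")
  )
}
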