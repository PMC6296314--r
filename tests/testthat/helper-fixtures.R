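# shared fixtures built in code

standard_grid <- function() indifference_skeleton(0.25, nu = 3, K = 5, delta = 0.06)

standard_constraints <- function() toxicity_constraints(p_mt = 0.50, p_dlt = 0.25)

# degenerate scenarios
zero_tox_scenario <- function(K = 5) {
  scenario_spec(replicate(K, diag(3), simplify = FALSE),
                name = "zero_tox")
}

certain_dlt_scenario <- function(K = 5) {
  P <- matrix(c(0, 0, 1, 0, 0, 1, 0, 0, 1), 3, 3, byrow = TRUE)
  scenario_spec(replicate(K, P, simplify = FALSE), name = "certain_dlt")
}

# DLT-only scenario: moderate state unreachable, so the two-constraint
# design and the single-constraint TITE-CRM see identical information
dlt_only_scenario <- function(p02 = c(0.02, 0.04, 0.07, 0.12, 0.2), K = 5) {
  scenario_spec(lapply(p02[seq_len(K)], function(p)
    cumulative_tox_matrix(0, p, 0)), name = "dlt_only")
}

# complete-follow-up records at one dose with given outcomes
complete_records <- function(dose, y, M = 6) {
  t_mt <- ifelse(y >= 1L, 2, NA_real_)
  t_dlt <- ifelse(y == 2L, 3, NA_real_)
  t_mt[y == 2L] <- 3  # direct jump to DLT
  patient_records(dose_index = dose, entry_time = 0, t_mt = t_mt,
                  t_dlt = t_dlt, now = M, M = M)
}

# sample complete observations from the working model itself
simulate_model_outcomes <- function(n_per_dose, grid, params) {
  recs <- list()
  for (k in seq_len(grid$K)) {
    x <- grid$skeleton[k]
    p2 <- f2(x, params)
    p1 <- f1(x, params) - p2
    u <- runif(n_per_dose)
    y <- ifelse(u <= p2, 2L, ifelse(u <= p1 + p2, 1L, 0L))
    recs[[k]] <- complete_records(rep(k, n_per_dose), y)
  }
  out <- do.call(rbind, recs)
  class(out) <- c("patient_records", "data.frame")
  out
}

stage_rank <- function(stages) {
  r <- c(stage1 = 1, cohort_repeat = 2, stage2_mt = 3, stage2_dlt = 3,
         stage3 = 4, bayes = 1)
  unname(r[stages])
}

# count-based log-likelihood for complete observations; independent of the
# per-patient implementation path
counts_loglik <- function(counts, skeleton, beta1, beta2) {
  F1 <- skeleton^beta1
  F2 <- skeleton^(beta1 + beta2)
  sum(counts[, 1] * log(1 - F1) + counts[, 2] * log(F1 - F2) +
        counts[, 3] * log(F2))
}
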