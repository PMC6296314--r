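test_that("transition-matrix validation reports each violation", {
  expect_length(validate_matrix(diag(3)), 0)
  P <- diag(3); P[1, ] <- c(0.5, 0.3, 0.1)
  expect_match(validate_matrix(P), "row sums", all = FALSE)
  P <- diag(3); P[3, 1] <- 0.1; P[3, 3] <- 0.9
  expect_match(validate_matrix(P), "upper triangular", all = FALSE)
  P <- cumulative_tox_matrix(0.1, 0.05, 0.2)
  expect_length(validate_matrix(P), 0)
})

test_that("outcome distribution is the first row of the matrix power", {
  expect_equal(unname(outcome_distribution(diag(3), 6)), c(1, 0, 0))
  P <- matrix(c(0, 0, 1, 0, 0, 1, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_equal(unname(outcome_distribution(P, 6)), c(0, 0, 1))
  # against a direct power computed in the test
  P <- cumulative_tox_matrix(0.13, 0.05, 0.25)
  Q <- P %*% P %*% P %*% P %*% P %*% P
  expect_equal(unname(outcome_distribution(P, 6)), unname(Q[1, ]))
})

test_that("simulated outcome frequencies match the chain distribution", {
  P <- cumulative_tox_matrix(0.13, 0.05, 0.25)
  truth <- outcome_distribution(P, 6)
  set.seed(5)
  n <- 20000
  z <- vapply(seq_len(n), function(i) simulate_trajectory(P, 6)$z,
              integer(1))
  freq <- tabulate(z + 1L, 3) / n
  se <- sqrt(truth * (1 - truth) / n)
  expect_true(all(abs(freq - truth) <= 4 * se + 1e-9))
})

test_that("deterministic chains give deterministic event times", {
  P <- matrix(c(0, 1, 0, 0, 0, 1, 0, 0, 1), 3, 3, byrow = TRUE)
  tr <- simulate_trajectory(P, 6)
  expect_equal(tr$t_mt, 1)
  expect_equal(tr$t_dlt, 2)
  expect_equal(tr$z, 2L)
  expect_equal(simulate_trajectory(diag(3), 6)$z, 0L)
})

test_that("trajectories are nondecreasing with consistent event times", {
  P <- cumulative_tox_matrix(0.2, 0.1, 0.3)
  set.seed(17)
  for (i in 1:200) {
    tr <- simulate_trajectory(P, 6)
    expect_true(all(diff(tr$path) >= 0))
    if (!is.na(tr$t_dlt)) expect_true(is.na(tr$t_mt) || tr$t_mt <= tr$t_dlt)
    expect_equal(tr$z, tr$path[6])
  }
})

test_that("true MTD applies both constraints with boundary inclusion", {
  cons <- standard_constraints()
  mk <- function(q1, q2) {
    probs <- cbind(1 - q1, q1 - q2, q2)
    colnames(probs) <- c("p0", "p1", "p2")
    structure(list(probs = probs, K = length(q1), M = 6),
              class = "scenario_spec")
  }
  # boundary equality satisfies the constraint
  s <- mk(q1 = rep(0.4, 5), q2 = c(0.05, 0.15, 0.25, 0.40, 0.55))
  expect_equal(true_mtd(s, cons), 3L)
  # dose 1 already violating the moderate constraint -> no MTD
  s <- mk(q1 = c(0.6, 0.7, 0.8), q2 = c(0.1, 0.2, 0.3))
  expect_true(is.na(true_mtd(s, cons)))
  # moderate arm limiting
  s <- mk(q1 = c(0.30, 0.50, 0.65, 0.8, 0.9), q2 = rep(0.05, 5))
  expect_equal(true_mtd(s, cons), 2L)
})

test_that("shipped scenarios are monotone with the advertised MTDs", {
  cons <- standard_constraints()
  scens <- example_scenarios()
  for (s in scens) {
    q1 <- 1 - s$probs[, 1]
    q2 <- s$probs[, 3]
    expect_true(all(diff(q1) > 0) && all(diff(q2) > 0))
  }
  expect_equal(unname(sapply(scens, true_mtd, cons)), c(1L, 3L, 2L))
})

test_that("accrual models give the stated arrival processes", {
  expect_equal(accrual_times(3, "fixed", 1), c(0, 1, 2))
  expect_equal(accrual_times(2, "fixed", 2), c(0, 0.5))
  set.seed(9)
  tt <- accrual_times(10000, "poisson", 1)
  expect_true(all(diff(tt) >= 0))
  expect_lt(abs(mean(diff(tt)) - 1), 0.04)
})

test_that("the shipped scenario file matches the built-in scenario", {
  f <- system.file("extdata", "scenario_coincide_mtd1.yaml",
                   package = "titecrmmc")
  s <- read_scenario(f)
  expect_equal(s$probs, example_scenarios()$coincide_mtd1$probs,
               tolerance = 1e-12)
  expect_equal(true_mtd(s, standard_constraints()), 1L)
})

test_that("scenario files round-trip through YAML and CSV", {
  scen <- example_scenarios()$coincide_mtd1
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = "rt", M = 6,
                        doses = lapply(scen$matrices, function(P)
                          lapply(seq_len(3), function(i) P[i, ]))), yml)
  back <- read_scenario(yml)
  expect_equal(back$probs, scen$probs)
  csv <- tempfile(fileext = ".csv")
  df <- do.call(rbind, lapply(seq_along(scen$matrices), function(k) {
    P <- scen$matrices[[k]]
    data.frame(dose = k, row = 0:2, to0 = P[, 1], to1 = P[, 2], to2 = P[, 3])
  }))
  write.csv(df, csv, row.names = FALSE)
  back2 <- read_scenario(csv)
  expect_equal(back2$probs, scen$probs)
})
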