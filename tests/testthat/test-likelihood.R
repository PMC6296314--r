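test_that("single-patient likelihood factors are the model probabilities", {
  grid <- standard_grid()
  b10 <- model_params(1, 1e-9)  # beta2 ~ 0: F2 ~ F1
  # Y = 2 at x = 0.25, beta = (1, 0), w = 1 -> log(0.25)
  p <- complete_records(3, 2L)
  expect_equal(weighted_log_likelihood(p, b10, grid), log(0.25),
               tolerance = 1e-6)
  # Y = 0 at x = 0.25 -> log(0.75)
  p <- complete_records(3, 0L)
  expect_equal(weighted_log_likelihood(p, b10, grid), log(0.75),
               tolerance = 1e-6)
})

test_that("the likelihood multiplies over patients", {
  grid <- dose_grid(c(0.25, 0.5))
  params <- model_params(1, 1)
  p <- complete_records(c(2, 2), c(1L, 2L))  # both at x = 0.5
  expect_equal(weighted_log_likelihood(p, params, grid),
               log(0.5 - 0.25) + log(0.25))
})

test_that("log-likelihood is invariant to patient order", {
  grid <- standard_grid()
  params <- model_params(0.7, 0.4)
  set.seed(3)
  p <- patient_records(dose_index = sample(1:5, 12, TRUE),
                       entry_time = 0:11,
                       t_mt = sample(c(NA, 1, 2, 4), 12, TRUE),
                       now = 14)
  p$t_dlt <- ifelse(!is.na(p$t_mt) & runif(12) < 0.4, p$t_mt + 1, NA)
  p <- update_followups(p, 14)
  perm <- p[sample(nrow(p)), ]
  expect_equal(weighted_log_likelihood(p, params, grid),
               weighted_log_likelihood(perm, params, grid))
})

test_that("heterogeneity status drives the staged design", {
  # nothing observed
  p <- patient_records(1:3, entry_time = 0:2, now = 3)
  expect_equal(heterogeneity_status(p), "no_grade2_yet")
  # moderate events, no DLT
  p <- patient_records(c(1, 1, 2), entry_time = 0, t_mt = c(2, NA, NA),
                       now = 3)
  expect_equal(heterogeneity_status(p), "moderate_only")
  # a DLT but no qualifying moderate-only completion
  p <- patient_records(c(1, 2), entry_time = 0, t_mt = c(NA, 2),
                       t_dlt = c(NA, 2), now = 3)
  expect_equal(heterogeneity_status(p), "dlt_without_moderate")
  # a DLT, a completed toxicity-free patient, a completed moderate patient
  p <- patient_records(c(1, 1, 2), entry_time = 0,
                       t_mt = c(NA, 3, 2), t_dlt = c(NA, NA, 2), now = 6)
  expect_equal(heterogeneity_status(p), "full")
  # the moderate patient still mid-follow-up does not qualify
  p <- patient_records(c(1, 1, 2), entry_time = c(0, 4, 0),
                       t_mt = c(NA, 1, 2), t_dlt = c(NA, NA, 2), now = 6)
  expect_equal(heterogeneity_status(p), "dlt_without_moderate")
})

test_that("the MLE does not exist before full heterogeneity", {
  p <- patient_records(1:3, entry_time = 0, now = 6)  # all Y = 0
  fit <- fit_mle(p, standard_grid())
  expect_s3_class(fit, "crmmc_fit")
  expect_equal(fit$status, "not_estimable")
  expect_equal(fit$reason, "no_grade2_yet")
})

test_that("MLE matches the closed-form multinomial fit", {
  # one patient of each outcome at x = 0.25 with full follow-up: the
  # unconstrained multinomial MLE is F1 = 2/3, F2 = 1/3, mapped through
  # the power model
  grid <- standard_grid()
  p <- complete_records(c(3, 3, 3), c(0L, 1L, 2L))
  fit <- fit_mle(p, grid)
  expect_equal(fit$status, "ok")
  expect_equal(fit$params$beta1, log(2 / 3) / log(0.25), tolerance = 1e-4)
  expect_equal(fit$params$beta1 + fit$params$beta2,
               log(1 / 3) / log(0.25), tolerance = 1e-4)
})

test_that("rescaling the weights of DLT patients leaves the MLE unchanged", {
  # the Y = 2 factor carries its weight as a beta-free constant
  grid <- standard_grid()
  set.seed(21)
  p <- simulate_model_outcomes(15, grid, model_params(0.8, 0.6))
  expect_equal(heterogeneity_status(p), "full")
  fit1 <- fit_mle(p, grid)
  q <- p
  q$c[q$y == 2L] <- pmax(q$t_dlt[q$y == 2L], 3)  # shrink their follow-up
  fit2 <- fit_mle(q, grid)
  expect_equal(fit1$gamma, fit2$gamma, tolerance = 1e-4)
})

test_that("with only DLT-or-nothing outcomes the model factorises like a
          single-constraint TITE-CRM", {
  grid <- standard_grid()
  # all events are direct DLTs; with beta2 = 0 each factor equals the
  # binary TITE likelihood factor with F = x^beta1
  p <- patient_records(c(1, 2, 3, 3), entry_time = c(0, 1, 2, 3),
                       t_mt = c(NA, 2, NA, 1), t_dlt = c(NA, 2, NA, 1),
                       now = 5)
  for (b in c(0.5, 1, 2)) {
    params <- model_params(b, 0)
    x <- grid$skeleton[p$dose_index]
    w <- linear_weight(p$c)
    e <- p$y == 2L
    binary <- sum(log(ifelse(e, w * x^b, 1 - w * x^b)))
    expect_equal(weighted_log_likelihood(p, params, grid), binary)
  }
})

test_that("parameter recovery from moderately sized complete data", {
  grid <- standard_grid()
  truth <- model_params(1.0, 0.5)
  set.seed(99)
  p <- simulate_model_outcomes(150, grid, truth)
  fit <- fit_mle(p, grid)
  expect_equal(fit$status, "ok")
  expect_lt(abs(fit$params$beta1 - 1.0), 0.25)
  expect_lt(abs(fit$params$beta2 - 0.5), 0.35)
})
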