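#' Configuration of a simulated dose-finding trial
#'
#' @param grid a [dose_grid()].
#' @param n total sample size.
#' @param constraints a [toxicity_constraints()].
#' @param M assessment window in cycles.
#' @param estimation `"likelihood_staged"` (three-stage design with MLE),
#'   `"bayes_normal"` or `"bayes_exponential"` (model-based from the first
#'   patient under the respective prior).
#' @param cohort_size stage-1 cohort size.
#' @param accrual `"fixed"` or `"poisson"`.
#' @param accrual_rate patients per cycle.
#' @param start_dose dose for the first patient (stage-1 cohorts start
#'   here).
#' @param bayes_engine `"quadrature"` (deterministic product-trapezoid
#'   integration, the default) or `"mcmc"` (adaptive random-walk
#'   Metropolis).
#' @param n_grid quadrature nodes per axis.
#' @param n_draws MCMC draws per dose decision (mcmc engine).
#' @param sigma prior standard deviation for the normal-on-log prior and
#'   for the single-constraint TITE-CRM comparator.
#' @param weight_fn time-to-event weight function `function(c, M)`.
#' @param selection_rule Bayesian dose-summary rule, `"distance"` or
#'   `"satisfy"`.
#' @return an object of class `trial_config`.
#' @export
trial_config <- function(grid, n = 24,
                         constraints = toxicity_constraints(),
                         M = 6,
                         estimation = c("likelihood_staged", "bayes_normal",
                                        "bayes_exponential"),
                         cohort_size = 3, accrual = c("fixed", "poisson"),
                         accrual_rate = 1, start_dose = 1,
                         bayes_engine = c("quadrature", "mcmc"),
                         n_grid = 61, n_draws = 4000, sigma = 1.34,
                         weight_fn = linear_weight,
                         selection_rule = c("distance", "satisfy")) {
  estimation <- match.arg(estimation)
  accrual <- match.arg(accrual)
  bayes_engine <- match.arg(bayes_engine)
  selection_rule <- match.arg(selection_rule)
  if (n < cohort_size) stop("n must be at least one cohort")
  if (start_dose < 1 || start_dose > grid$K) stop("start_dose out of range")
  structure(list(grid = grid, n = n, constraints = constraints, M = M,
                 estimation = estimation, cohort_size = cohort_size,
                 accrual = accrual, accrual_rate = accrual_rate,
                 start_dose = as.integer(start_dose),
                 bayes_engine = bayes_engine, n_grid = n_grid,
                 n_draws = n_draws, sigma = sigma, weight_fn = weight_fn,
                 selection_rule = selection_rule),
            class = "trial_config")
}

empty_records <- function() {
  df <- data.frame(dose_index = integer(0), entry_time = numeric(0),
                   t_mt = numeric(0), t_dlt = numeric(0), c = numeric(0),
                   y = integer(0))
  class(df) <- c("patient_records", "data.frame")
  df
}

argmin_dose_low <- function(F, target) which.min(abs(F - target))

# grade >= 2 event strictly before any DLT (a direct 0 -> DLT jump is not a
# separate moderate event)
moderate_event_seen <- function(recs) {
  any(!is.na(recs$t_mt) & recs$t_mt <= recs$c &
        (is.na(recs$t_dlt) | recs$t_mt < recs$t_dlt))
}

# dose decision of the staged likelihood design for the j-th arrival
# (j = n + 1 with complete follow-up gives the final selection); the
# first-cohort special rules are handled by the engine before this is called
decide_likelihood <- function(j, recs, cfg, current_dose, final = FALSE) {
  cs <- cfg$cohort_size
  K <- cfg$grid$K
  if (!final && j <= cs)
    return(list(dose = cfg$start_dose, stage = "stage1", stop = FALSE))
  any_dlt <- any(!is.na(recs$t_dlt) & recs$t_dlt <= recs$c)
  any_mod <- moderate_event_seen(recs)
  if (!any_dlt && !any_mod) {
    dose <- min(cfg$start_dose + ceiling(j / cs) - 1L, K)
    return(list(dose = dose, stage = "stage1", stop = FALSE))
  }
  het <- heterogeneity_status(recs, cfg$M)
  if (het == "full") {
    fit <- fit_mle(recs, cfg$grid, cfg$M, cfg$weight_fn)
    return(list(dose = recommend_mle(fit$params, cfg$grid, cfg$constraints),
                stage = "stage3", stop = FALSE))
  }
  x <- cfg$grid$skeleton[recs$dose_index]
  w <- cfg$weight_fn(recs$c, cfg$M)
  if (any_dlt) {
    events <- !is.na(recs$t_dlt) & recs$t_dlt <= recs$c
    beta <- fit_tite1(events, x, w)
    dose <- if (is.na(beta)) current_dose else
      argmin_dose_low(cfg$grid$skeleton^beta, cfg$constraints$p_dlt)
    list(dose = dose, stage = "stage2_dlt", stop = FALSE)
  } else {
    events <- recs$y >= 1L
    beta <- fit_tite1(events, x, w)
    dose <- if (is.na(beta)) current_dose else
      argmin_dose_low(cfg$grid$skeleton^beta, cfg$constraints$p_mt)
    list(dose = dose, stage = "stage2_mt", stop = FALSE)
  }
}

decide_bayes <- function(j, recs, cfg, prior, final = FALSE, mcmc_seed = NULL) {
  if (!final && j == 1L)
    return(list(dose = cfg$start_dose, stage = "bayes", stop = FALSE))
  if (cfg$bayes_engine == "quadrature") {
    summ <- posterior_dose_quadrature(recs, prior, cfg$grid, cfg$constraints,
                                      M = cfg$M, weight_fn = cfg$weight_fn,
                                      n_grid = cfg$n_grid,
                                      rule = cfg$selection_rule)
  } else {
    draws <- posterior_draws(recs, prior, cfg$grid, n_draws = cfg$n_draws,
                             seed = mcmc_seed, M = cfg$M,
                             weight_fn = cfg$weight_fn)
    summ <- constraint_dose_distribution(draws, cfg$grid, cfg$constraints,
                                         rule = cfg$selection_rule)
  }
  list(dose = recommend_bayes(summ), stage = "bayes", stop = FALSE)
}

make_trial_result <- function(recs, assignments, stages, selection, stopped,
                              n_to_het, K, seed) {
  alloc <- tabulate(recs$dose_index, nbins = K)
  structure(list(selection = selection, stopped = stopped,
                 patients = recs, assignments = assignments,
                 stages = stages, allocations = alloc,
                 n_moderate = sum(recs$y == 1L),
                 n_dlt = sum(recs$y == 2L),
                 n_to_full_heterogeneity = n_to_het,
                 n_enrolled = nrow(recs), seed = seed),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  if (x$stopped) cat("trial stopped early (all-DLT first cohort);")
  else cat("recommended dose level:", x$selection, "-")
  cat(" n =", x$n_enrolled, "| moderate:", x$n_moderate,
      "| DLT:", x$n_dlt, "\n")
  cat("allocations:", paste(x$allocations, collapse = " "), "\n")
  invisible(x)
}

#' Simulate one TITE-CRM trial with multiple constraints
#'
#' Runs the design patient by patient: at each arrival every enrollee's
#' follow-up and censored outcome are updated to the current time and the
#' arriving patient's dose is chosen by the configured estimation path,
#' subject to the no-skipping cap.  The likelihood path is the three-stage
#' design (stage-1 cohorts escalating one level per toxicity-free cohort
#' until the first grade >= 2 toxicity; a single-constraint TITE-CRM in
#' stage 2; the full two-constraint model once outcome heterogeneity is
#' full, skipping stage 2 if heterogeneity arrives in stage 1), with the
#' first-cohort special rules: an all-moderate first cohort repeats its dose
#' for the next cohort and an all-DLT first cohort stops the trial.  The
#' Bayesian paths use the posterior dose summaries from the first patient
#' on.  The final recommendation is made after every patient completes the
#' assessment window, i.e. on complete observations with unit weights.
#'
#' Patient responses are generated from the scenario's per-dose transition
#' matrices via per-patient latent uniforms drawn up front, so responses do
#' not depend on entry times or on the estimation path consuming the
#' stream.
#'
#' @param config a [trial_config()].
#' @param scenario a [scenario_spec()] with as many doses as the grid.
#' @param seed optional integer seed making the trial reproducible.
#' @return an object of class `trial_result`.
#' @export
run_titecrmmc_trial <- function(config, scenario, seed = NULL) {
  if (scenario$K != config$grid$K)
    stop("scenario and dose grid disagree on the number of doses")
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
  }
  n <- config$n; M <- config$M; K <- config$grid$K
  U <- matrix(stats::runif(n * M), n, M)
  entry <- accrual_times(n, config$accrual, config$accrual_rate)
  mcmc_seeds <- if (config$bayes_engine == "mcmc")
    sample.int(2147483646L, n + 1L) else rep(NA_integer_, n + 1L)
  prior <- switch(config$estimation,
                  bayes_normal = prior_spec("normal_on_log",
                                            sigma = config$sigma),
                  bayes_exponential = prior_spec("exponential_on_beta"),
                  NULL)
  recs <- empty_records()
  assignments <- integer(0)
  stages <- character(0)
  stopped <- FALSE
  highest <- 0L
  current <- config$start_dose
  n_to_het <- NA_integer_
  repeat_first <- FALSE
  cs <- config$cohort_size
  likelihood <- config$estimation == "likelihood_staged"
  for (j in seq_len(n)) {
    recs_now <- update_followups(recs, entry[j], M)
    if (is.na(n_to_het) && nrow(recs_now) > 0L &&
        heterogeneity_status(recs_now, M) == "full")
      n_to_het <- nrow(recs_now)
    dec <- NULL
    if (likelihood && j > cs && j <= 2L * cs) {
      # first-cohort special rules (likelihood path only): an all-DLT first
      # cohort stops the trial; an all-moderate first cohort repeats its
      # dose for the whole of cohort 2, decided when cohort 2 starts
      if (all(recs_now$y[seq_len(cs)] == 2L))
        dec <- list(dose = NA_integer_, stage = "stopped", stop = TRUE)
      else {
        if (j == cs + 1L)
          repeat_first <- all(recs_now$y[seq_len(cs)] == 1L)
        if (repeat_first)
          dec <- list(dose = config$start_dose, stage = "cohort_repeat",
                      stop = FALSE)
      }
    }
    if (is.null(dec))
      dec <- if (likelihood) decide_likelihood(j, recs_now, config, current)
      else decide_bayes(j, recs_now, config, prior,
                        mcmc_seed = mcmc_seeds[j])
    if (dec$stop) { stopped <- TRUE; break }
    dose <- max(1L, min(dec$dose, K))
    if (j > 1L) dose <- restrict_no_skip(dose, highest)
    traj <- trajectory_from_uniforms(scenario$matrices[[dose]], M, U[j, ])
    recs <- rbind(recs, data.frame(dose_index = dose, entry_time = entry[j],
                                   t_mt = traj$t_mt, t_dlt = traj$t_dlt,
                                   c = NA_real_, y = NA_integer_))
    class(recs) <- c("patient_records", "data.frame")
    assignments <- c(assignments, dose)
    stages <- c(stages, dec$stage)
    highest <- max(highest, dose)
    current <- dose
  }
  end_time <- if (nrow(recs)) max(recs$entry_time) + M else 0
  recs <- update_followups(recs, end_time, M)
  if (is.na(n_to_het) && nrow(recs) > 0L &&
      heterogeneity_status(recs, M) == "full")
    n_to_het <- nrow(recs)
  selection <- NA_integer_
  if (!stopped && nrow(recs) > 0L) {
    if (likelihood && nrow(recs) == cs && all(recs$y == 2L)) {
      stopped <- TRUE  # all-DLT first cohort seen only at trial end
    } else {
      dec <- if (likelihood)
        decide_likelihood(nrow(recs) + 1L, recs, config, current,
                          final = TRUE)
      else decide_bayes(nrow(recs) + 1L, recs, config, prior, final = TRUE,
                        mcmc_seed = mcmc_seeds[n + 1L])
      selection <- restrict_no_skip(max(1L, min(dec$dose, K)), highest)
    }
  }
  make_trial_result(recs, assignments, stages, selection, stopped,
                    n_to_het, K, seed)
}

# posterior mean of beta for the one-parameter empiric model x^beta,
# beta = exp(gamma), gamma ~ N(0, sigma^2), by 1-D trapezoid quadrature
titecrm_posterior_mean <- function(events, x, w, sigma, n_grid = 201,
                                   span = 6) {
  gs <- seq(-span * sigma, span * sigma, length.out = n_grid)
  tw <- rep(1, n_grid); tw[c(1, n_grid)] <- 0.5
  logx <- log(x)
  ll <- vapply(gs, function(g) {
    if (!length(x)) return(0)
    F <- exp(exp(g) * logx)
    p <- ifelse(events, w * F, 1 - w * F)
    if (any(p <= 0)) return(-1e10)
    sum(log(p))
  }, numeric(1))
  lw <- ll + stats::dnorm(gs, 0, sigma, log = TRUE)
  wq <- tw * exp(lw - max(lw))
  sum(wq * exp(gs)) / sum(wq)
}

#' Simulate one single-constraint TITE-CRM trial (comparator)
#'
#' The conventional TITE-CRM on the DLT outcome alone, with the empiric
#' working model `x^beta`, `beta = exp(gamma)`.  The default Bayesian
#' variant uses a `N(0, sigma^2)` prior on `gamma` and assigns
#' `argmin_k |x_k^b - p_dlt|` with `b` the posterior mean of `beta`
#' (computed by deterministic 1-D quadrature), model-based from the second
#' patient on.  `estimation = "likelihood"` instead mirrors the staged
#' design restricted to the DLT constraint: stage-1 cohorts until the first
#' DLT (with the all-DLT first-cohort stop), then the one-parameter
#' weighted MLE.  No-skipping and the complete-observation final selection
#' are as in [run_titecrmmc_trial()].
#'
#' @inheritParams run_titecrmmc_trial
#' @param estimation `"bayes"` or `"likelihood"`.
#' @return an object of class `trial_result`.
#' @export
run_titecrm_trial <- function(config, scenario, seed = NULL,
                              estimation = c("bayes", "likelihood")) {
  estimation <- match.arg(estimation)
  if (scenario$K != config$grid$K)
    stop("scenario and dose grid disagree on the number of doses")
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
  }
  n <- config$n; M <- config$M; K <- config$grid$K
  cs <- config$cohort_size
  U <- matrix(stats::runif(n * M), n, M)
  entry <- accrual_times(n, config$accrual, config$accrual_rate)
  recs <- empty_records()
  assignments <- integer(0)
  stages <- character(0)
  stopped <- FALSE
  highest <- 0L
  current <- config$start_dose

  decide <- function(j, recs_now, final = FALSE) {
    if (estimation == "bayes") {
      if (!final && j == 1L)
        return(list(dose = config$start_dose, stage = "bayes", stop = FALSE))
      events <- !is.na(recs_now$t_dlt) & recs_now$t_dlt <= recs_now$c
      x <- config$grid$skeleton[recs_now$dose_index]
      w <- config$weight_fn(recs_now$c, M)
      b <- titecrm_posterior_mean(events, x, w, config$sigma)
      dose <- argmin_dose_low(config$grid$skeleton^b,
                              config$constraints$p_dlt)
      return(list(dose = dose, stage = "bayes", stop = FALSE))
    }
    # likelihood variant: staged on the DLT outcome only
    if (!final && j <= cs)
      return(list(dose = config$start_dose, stage = "stage1", stop = FALSE))
    if (nrow(recs_now) >= cs && (j <= 2L * cs ||
                                 (final && nrow(recs_now) <= cs))) {
      if (all(recs_now$y[seq_len(cs)] == 2L))
        return(list(dose = NA_integer_, stage = "stopped", stop = TRUE))
    }
    any_dlt <- any(!is.na(recs_now$t_dlt) & recs_now$t_dlt <= recs_now$c)
    if (!any_dlt) {
      dose <- min(config$start_dose + ceiling(j / cs) - 1L, K)
      return(list(dose = dose, stage = "stage1", stop = FALSE))
    }
    events <- !is.na(recs_now$t_dlt) & recs_now$t_dlt <= recs_now$c
    x <- config$grid$skeleton[recs_now$dose_index]
    w <- config$weight_fn(recs_now$c, M)
    beta <- fit_tite1(events, x, w)
    dose <- if (is.na(beta)) current else
      argmin_dose_low(config$grid$skeleton^beta, config$constraints$p_dlt)
    list(dose = dose, stage = "stage2_dlt", stop = FALSE)
  }

  for (j in seq_len(n)) {
    recs_now <- update_followups(recs, entry[j], M)
    dec <- decide(j, recs_now)
    if (dec$stop) { stopped <- TRUE; break }
    dose <- max(1L, min(dec$dose, K))
    if (j > 1L) dose <- restrict_no_skip(dose, highest)
    traj <- trajectory_from_uniforms(scenario$matrices[[dose]], M, U[j, ])
    recs <- rbind(recs, data.frame(dose_index = dose, entry_time = entry[j],
                                   t_mt = traj$t_mt, t_dlt = traj$t_dlt,
                                   c = NA_real_, y = NA_integer_))
    class(recs) <- c("patient_records", "data.frame")
    assignments <- c(assignments, dose)
    stages <- c(stages, dec$stage)
    highest <- max(highest, dose)
    current <- dose
  }
  end_time <- if (nrow(recs)) max(recs$entry_time) + M else 0
  recs <- update_followups(recs, end_time, M)
  selection <- NA_integer_
  if (!stopped && nrow(recs) > 0L) {
    dec <- decide(nrow(recs) + 1L, recs, final = TRUE)
    if (dec$stop) stopped <- TRUE
    else selection <- restrict_no_skip(max(1L, min(dec$dose, K)), highest)
  }
  make_trial_result(recs, assignments, stages, selection, stopped,
                    NA_integer_, K, seed)
}
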