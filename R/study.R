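#' Probability of correct selection and of overdosing
#'
#' `pcs` is the proportion of simulated trials recommending the true MTD;
#' early-stopped trials (selection `NA`) count as not correct.  When the
#' scenario has no tolerable dose (`theta = NA`) the correct action is to
#' stop, so `pcs` is the proportion of stopped trials.  `prob_above` is the
#' proportion recommending a dose above the true MTD; it is `NA` when the
#' true MTD is the highest dose level (not applicable) and 0 when there is
#' no true MTD (stopping is not overdosing, and any selection is counted by
#' `pcs`, not here).
#'
#' @param selections integer vector of selected dose indices, `NA` for
#'   stopped trials.
#' @param theta true MTD index, or `NA` when no dose is tolerable.
#' @param K number of dose levels (needed to recognise `theta = K`).
#' @return a proportion.
#' @export
pcs <- function(selections, theta, K = max(selections, na.rm = TRUE)) {
  if (!length(selections)) stop("no selections")
  if (is.na(theta)) return(mean(is.na(selections)))
  mean(!is.na(selections) & selections == theta)
}

#' @rdname pcs
#' @export
prob_above <- function(selections, theta, K = max(selections, na.rm = TRUE)) {
  if (!length(selections)) stop("no selections")
  if (is.na(theta)) return(0)
  if (theta == K) return(NA_real_)
  mean(!is.na(selections) & selections > theta)
}

# fixed method codes keep per-replicate seeds stable when the set of
# methods in a study changes
method_code <- function(method) {
  codes <- c(titecrmmc_likelihood = 1L, titecrmmc_bayes_normal = 2L,
             titecrmmc_bayes_exponential = 3L, titecrm_bayes = 4L,
             titecrm_likelihood = 5L, benchmark = 6L)
  if (!method %in% names(codes)) stop("unknown method: ", method)
  codes[[method]]
}

derive_seed <- function(seed, scen_idx, mcode, rep) {
  s <- ((as.numeric(seed) %% 100000) * 31 + scen_idx * 1009 +
          mcode * 10007) %% 2101001
  as.integer((s * 1013 + rep) %% 2147483587 + 1)
}

run_one <- function(method, config, scenario, seed) {
  switch(method,
    titecrmmc_likelihood = {
      cfg <- config; cfg$estimation <- "likelihood_staged"
      run_titecrmmc_trial(cfg, scenario, seed)
    },
    titecrmmc_bayes_normal = {
      cfg <- config; cfg$estimation <- "bayes_normal"
      run_titecrmmc_trial(cfg, scenario, seed)
    },
    titecrmmc_bayes_exponential = {
      cfg <- config; cfg$estimation <- "bayes_exponential"
      run_titecrmmc_trial(cfg, scenario, seed)
    },
    titecrm_bayes = run_titecrm_trial(config, scenario, seed,
                                      estimation = "bayes"),
    titecrm_likelihood = run_titecrm_trial(config, scenario, seed,
                                           estimation = "likelihood"),
    stop("unknown method: ", method))
}

#' Operating-characteristics study over scenarios and methods
#'
#' Runs `reps` independent simulated trials for every scenario x method
#' combination with a deterministic per-replicate seed schedule (derived
#' from the study seed, the scenario position and a fixed per-method code,
#' so adding or dropping methods leaves the other methods' streams
#' untouched) and aggregates selections and allocations into the usual
#' operating characteristics.  The `"benchmark"` method simulates complete
#' profiles instead of running a trial.
#'
#' @param scenarios named list of [scenario_spec()] objects.
#' @param methods character vector among `"titecrmmc_likelihood"`,
#'   `"titecrmmc_bayes_normal"`, `"titecrmmc_bayes_exponential"`,
#'   `"titecrm_bayes"`, `"titecrm_likelihood"`, `"benchmark"`.
#' @param config a [trial_config()] template (its `estimation` field is
#'   overridden per method).
#' @param reps replicates per combination.
#' @param seed study seed.
#' @return an object of class `oc_study`: list with `oc` (one row per
#'   scenario x method: `theta`, `pcs`, `pcs_se`, `prob_above`, mean
#'   toxicity counts, median patients to full heterogeneity, selection and
#'   allocation frequencies) and `selections` (long format, one row per
#'   replicate).
#' @export
run_study <- function(scenarios, methods, config, reps = 200, seed = 1) {
  if (reps < 1) stop("reps must be >= 1")
  if (is.null(names(scenarios)))
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  K <- config$grid$K
  oc_rows <- list()
  sel_rows <- list()
  for (si in seq_along(scenarios)) {
    scen <- scenarios[[si]]
    theta <- true_mtd(scen, config$constraints)
    for (method in methods) {
      mc <- method_code(method)
      if (method == "benchmark") {
        sel <- vapply(seq_len(reps), function(r) {
          s <- derive_seed(seed, si, mc, r)
          benchmark_selections(scen, config$n, 1L, config$constraints,
                               seed = s)
        }, integer(1))
        n_mod <- n_dlt <- n_het <- rep(NA_real_, reps)
        alloc <- matrix(NA_real_, reps, K)
      } else {
        sel <- integer(reps); n_mod <- n_dlt <- n_het <- numeric(reps)
        alloc <- matrix(0, reps, K)
        for (r in seq_len(reps)) {
          res <- run_one(method, config, scen, derive_seed(seed, si, mc, r))
          sel[r] <- if (res$stopped) NA_integer_ else res$selection
          n_mod[r] <- res$n_moderate
          n_dlt[r] <- res$n_dlt
          n_het[r] <- res$n_to_full_heterogeneity
          alloc[r, ] <- res$allocations
        }
      }
      p <- pcs(sel, theta, K)
      sel_freq <- vapply(seq_len(K), function(k)
        mean(!is.na(sel) & sel == k), numeric(1))
      row <- data.frame(scenario = names(scenarios)[si], method = method,
                        theta = theta, reps = reps, pcs = p,
                        pcs_se = sqrt(p * (1 - p) / reps),
                        prob_above = prob_above(sel, theta, K),
                        prob_stopped = mean(is.na(sel)),
                        mean_moderate = mean(n_mod),
                        mean_dlt = mean(n_dlt),
                        median_n_to_heterogeneity =
                          if (all(is.na(n_het))) NA_real_
                          else stats::median(n_het, na.rm = TRUE))
      for (k in seq_len(K)) row[[paste0("sel_", k)]] <- sel_freq[k]
      for (k in seq_len(K)) row[[paste0("alloc_", k)]] <-
        mean(alloc[, k]) / config$n
      oc_rows[[length(oc_rows) + 1L]] <- row
      sel_rows[[length(sel_rows) + 1L]] <-
        data.frame(scenario = names(scenarios)[si], method = method,
                   rep = seq_len(reps), selection = sel)
    }
  }
  structure(list(oc = do.call(rbind, oc_rows),
                 selections = do.call(rbind, sel_rows),
                 seed = seed, n = config$n),
            class = "oc_study")
}

#' @export
print.oc_study <- function(x, ...) {
  cat("operating characteristics (", x$oc$reps[1], "replicates, n =",
      x$n, ")\n")
  print(x$oc[, c("scenario", "method", "theta", "pcs", "pcs_se",
                 "prob_above", "prob_stopped")], row.names = FALSE)
  invisible(x)
}
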