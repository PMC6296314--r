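#' Prior specification for Bayesian estimation
#'
#' Two parametrisations are supported.  `"normal_on_log"` places independent
#' `N(0, sigma^2)` priors on the log-scale parameters `gamma_l` with
#' `beta_l = exp(gamma_l)`; the default `sigma = 1.34` is used as a standard
#' deviation.  `"exponential_on_beta"` places independent Exponential(rate)
#' priors directly on `beta_l` (the multiple-constraint CRM convention);
#' internally the density is carried on the gamma scale with its Jacobian.
#'
#' @param kind `"normal_on_log"` or `"exponential_on_beta"`.
#' @param sigma prior standard deviation of each `gamma_l` (normal prior).
#' @param rate prior rate of each `beta_l` (exponential prior).
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(kind = c("normal_on_log", "exponential_on_beta"),
                       sigma = 1.34, rate = 1) {
  kind <- match.arg(kind)
  if (sigma <= 0 || rate <= 0) stop("sigma and rate must be positive")
  structure(list(kind = kind, sigma = sigma, rate = rate),
            class = "prior_spec")
}

# log prior density on the gamma (log beta) scale, including the Jacobian
# for the exponential-on-beta parametrisation
log_prior_gamma <- function(gamma, prior) {
  if (prior$kind == "normal_on_log") {
    sum(stats::dnorm(gamma, 0, prior$sigma, log = TRUE))
  } else {
    sum(log(prior$rate) - prior$rate * exp(gamma) + gamma)
  }
}

#' Log posterior density of the working-model parameters
#'
#' Weighted log-likelihood plus the log prior density in the prior's own
#' parametrisation (the gamma scale for the normal prior, the beta scale
#' for the exponential prior; the gamma-scale samplers add the Jacobian
#' themselves).  With no patient data the likelihood term vanishes and the
#' log prior alone is returned.  Parameters outside the prior support
#' (nonpositive `beta` under the exponential prior) give `-Inf`.
#'
#' @param params a [model_params()] object, or a length-2 numeric of
#'   `(beta1, beta2)`.
#' @param patients a [patient_records()] data frame (may have zero rows).
#' @param prior a [prior_spec()].
#' @inheritParams weighted_log_likelihood
#' @return the unnormalised log posterior density.
#' @export
log_posterior <- function(params, patients, prior, grid, M = 6,
                          weight_fn = linear_weight) {
  if (is.numeric(params)) {
    if (any(params <= 0)) return(-Inf)
    params <- model_params(params[1], params[2])
  }
  gamma <- c(log(params$beta1), log(params$beta2))
  if (any(!is.finite(gamma))) return(-Inf)
  lp <- if (prior$kind == "normal_on_log")
    sum(stats::dnorm(gamma, 0, prior$sigma, log = TRUE))
  else
    sum(log(prior$rate) - prior$rate * c(params$beta1, params$beta2))
  if (nrow(patients) > 0L)
    lp <- lp + weighted_log_likelihood(patients, params, grid, M, weight_fn)
  lp
}

#' Posterior draws by adaptive random-walk Metropolis
#'
#' Samples the posterior of `(gamma1, gamma2)` with a Gaussian random-walk
#' Metropolis sampler whose proposal scale is adapted towards an acceptance
#' rate of about 0.3 during burn-in and then frozen.  Four chains are run
#' from dispersed starting points and pooled after burn-in; a Gelman-Rubin
#' style scale-reduction diagnostic above 1.2 on either parameter raises an
#' error.  Draws are reproducible for a fixed `seed` and leave the caller's
#' RNG stream untouched.
#'
#' @inheritParams log_posterior
#' @param n_draws total number of pooled posterior draws (>= 1000).
#' @param seed integer seed for the sampler.
#' @param n_chains number of chains.
#' @param burn burn-in iterations per chain.
#' @return a matrix with columns `beta1`, `beta2` and attributes
#'   `acceptance` and `rhat`.
#' @export
posterior_draws <- function(patients, prior, grid, n_draws = 10000,
                            seed = NULL, M = 6, weight_fn = linear_weight,
                            n_chains = 4, burn = 2500) {
  if (n_draws < 1000) stop("n_draws must be at least 1000")
  if (!is.null(seed) && !is.na(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
  }
  lpost <- function(g) {
    ll <- log_prior_gamma(g, prior)
    if (nrow(patients) > 0L) {
      lk <- weighted_log_likelihood(patients, model_params_from_gamma(g),
                                    grid, M, weight_fn)
      ll <- ll + lk
    }
    if (!is.finite(ll)) -1e10 else ll
  }
  per_chain <- ceiling(n_draws / n_chains)
  starts <- list(c(0, 0), c(1, -1), c(-1, 1), c(0.5, 0.5))
  chains <- vector("list", n_chains)
  acc_all <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    g <- starts[[(ch - 1L) %% length(starts) + 1L]]
    lp <- lpost(g)
    scale <- 0.8
    keep <- matrix(NA_real_, per_chain, 2)
    n_acc <- 0L
    total <- burn + per_chain
    for (it in seq_len(total)) {
      prop <- g + stats::rnorm(2, 0, scale)
      lp_prop <- lpost(prop)
      if (log(stats::runif(1)) < lp_prop - lp) {
        g <- prop; lp <- lp_prop
        if (it > burn) n_acc <- n_acc + 1L
        acc <- 1
      } else acc <- 0
      if (it <= burn) scale <- exp(log(scale) + (acc - 0.3) / sqrt(it))
      if (it > burn) keep[it - burn, ] <- g
    }
    chains[[ch]] <- keep
    acc_all[ch] <- n_acc / per_chain
  }
  rhat <- vapply(1:2, function(j) {
    means <- vapply(chains, function(m) mean(m[, j]), numeric(1))
    vars <- vapply(chains, function(m) stats::var(m[, j]), numeric(1))
    W <- mean(vars)
    B <- per_chain * stats::var(means)
    sqrt(((per_chain - 1) / per_chain * W + B / per_chain) / W)
  }, numeric(1))
  if (any(!is.finite(rhat)) || any(rhat > 1.2))
    stop(sprintf("posterior sampler did not mix (rhat = %.3f, %.3f)",
                 rhat[1], rhat[2]))
  gam <- do.call(rbind, chains)[seq_len(n_draws), , drop = FALSE]
  out <- cbind(beta1 = exp(gam[, 1]), beta2 = exp(gam[, 2]))
  attr(out, "acceptance") <- acc_all
  attr(out, "rhat") <- rhat
  out
}

argmin_low <- function(v) which.min(v)  # which.min already takes the first (lowest) index on ties

# smallest index with cumulative mass >= 1/2 (lower median; conservative dosing)
lower_median_index <- function(mass) {
  unname(which(cumsum(mass) >= 0.5 - 1e-12)[1])
}

# per-parameter-value constraint doses: argmin_k |F_l(x_k) - p_l|, ties low
constraint_doses <- function(beta1, beta12, grid, constraints, rule) {
  logx <- log(grid$skeleton)
  F1 <- exp(outer(beta1, logx))
  F2 <- exp(outer(beta12, logx))
  if (rule == "distance") {
    d_mt <- max.col(-abs(F1 - constraints$p_mt), ties.method = "first")
    d_dlt <- max.col(-abs(F2 - constraints$p_dlt), ties.method = "first")
  } else {
    pick_max_ok <- function(FF, p) {
      ok <- FF <= p + 1e-12
      idx <- apply(ok, 1, function(r) if (any(r)) max(which(r)) else 1L)
      as.integer(idx)
    }
    d_mt <- pick_max_ok(F1, constraints$p_mt)
    d_dlt <- pick_max_ok(F2, constraints$p_dlt)
  }
  list(mt = d_mt, dlt = d_dlt)
}

#' Marginal posterior dose distributions under each constraint
#'
#' Maps each posterior draw to the dose level whose modelled probability is
#' closest to the respective target (`argmin_k |F_l(x_k; beta) - p_l|`, ties
#' to the lower dose), yielding the marginal posterior distribution over
#' dose levels for the moderate-toxicity and the DLT constraint, and their
#' medians (smallest index with cumulative mass >= 0.5).  The alternative
#' `rule = "satisfy"` maps a draw to the maximum dose satisfying the
#' constraint instead.
#'
#' @param draws matrix with columns `beta1`, `beta2` (e.g. from
#'   [posterior_draws()]); draw weights may be supplied for quadrature use.
#' @param grid a [dose_grid()].
#' @param constraints a [toxicity_constraints()].
#' @param weights optional nonnegative draw weights (default: equal).
#' @param rule `"distance"` (default) or `"satisfy"`.
#' @return an object of class `constraint_dose_summary`: list with
#'   `mass_mt`, `mass_dlt` (probability vectors over dose levels),
#'   `median_mt`, `median_dlt` (dose indices).
#' @export
constraint_dose_distribution <- function(draws, grid, constraints,
                                         weights = NULL,
                                         rule = c("distance", "satisfy")) {
  rule <- match.arg(rule)
  if (nrow(draws) == 0L) stop("no posterior draws")
  if (is.null(weights)) weights <- rep(1, nrow(draws))
  weights <- weights / sum(weights)
  d <- constraint_doses(draws[, 1], draws[, 1] + draws[, 2], grid,
                        constraints, rule)
  mass <- function(idx) {
    m <- vapply(seq_len(grid$K), function(k) sum(weights[idx == k]),
                numeric(1))
    names(m) <- grid$labels
    m
  }
  mass_mt <- mass(d$mt)
  mass_dlt <- mass(d$dlt)
  structure(list(mass_mt = mass_mt, mass_dlt = mass_dlt,
                 median_mt = lower_median_index(mass_mt),
                 median_dlt = lower_median_index(mass_dlt)),
            class = "constraint_dose_summary")
}

#' @export
print.constraint_dose_summary <- function(x, ...) {
  cat("marginal posterior dose distributions\n")
  print(rbind(`grade>=2` = round(x$mass_mt, 3), DLT = round(x$mass_dlt, 3)))
  cat(sprintf("median dose levels: grade>=2 -> %d, DLT -> %d\n",
              x$median_mt, x$median_dlt))
  invisible(x)
}

#' Posterior dose summary by two-dimensional quadrature
#'
#' Deterministic alternative to MCMC: the posterior over `(gamma1, gamma2)`
#' is integrated on a product trapezoid grid (normal prior: `+/- span`
#' prior standard deviations per axis; exponential prior: a fixed gamma
#' range covering essentially all prior mass) and pushed through the same
#' constraint-dose map as [constraint_dose_distribution()].
#'
#' @inheritParams log_posterior
#' @inheritParams constraint_dose_distribution
#' @param constraints a [toxicity_constraints()].
#' @param n_grid nodes per axis.
#' @param span half-width of the normal-prior grid in prior standard
#'   deviations.
#' @return a `constraint_dose_summary`.
#' @export
posterior_dose_quadrature <- function(patients, prior, grid, constraints,
                                      M = 6, weight_fn = linear_weight,
                                      n_grid = 61, span = 6,
                                      rule = c("distance", "satisfy")) {
  rule <- match.arg(rule)
  if (prior$kind == "normal_on_log") {
    gs <- seq(-span * prior$sigma, span * prior$sigma, length.out = n_grid)
  } else {
    gs <- seq(-12, 4.5, length.out = n_grid)
  }
  tw <- rep(1, n_grid); tw[c(1, n_grid)] <- 0.5
  nodes <- expand.grid(g1 = gs, g2 = gs)
  wt2 <- as.vector(outer(tw, tw))
  lp <- log_prior_gamma_vec(nodes$g1, prior) + log_prior_gamma_vec(nodes$g2, prior)
  if (nrow(patients) > 0L)
    lp <- lp + loglik_nodes(nodes$g1, nodes$g2, patients, grid, M, weight_fn)
  lw <- lp - max(lp)
  w <- wt2 * exp(lw)
  draws <- cbind(beta1 = exp(nodes$g1), beta2 = exp(nodes$g2))
  constraint_dose_distribution(draws, grid, constraints, weights = w,
                               rule = rule)
}

log_prior_gamma_vec <- function(g, prior) {
  if (prior$kind == "normal_on_log") {
    stats::dnorm(g, 0, prior$sigma, log = TRUE)
  } else {
    log(prior$rate) - prior$rate * exp(g) + g
  }
}

# vectorised weighted log-likelihood over many (gamma1, gamma2) nodes
loglik_nodes <- function(g1, g2, patients, grid, M, weight_fn) {
  x <- grid$skeleton[patients$dose_index]
  w <- weight_fn(patients$c, M)
  logx <- log(x)
  b1 <- exp(g1)
  b12 <- b1 + exp(g2)
  F1 <- exp(outer(b1, logx))            # nodes x patients
  F2 <- exp(outer(b12, logx))
  y <- patients$y
  P <- matrix(NA_real_, length(g1), length(y))
  for (j in seq_along(y)) {
    P[, j] <- switch(as.character(y[j]),
                     "0" = 1 - w[j] * F1[, j],
                     "1" = w[j] * (F1[, j] - F2[, j]),
                     "2" = w[j] * F2[, j])
  }
  P[P <= 0] <- NA
  ll <- rowSums(log(P))
  ll[!is.finite(ll)] <- -1e10
  ll
}
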