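---
title: "Dose finding under moderate-toxicity and DLT constraints: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose finding under moderate-toxicity and DLT constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titecrmmc)
```

## The problem

Conventional phase-I designs define the maximum tolerated dose (MTD) by a
single constraint on the probability of dose-limiting toxicity (DLT) within
one or two treatment cycles.  For targeted therapies given over many cycles,
two things go wrong: toxicities arrive late (so early dose decisions are
based on heavily censored data) and moderate (grade 2) toxicities — which
drive dose reductions and treatment discontinuation even though they are
not DLTs — are ignored.  This package implements a time-to-event continual
reassessment method with *multiple* toxicity constraints: the MTD is the
highest dose $x$ satisfying both

$$\Pr(Z \ge 1 \mid x) \le p_{\mathrm{MT}}, \qquad
  \Pr(Z \ge 2 \mid x) \le p_{\mathrm{DLT}},$$

where $Z \in \{0, 1, 2\}$ is the maximal toxicity grade over an $M$-cycle
window (none / moderate without DLT / DLT), with default targets
$(p_{\mathrm{MT}}, p_{\mathrm{DLT}}) = (0.50, 0.25)$ and $M = 6$.

## Working model and censored likelihood

The empiric two-parameter working model places both constraints on a common
skeleton $x_1 < \dots < x_K$:

$$F_1(x;\beta) = x^{\beta_1}, \qquad F_2(x;\beta) = x^{\beta_1+\beta_2},
  \qquad \beta_1 > 0,\ \beta_2 \ge 0,$$

so $F_2 \le F_1$ structurally.  Parameters are stored and optimised on the
log scale $\beta_l = e^{\gamma_l}$, which makes positivity structural rather
than a constraint-handling problem and avoids boundary pathologies;
probabilities are evaluated as $\exp(\beta \log x)$ for stability near
$x \to 0$.

A patient followed for $c \le M$ cycles has censored outcome $Y$ ($Y=2$ if
a DLT has occurred by $c$, $Y=1$ if only a moderate toxicity has, else
$Y=0$) and contributes

$$\big[1 - w(c) F_1\big]^{I(Y=0)}
  \big[w(c) F_1 - w(c) F_2\big]^{I(Y=1)}
  \big[w(c) F_2\big]^{I(Y=2)},$$

with the linear weight $w(c) = c/M$ for every patient still inside the
window and $w = 1$ at completion.  At full follow-up this collapses to the
complete-observation multinomial model $(1-F_1,\, F_1-F_2,\, F_2)$.  The
weight function is pluggable (`weight_fn` everywhere), but the equal linear
weight is the only configuration exercised by the shipped tests.  With
*unequal* weights the middle probability can go negative; we raise an error
rather than clip, since the equal-weight default never triggers it.

## Estimation paths

**Likelihood (staged).**  The two-parameter MLE exists only after "full
heterogeneity" — all three outcome categories observed.  We qualify
strictly: a DLT counts at occurrence; moderate-only and toxicity-free
outcomes count only for patients who *completed* the window, because a
partially followed patient can still change category.  (Whether a
mid-follow-up moderate toxicity should count is genuinely open; the strict
reading is the default and the status function is the single place it is
encoded.)  Before full heterogeneity the design is staged:

1. cohorts of three, escalating one level per toxicity-free cohort,
   until the first grade $\ge 2$ toxicity;
2. a single-constraint TITE-CRM — on the moderate-toxicity constraint if
   only moderate events have occurred, on the DLT constraint whenever a
   DLT has (including the unstated mixed case of DLTs plus
   not-yet-qualifying moderate events, where the primary DLT constraint is
   the safer choice);
3. the full two-constraint model once heterogeneity is full (stage 2 is
   skipped if that happens during stage 1).

Two special rules govern the first cohort only: if all its patients show
moderate toxicity (no DLT), the second cohort repeats the dose — decided
once, when the second cohort starts, so the stage sequence never moves
backwards; if all show DLTs, the trial stops.  The MLE maximises the
weighted likelihood over $(\gamma_1,\gamma_2)$ by BFGS from three
deterministic starts $(0,0), (1,-1), (-1,1)$, keeping the smallest
$\lVert\gamma\rVert$ among ties; dose assignment is
$\min\{\arg\min_k |F_1(x_k)-p_{\mathrm{MT}}|,\
\arg\min_k |F_2(x_k)-p_{\mathrm{DLT}}|\}$ with distance ties broken to the
lower dose.  If heterogeneity is never reached, the final recommendation
falls back to the stage-2 single-constraint rule.

**Bayesian.**  Two parametrisations: independent $N(0, \sigma^2)$ priors on
$\gamma_l$ (default $\sigma = 1.34$, used as a *standard deviation* as
printed in the sources this design follows, although the older CRM
convention reads 1.34 as a variance — $\sigma$ is a config knob for that
reason), or independent Exponential(1) priors on $\beta_l$.  Each posterior
draw is mapped to the dose minimising $|F_l(x_k;\beta) - p_l|$ per
constraint, giving marginal posterior dose distributions; the summary is
the lower median (smallest index with cumulative mass $\ge 1/2$ —
conservative dosing), and the assignment is the minimum of the two medians.
An alternative "satisfy" rule (highest dose meeting the constraint per
draw) is available as a switch; the distance rule is the default because it
matches the worked assignment example.  The Bayesian path needs no staging
and is used from the first patient; only patient 1's dose is fixed at the
start dose.

Two engines compute the posterior functional: a deterministic product
trapezoid quadrature over a $[\pm 6\sigma]^2$ grid in $(\gamma_1,\gamma_2)$
(default, 61 nodes per axis inside trials) and an adaptive random-walk
Metropolis sampler (4 chains, adapted during burn-in toward acceptance
0.3, split scale-reduction diagnostic, error above 1.2).  The tests require
the two routes to agree within 0.02 per dose index, so the trial engine's
choice of the cheaper engine is a speed decision, not a modelling one.

**No skipping.**  Escalation is capped at one level above the highest dose
tried, the standard CRM convention; de-escalation is never restricted.  The
final MTD recommendation is the dose the $(n+1)$-th patient would receive
once every patient has complete follow-up (all weights 1).

**Start dose.**  All paths start at dose 1.  The staged narrative requires
it, and with a vague prior the prior-implied dose sits near the top of the
grid, which no phase-I protocol would administer first.

## Skeleton calibration

`indifference_skeleton()` builds the skeleton from a target, a prior MTD
position $\nu$, $K$ and an indifference half-width $\delta$: the value at
$\nu$ is the target, and each neighbour solves the pair of indifference
equations for the empiric model — at the parameter putting dose $i$ on the
lower bound $p-\delta$, dose $i+1$ sits on the upper bound $p+\delta$,
giving $x_{i+1} = (p+\delta)^{\log x_i / \log(p-\delta)}$ upward and the
symmetric step downward.  With $(p, \nu, K, \delta) = (0.25, 3, 5, 0.06)$
this yields the standard grid rounding to 0.06, 0.14, 0.25, 0.38, 0.50.
Full-precision values are kept internally; two-decimal rounding is
display-only.  Searching for the $\delta$ that maximises average accuracy
is out of scope — $\delta$ is an input.

## Simulating cumulative toxicity

Each dose carries a $3 \times 3$ per-cycle transition matrix over the
maximal-toxicity states; matrices are upper triangular (the maximal grade
cannot improve) with the DLT state absorbing, and a supplied file claiming
otherwise is corrected with a warning.  The true outcome distribution at
the end of the window is the first row of $P^M$, and the true MTD applies
the two constraints to it with boundary equality allowed.  Event times are
1-based end-of-cycle visit indices while accrual is continuous (fixed rate
or a unit-rate Poisson process); follow-up is trial time minus entry,
capped at $M$ (and snapped to $M$ within $10^{-9}$ to keep floating-point
noise from continuous entry times out of the completion logic).  Trials
pre-draw each patient's per-cycle uniforms, so responses are independent of
entry times and of which design consumes the stream — this is what makes
the design-reduction check (multiple-constraint design $\equiv$
single-constraint TITE-CRM on a DLT-only scenario, same seed) hold exactly.

What the generator emulates: monotone accumulation of the maximal grade,
late-onset events, coinciding or conflicting constraints.  What it does
not: within-patient dose modifications, recovery or reversible toxicity,
grade-specific (1 vs 2) distinctions below the moderate threshold, and
inter-patient heterogeneity beyond the chain itself.  Passing tests
therefore say nothing about, e.g., designs under informative dropout.

Three shipped scenarios (`example_scenarios()`) cover the main regimes
under the default targets: both constraints coinciding at dose 1, both at
dose 3, and the moderate constraint limiting at dose 2 while DLT alone
would allow dose 3.  Their per-cycle rates were chosen once so that the
six-cycle probabilities land where each regime requires (e.g. dose 1 of the
first scenario at roughly $(0.50, 0.23)$), and are not revisited.

## Benchmark and comparator

The nonparametric benchmark draws one latent uniform per patient, shared
across doses and thresholds, thresholds it against the true tail
probabilities to obtain a complete (and automatically monotone) toxicity
profile at every dose, and applies the same
minimum-of-distance-minimisers rule to the sample proportions.  It is an
accuracy upper bound because complete profiles are never observed.  Tied
distances go to the lower dose, consistent with "the minimum of the dose
levels" — which means a single toxicity-free profile selects dose 1, the
one place this convention is visible.

The single-constraint TITE-CRM comparator uses the one-parameter empiric
model with a $N(0, \sigma^2)$ prior on $\gamma$ and assigns by the
posterior mean of $\beta$ (1-D quadrature); a likelihood variant mirrors
the staged design restricted to DLTs.

## Operating characteristics

`run_study()` crosses scenarios with methods, with per-replicate seeds
derived from the study seed, the scenario position and a fixed per-method
code, so adding a method never shifts another method's stream.  Reported
metrics: PCS (selection frequency at the true MTD; stopped trials count as
incorrect, except when no dose is tolerable, where stopping *is* correct),
probability of selecting above the MTD (not applicable when the MTD is the
top dose), selection and allocation frequencies, toxicity counts, and the
median number of patients before full heterogeneity.  Monte-Carlo standard
errors $\sqrt{p(1-p)/\text{reps}}$ accompany each PCS.

## Numerical choices and test scale

* MLE: BFGS, relative tolerance $10^{-12}$, three restarts, ties by
  smallest $\lVert\gamma\rVert$; non-convergence from every restart is an
  error, distinct from the routine `not_estimable` signal.
* Quadrature: trapezoid weights, $[\pm 6\sigma]^2$ (normal prior) or
  $\gamma \in [-12, 4.5]$ (exponential prior, covering essentially all
  prior mass); 61 nodes per axis in trials, 101 in oracle comparisons.
* Degenerate inputs: an all-event single-constraint fit (no weighted
  non-event) is not estimable and the design repeats the current dose.
* The shipped test suite runs at sizes chosen to finish in about two
  minutes while keeping Monte-Carlo error well inside asserted tolerances:
  a 250-replicate fixture study at $n = 24$ plus a 2000-replicate
  benchmark, 1000 randomized trace-invariant trials at $n = 9\ldots15$,
  $10^5$ simulator draws against $P^6$, and $2\times10^4$ prior draws
  against quadrature.

## Known limitations

Ordinal outcomes stop at three levels (no third constraint for
life-threatening toxicity, though the likelihood factorisation extends);
no coherence rules beyond no-skipping; no covariates; cohort sizes other
than three in stage 1 are accepted by the config but untested; and the
Bayesian MCMC engine inside full trial simulation is substantially slower
than quadrature and intended for spot checks rather than 2000-replicate
studies.
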