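Package: titecrmmc
Title: Time-to-Event Continual Reassessment Method with Multiple Toxicity Constraints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Phase-I dose-finding designs for late-onset and cumulative
    toxicities under separate constraints on moderate (grade 2 or higher)
    toxicity and dose-limiting toxicity (DLT).  Implements the TITE-CRM with
    multiple constraints: a censored weighted-likelihood model over ordinal
    toxicity outcomes with maximum-likelihood (staged) and Bayesian
    (marginal-posterior-median dose) estimation, indifference-interval
    skeleton calibration for the empiric working model, a discrete-time
    Markov simulator of cumulative toxicity, fixed and Poisson accrual,
    the nonparametric complete-observation benchmark, the single-constraint
    TITE-CRM comparator, and simulation of operating characteristics
    (probability of correct selection, overdose selection).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
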