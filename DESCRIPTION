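Package: ipdnma
Title: One-Stage Individual Participant Data Network Meta-Analysis for
    Time-to-Event Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits one-stage Bayesian network meta-analysis models to
    individual participant data with time-to-event outcomes, using the
    Royston-Parmar flexible parametric survival model (restricted cubic
    spline on the log cumulative hazard scale) with trial-specific
    baselines.  Treatment-covariate interactions can be parameterised to
    separate or to combine the within-trial and across-trial components,
    so that ecological bias can be quantified and the agreement of the two
    sources of evidence assessed before they are pooled.  Includes
    pairwise heterogeneity statistics, proportional-hazards and linearity
    tests, loop inconsistency parameters, deviance information criterion
    model comparison, Bayesian truncated-normal imputation of missing
    covariates, treatment rankings by covariate level, a nine-step
    analysis framework orchestrating these steps, and a synthetic network
    generator with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    flexsurv,
    metafor,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
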