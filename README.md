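# ipdnma

One-stage Bayesian network meta-analysis (NMA) of individual participant
data (IPD) with time-to-event outcomes, with treatment-covariate
interactions that **separate the within-trial from the across-trial
evidence**.

## Who this is for

Meta-analysts with patient-level survival data from a connected network of
randomised trials (e.g. the cervical-cancer overall-survival networks that
motivate the package's synthetic data generator) who want to ask whether a
patient-level covariate — disease stage, age, a biomarker — modifies the
relative effect of the treatments.  Treatment-covariate interactions in a
meta-analysis mix two sources of evidence: the *within-trial* interaction,
estimated from covariate variation among patients inside each randomised
trial, and the *across-trial* interaction, estimated from the relation
between trial-mean covariate values and trial-level treatment effects.
The across-trial component is observational and susceptible to confounding
and ecological bias, so the two must be inspected separately before anyone
is tempted to pool them.

## The model

The survival model is the Royston-Parmar flexible parametric model on the
log cumulative hazard scale.  For patient *i* in trial *j*,

    ln H_j(t | x_ij) = s_j(ln t) + beta_1 trt_1ij + ... + beta_q trt_qij
                       + alpha_j (z_ij - zbar_j)
                       + sum_k deltaA_k trt_kij (z_ij - zbar_j)
                       + sum_k deltaB_k trt_kij zbar_j

where `s_j` is a trial-specific restricted cubic spline (the baseline),
the `trt_k` are treatment indicators mapped through the consistency
equations of the network (any contrast a→b equals `beta_b − beta_a`, with
the reference fixed at 0), `z_ij` is the patient-level covariate and
`zbar_j` its trial mean.  `deltaA` is the within-trial and `deltaB` the
across-trial interaction; their difference `deltaB_k − deltaA_k` quantifies
the ecological bias for contrast *k*.  The alternative single-effect
("combined") parameterisation replaces the last three terms with
`alpha_j z_ij + sum_k delta_k trt_kij z_ij`.  Options include fixed or
random (multivariate normal, Wishart-prior precision) treatment effects,
common / fixed-trial / random-trial covariate effects, loop inconsistency
parameters, treatment-by-`ln t` coefficients for proportional-hazards
testing, and Bayesian truncated-normal imputation of missing covariate
values.  Posterior sampling is by an adaptive blocked
Metropolis-within-Gibbs sampler written for this likelihood; states that
violate the monotonicity of the cumulative hazard are rejected, never
silently retained.

A nine-step framework (`run_framework()`) orchestrates the full analysis:
pairwise heterogeneity (Cochran Q, I², tau²), network construction,
fixed- vs random-effect selection with DIC, inconsistency, covariate
audit (missingness, linearity), covariate-mode selection, and the
separated and combined interaction models with a half-standard-error
agreement criterion and treatment rankings per covariate level.

## Worked example

A synthetic 12-trial, 3-treatment network with known truth: within-trial
interaction 0.4, across-trial interaction −0.2 on every contrast (so the
generator builds in an ecological bias of −0.6):

```r
library(ipdnma)

cfg <- generator_config(
  treatments = c("A", "B", "C"), reference = "A",
  trials = c(rep(list(c("A", "B")), 4), rep(list(c("A", "C")), 4),
             rep(list(c("B", "C")), 4)),
  n_per_arm = 100, beta = c(B = -0.3, C = 0.2), alpha = 0.4,
  baseline_shape_range = c(1, 1.2), baseline_rate_range = c(0.8, 1.2),
  trial_mean_range = c(0, 2), within_sd = 0.6, ordinal = FALSE,
  delta_a = c(B = 0.4, C = 0.4),   # within-trial interaction
  delta_b = c(B = -0.2, C = -0.2), # across-trial interaction
  admin_time = 3, dropout_rate = 0.05, seed = 1)
gen <- generate_network(cfg)
gen$data
#> IPD survival dataset: 2400 patients, 12 trials, 3 treatments, 2254 events
#> covariates: stage

net <- build_network(gen$data, reference = "A")
cfg_sep <- nma_config(covariate = "stage", covariate_mode = "fixed_trial",
                      interaction_mode = "separated", n_knots = 0)
fit <- fit_nma(build_design(gen$data, net, cfg_sep),
               settings = mcmc_settings(n_burnin = 2000, n_iter = 2000,
                                        n_chains = 2, seed = 1))
posterior_summary(fit, c("deltaA[B]", "deltaA[C]", "deltaB[B]", "deltaB[C]"))
#>   parameter        mean        sd      lower       upper
#> 1 deltaA[B]  0.33592852 0.1254267  0.1018445  0.58281774
#> 2 deltaA[C]  0.34861710 0.1157875  0.1373288  0.56831594
#> 3 deltaB[B] -0.21613783 0.2480673 -0.7778168  0.22708918
#> 4 deltaB[C] -0.05782247 0.2238517 -0.4756532  0.36887386

ecological_bias(fit)
#>   contrast       mean        sd      lower       upper
#> 1        B -0.5520664 0.2708850 -1.0965104 -0.01985929
#> 2        C -0.4064396 0.2540222 -0.8738352  0.11715453

agreement(fit)
#>   contrast within se_within  across se_across difference threshold  verdict
#> 1        B  0.336     0.123 -0.2161     0.256      0.552     0.128 disagree
#> 2        C  0.349     0.110 -0.0578     0.215      0.406     0.108 disagree
#> overall: disagree
```

The within-trial estimates sit near their true value 0.4 and the
across-trial estimates near −0.2; the ecological-bias summaries recover
the built-in gap of −0.6; and the half-SE agreement criterion correctly
concludes that the two sources of evidence should *not* be combined, so a
combined-interaction model (step 9 of the framework) would be flagged
"not recommended".

A thin command-line wrapper is installed as `exec/ipdnma` with subcommands
`simulate`, `pairwise`, `fit` and `framework`.

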