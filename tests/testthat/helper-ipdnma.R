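## Shared fixtures, all generated in code.  Stochastic tests use seed 1
## throughout unless a different fixed seed is part of the scenario.

fast_settings <- function(burn = 400L, iter = 800L, seed = 1L) {
  mcmc_settings(n_burnin = burn, n_iter = iter, n_chains = 2L, seed = seed)
}

## small 3-treatment network generator; arguments override the scenario
triangle_config <- function(trials_per_edge = 2L, n_per_arm = 60L, ...) {
  generator_config(
    treatments = c("A", "B", "C"), reference = "A",
    trials = c(rep(list(c("A", "B")), trials_per_edge),
               rep(list(c("A", "C")), trials_per_edge),
               rep(list(c("B", "C")), trials_per_edge)),
    n_per_arm = n_per_arm,
    baseline_shape_range = c(1, 1.2), baseline_rate_range = c(0.8, 1.2),
    beta = c(B = -0.3, C = 0.2), alpha = 0.4,
    trial_mean_range = c(0.3, 1.7), within_sd = 0.6, ordinal = FALSE,
    admin_time = 3, dropout_rate = 0.05, seed = 1L, ...
  )
}

## deterministic toy IPD table: 2 trials x 2 arms, optional covariate holes
toy_records <- function() {
  data.frame(
    trial = c("t1", "t1", "t2", "t2"),
    treatment = c("A", "B", "A", "B"),
    time = c(1, 2, 3, 4),
    event = c(1, 1, 0, 1),
    stage = c(0, 1, 2, NA),
    stringsAsFactors = FALSE
  )
}

toy_dataset <- function() {
  ipd_dataset(toy_records(), covariates = list(stage = c(0, 2)))
}

## a real (tiny) fit whose draws tests may overwrite with crafted values
tiny_fit <- function(interaction_mode = "none", ...) {
  gen <- generate_network(triangle_config(n_per_arm = 30L))
  net <- build_network(gen$data, "A")
  cfg <- if (interaction_mode == "none") {
    nma_config(n_knots = 0)
  } else {
    nma_config(covariate = "stage", covariate_mode = "fixed_trial",
               interaction_mode = interaction_mode, n_knots = 0)
  }
  fit_nma(build_design(gen$data, net, cfg),
          settings = fast_settings(burn = 100L, iter = 200L), ...)
}

## overwrite monitored columns of a fit with crafted draws
set_draws <- function(fit, values) {
  for (ch in seq_along(fit$draws)) {
    for (nm in names(values)) {
      v <- values[[nm]]
      fit$draws[[ch]][, nm] <- if (length(v) == 1L) v else {
        rep_len(v, nrow(fit$draws[[ch]]))
      }
    }
  }
  fit
}
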