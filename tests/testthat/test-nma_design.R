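## dataset with an A-B trial, an A-C trial and a B-C trial plus covariate
design_dataset <- function(zvals = c(2, 1, 1, 1, 0, 1)) {
  df <- data.frame(
    trial = rep(c("t1", "t2", "t3"), each = 2),
    treatment = c("A", "B", "A", "C", "B", "C"),
    time = c(1, 2, 1.5, 2.5, 1, 3),
    event = 1,
    stage = zvals,
    stringsAsFactors = FALSE
  )
  ipd_dataset(df, covariates = list(stage = c(0, 2)))
}

test_that("column-count audit holds across parameterisations", {
  dat <- design_dataset()
  net <- build_network(dat, "A")
  q <- 2L; J <- 3L
  count <- function(design, group) sum(design$par$group == group)

  d1 <- build_design(dat, net, nma_config(covariate = "stage",
                                          covariate_mode = "common",
                                          n_knots = 0))
  expect_equal(count(d1, "beta"), q)
  expect_equal(count(d1, "alpha"), 1L)

  d2 <- build_design(dat, net, nma_config(covariate = "stage",
                                          covariate_mode = "fixed_trial",
                                          interaction_mode = "separated",
                                          n_knots = 0))
  expect_equal(count(d2, "alpha"), J)
  expect_equal(count(d2, "delta_a") + count(d2, "delta_b"), 2L * q)

  d3 <- build_design(dat, net, nma_config(covariate = "stage",
                                          covariate_mode = "fixed_trial",
                                          interaction_mode = "combined",
                                          n_knots = 0))
  expect_equal(count(d3, "delta"), q)

  d4 <- build_design(dat, net,
                     nma_config(inconsistency = list(c("A", "B", "C")),
                                n_knots = 0))
  expect_equal(count(d4, "omega"), 1L)

  d5 <- build_design(dat, net, nma_config(ph_interactions = TRUE,
                                          n_knots = 0))
  expect_equal(count(d5, "phi"), q)
})

test_that("a B-vs-C trial gets the consistency-mapped pattern beta_C - beta_B", {
  dat <- design_dataset()
  net <- build_network(dat, "A")
  des <- build_design(dat, net, nma_config(n_knots = 0))
  X <- des$X
  rowC <- which(des$trial_ids[des$trial_idx] == "t3" & des$treatment == "C")
  rowB <- which(des$trial_ids[des$trial_idx] == "t3" & des$treatment == "B")
  expect_equal(unname(X[rowC, c("beta[B]", "beta[C]")]), c(-1, 1))
  expect_equal(unname(X[rowB, c("beta[B]", "beta[C]")]), c(0, 0))
  ## the row pattern equals the consistency-map weights for B -> C
  w <- contrast_weights(net, "B", "C")
  expect_equal(X[rowC, c("beta[B]", "beta[C]")],
               c(`beta[B]` = unname(w["B"]), `beta[C]` = unname(w["C"])))
})

test_that("separated interaction columns centre at the trial mean", {
  ## patient with z = 2 in a trial whose mean is 1.4
  df <- data.frame(
    trial = rep(c("t1"), 5),
    treatment = c("A", "B", "B", "A", "B"),
    time = c(1, 2, 3, 1.5, 2.5), event = 1,
    stage = c(1, 2, 1, 2, 1)
  )
  df2 <- df; df2$trial <- "t2"; df2$treatment <- c("A", "C", "C", "A", "C")
  dat <- ipd_dataset(rbind(df, df2), covariates = list(stage = c(0, 2)))
  net <- build_network(dat, "A")
  des <- build_design(dat, net, nma_config(covariate = "stage",
                                           covariate_mode = "fixed_trial",
                                           interaction_mode = "separated",
                                           n_knots = 0))
  expect_equal(unname(des$zbar["t1"]), 1.4)
  i <- which(des$trial_ids[des$trial_idx] == "t1" & des$z == 2 &
               des$treatment == "B")[1]
  expect_equal(unname(des$X[i, "deltaA[B]"]), 0.6, tolerance = 1e-12)
  expect_equal(unname(des$X[i, "deltaB[B]"]), 1.4, tolerance = 1e-12)
  expect_equal(unname(des$X[i, "alpha[t1]"]), 0.6, tolerance = 1e-12)
})

test_that("centering identity: all trial means zero makes separated and combined columns identical", {
  df <- data.frame(
    trial = rep(c("t1", "t2"), each = 4),
    treatment = rep(c("A", "A", "B", "B"), 2),
    time = rep(c(1, 2, 1.5, 3), 2), event = 1,
    stage = c(-1, 1, -0.5, 0.5, -2, 2, -1, 1)
  )
  dat <- ipd_dataset(df, covariates = list(stage = c(-2, 2)))
  net <- build_network(dat, "A")
  ds <- build_design(dat, net, nma_config(covariate = "stage",
                                          covariate_mode = "fixed_trial",
                                          interaction_mode = "separated",
                                          n_knots = 0))
  dc <- build_design(dat, net, nma_config(covariate = "stage",
                                          covariate_mode = "fixed_trial",
                                          interaction_mode = "combined",
                                          n_knots = 0))
  expect_equal(unname(ds$zbar), c(0, 0))
  shared <- intersect(colnames(ds$X), colnames(dc$X))
  expect_identical(ds$X[, shared], dc$X[, shared])
  expect_identical(unname(ds$X[, c("deltaA[B]")]),
                   unname(dc$X[, c("delta[B]")]))
  expect_true(all(ds$X[, "deltaB[B]"] == 0))
})

test_that("separated mode demands trial means when a trial is fully missing", {
  dat <- design_dataset(zvals = c(2, 1, NA, NA, 0, 1))
  net <- build_network(dat, "A")
  expect_error(
    build_design(dat, net, nma_config(covariate = "stage",
                                      covariate_mode = "fixed_trial",
                                      interaction_mode = "separated",
                                      n_knots = 0)),
    "two-pass")
  ## supplying the mean (as the two-pass procedure would) resolves it
  d <- build_design(dat, net,
                    nma_config(covariate = "stage",
                               covariate_mode = "fixed_trial",
                               interaction_mode = "separated",
                               trial_means = c(t2 = 1.1), n_knots = 0))
  expect_equal(unname(d$zbar["t2"]), 1.1)
})

test_that("attach_imputation adds one latent per missing value, none when complete", {
  dat_ok <- design_dataset()
  net <- build_network(dat_ok, "A")
  d0 <- build_design(dat_ok, net, nma_config(covariate = "stage",
                                             covariate_mode = "common",
                                             n_knots = 0))
  expect_identical(attach_imputation(d0), d0)

  dat1 <- design_dataset(zvals = c(2, 1, 1, NA, 0, 1))
  d1 <- attach_imputation(build_design(dat1, net,
                                       nma_config(covariate = "stage",
                                                  covariate_mode = "common",
                                                  imputation = "truncated_normal",
                                                  n_knots = 0)))
  expect_equal(length(d1$impute$latent_idx), 1L)
  expect_equal(d1$config$imputation, "truncated_normal")
})

test_that("effective trial means weight observed and imputed values by counts", {
  df <- data.frame(
    trial = c(rep("t1", 100), rep("t2", 4), rep("t3", 2)),
    treatment = rep(c("A", "B"), 53),
    time = 1, event = 1,
    stage = c(rep(1.0, 80), rep(NA, 20), rep(0.7, 4), NA, NA)
  )
  dat <- ipd_dataset(df, covariates = list(stage = c(0, 2)))
  em <- effective_trial_means(dat, imputed = c(rep(1.5, 20), 1.2, 0.8),
                              covariate = "stage")
  expect_equal(unname(em["t1"]), (80 * 1.0 + 20 * 1.5) / 100)
  expect_equal(unname(em["t2"]), 0.7)   # fully observed: unchanged
  expect_equal(unname(em["t3"]), 1.0)   # fully missing: mean of imputed means
})

test_that("model configurations serialise to text and back", {
  cfg <- nma_config(treatment_effects = "random", covariate = "stage",
                    covariate_mode = "fixed_trial",
                    interaction_mode = "separated",
                    inconsistency = list(list(loop = c("A", "B", "C"),
                                              edge = c("B", "C"))),
                    ph_interactions = TRUE,
                    imputation = "truncated_normal",
                    trial_means = c(t1 = 0.5, t2 = 1.25),
                    n_knots = 1L)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$treatment_effects, "random")
  expect_equal(cfg2$trial_means, c(t1 = 0.5, t2 = 1.25))
  expect_equal(cfg2$inconsistency[[1]]$edge, c("B", "C"))
  expect_true(cfg2$ph_interactions)
  expect_equal(cfg2$n_knots, 1L)
})

test_that("config invariants are enforced", {
  expect_error(nma_config(interaction_mode = "combined"), "covariate")
  expect_error(nma_config(covariate_mode = "common"), "covariate name")
})
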