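test_that("identical seed and settings give bit-identical draws", {
  gen <- generate_network(triangle_config(trials_per_edge = 1L,
                                          n_per_arm = 25L))
  des <- build_design(gen$data, build_network(gen$data, "A"),
                      nma_config(n_knots = 0))
  st <- fast_settings(burn = 100L, iter = 150L)
  f1 <- fit_nma(des, settings = st)
  f2 <- fit_nma(des, settings = st)
  expect_identical(f1$draws, f2$draws)
})

test_that("with no events a tight prior dominates the treatment effect", {
  df <- data.frame(trial = "t1", treatment = rep(c("A", "B"), each = 30),
                   time = runif(60, 0.5, 2), event = 0)
  dat <- ipd_dataset(df)
  des <- build_design(dat, build_network(dat, "A"), nma_config(n_knots = 0))
  fit <- fit_nma(des, priors = prior_spec(beta_sd = list(`beta[B]` = 0.01)),
                 settings = fast_settings(burn = 500L, iter = 1500L))
  expect_lt(abs(posterior_summary(fit, "beta[B]")$mean), 0.01)
})

test_that("DIC arithmetic: constant deviance and conjugate normal-means", {
  ## constant deviance: pD = 0, DIC = Dbar
  d0 <- dic_from_deviance(rep(7.5, 100), 7.5)
  expect_equal(d0$pD, 0)
  expect_equal(d0$DIC, 7.5)
  expect_false(d0$negative_pD)

  ## known-variance normal means, flat prior: posterior theta_i ~ N(y_i, 1)
  ## and pD should equal the number of free means
  set.seed(1)
  k <- 5L; y <- rnorm(k, 0, 3); n_draw <- 40000L
  theta <- matrix(rnorm(n_draw * k, mean = rep(y, each = n_draw), sd = 1),
                  n_draw, k)
  dev <- rowSums(sweep(theta, 2, y)^2)       # -2 loglik up to a constant
  res <- dic_from_deviance(dev, 0)            # deviance at theta = y is 0
  expect_equal(res$pD, k, tolerance = 0.1)
})

test_that("adding a coefficient pinned at zero leaves DIC unchanged", {
  gen <- generate_network(triangle_config(trials_per_edge = 1L,
                                          n_per_arm = 50L))
  net <- build_network(gen$data, "A")
  st <- fast_settings(burn = 400L, iter = 1200L)
  f0 <- fit_nma(build_design(gen$data, net, nma_config(n_knots = 0)),
                settings = st)
  desp <- build_design(gen$data, net,
                       nma_config(n_knots = 0, ph_interactions = TRUE))
  fp <- fit_nma(desp,
                priors = prior_spec(beta_sd = list(`phi[B]` = 1e-4,
                                                   `phi[C]` = 1e-4)),
                settings = st)
  expect_lt(abs(dic(f0)$DIC - dic(fp)$DIC), 3)
})

test_that("derived contrasts obey the consistency equations exactly", {
  fit <- tiny_fit()
  fit <- set_draws(fit, list(`beta[B]` = -0.2, `beta[C]` = -0.4))
  dc <- derived_contrasts(fit)
  ## reference -> treatment contrasts are the basic parameters
  expect_equal(dc$mean[dc$from == "A" & dc$to == "B"], -0.2)
  ## B -> C = beta_C - beta_B with zero posterior spread
  bc <- dc[dc$from == "B" & dc$to == "C", ]
  expect_equal(bc$mean, -0.2)
  expect_equal(bc$sd, 0)
  expect_equal(unname(bc$lower), unname(bc$upper))
  ## per-draw identity on unmodified draws
  fit2 <- tiny_fit()
  B <- draws_matrix(fit2, c("beta[B]", "beta[C]"))
  expect_equal(B[, 2] - B[, 1], (B[, 2] - 0) - (B[, 1] - 0))
})

test_that("ecological bias is the across-minus-within difference", {
  fit <- tiny_fit(interaction_mode = "separated")
  ## within = across identically: zero difference, zero-width interval
  fit0 <- set_draws(fit, list(`deltaA[B]` = 0.3, `deltaB[B]` = 0.3,
                              `deltaA[C]` = -0.1, `deltaB[C]` = -0.1))
  eb0 <- ecological_bias(fit0)
  expect_equal(eb0$mean, c(0, 0))
  expect_equal(unname(eb0$upper - eb0$lower), c(0, 0))
  ## posterior means reported for a published comparison imply a bias of
  ## 0.110 - (-0.035) = 0.145 for that contrast
  fit1 <- set_draws(fit, list(`deltaA[B]` = -0.035, `deltaB[B]` = 0.110))
  expect_equal(ecological_bias(fit1)$mean[1], 0.145)
  ## combined-mode fits have no within/across decomposition
  fitc <- tiny_fit(interaction_mode = "combined")
  expect_error(ecological_bias(fitc), "separated")
})

test_that("covariate sign flip mirrors the ecological bias difference", {
  gen <- generate_network(triangle_config(
    trials_per_edge = 2L, n_per_arm = 60L,
    delta_a = c(B = 0.5, C = 0.5), delta_b = c(B = -0.3, C = -0.3)))
  flip <- gen$data
  flip$records$stage <- -flip$records$stage
  flip <- ipd_dataset(flip$records, covariates = list(stage = c(-2, 0)),
                      treatments = flip$treatments)
  cfgd <- function(d) build_design(d, build_network(d, "A"),
                                   nma_config(covariate = "stage",
                                              covariate_mode = "fixed_trial",
                                              interaction_mode = "separated",
                                              n_knots = 0))
  m1 <- fit_nma_ml(cfgd(gen$data), hessian = FALSE)
  m2 <- fit_nma_ml(cfgd(flip), hessian = FALSE)
  d1 <- m1$coef["deltaB[B]"] - m1$coef["deltaA[B]"]
  d2 <- m2$coef["deltaB[B]"] - m2$coef["deltaA[B]"]
  expect_equal(unname(d1), -unname(d2), tolerance = 1e-4)
})

test_that("ranking probabilities behave at the extremes and sum to one", {
  fit <- tiny_fit()
  ## strictly best treatment gets rank-1 probability 1
  fitd <- set_draws(fit, list(`beta[B]` = -1, `beta[C]` = 1))
  rk <- rank_treatments(fitd, 0)[[1]]
  expect_equal(unname(rk["B", "rank1"]), 1)
  expect_equal(unname(rk["A", "rank2"]), 1)
  expect_equal(unname(rowSums(rk)), rep(1, 3))
  ## exchangeable treatments split the top rank about evenly
  set.seed(1)
  nd <- nrow(draws_matrix(fit))
  sym <- matrix(rnorm(2 * nd, 0, 0.5), ncol = 2)
  fits <- fit
  half <- nrow(fits$draws[[1]])
  fits$draws[[1]][, c("beta[B]", "beta[C]")] <- sym[seq_len(half), ]
  fits$draws[[2]][, c("beta[B]", "beta[C]")] <- sym[half + seq_len(half), ]
  rks <- rank_treatments(fits, 0)[[1]]
  expect_equal(unname(rks["B", "rank1"]), unname(rks["C", "rank1"]),
               tolerance = 0.15)
  expect_equal(unname(rowSums(rks)), rep(1, 3))
})

test_that("interaction fits shift rankings across covariate levels", {
  fit <- tiny_fit(interaction_mode = "combined")
  fit <- set_draws(fit, list(`beta[B]` = -0.5, `beta[C]` = 0,
                             `delta[B]` = 0.5, `delta[C]` = -0.3))
  rk <- rank_treatments(fit, c(0, 2))
  expect_equal(unname(rk[["z=0"]]["B", "rank1"]), 1)   # B best at z = 0
  expect_equal(unname(rk[["z=2"]]["C", "rank1"]), 1)   # C best at z = 2
})

test_that("split-Rhat flags divergent chains and accepts matched ones", {
  fit <- tiny_fit()
  set.seed(1)
  niter <- nrow(fit$draws[[1]])
  ## well-mixed iid chains: Rhat near 1
  for (ch in 1:2) fit$draws[[ch]][, "beta[B]"] <- rnorm(niter)
  cv <- convergence(fit)
  expect_lt(cv$rhat[cv$parameter == "beta[B]"], 1.02)
  expect_false(cv$flagged[cv$parameter == "beta[B]"])
  ## one chain offset by +10: strongly flagged
  fit$draws[[2]][, "beta[B]"] <- fit$draws[[2]][, "beta[B]"] + 10
  cv2 <- convergence(fit)
  expect_gt(cv2$rhat[cv2$parameter == "beta[B]"], 2)
  expect_true(cv2$flagged[cv2$parameter == "beta[B]"])
  ## a single chain cannot be diagnosed
  fit$draws <- fit$draws[1]
  expect_error(convergence(fit), "2 chains")
})

test_that("draws and summaries export to CSV", {
  fit <- tiny_fit()
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, path)
  dd <- read.csv(path)
  expect_setequal(unique(dd$parameter), fit$par_names)
  expect_equal(nrow(dd),
               2L * nrow(fit$draws[[1]]) * length(fit$par_names))
  ps <- posterior_summary(fit)
  expect_true(all(ps$lower <= ps$upper))
})
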