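test_that("heterogeneity statistics match the inverse-variance formulas", {
  ## worked case: y = {0, 1}, se = {0.5, 0.5}
  h <- heterogeneity(c(0, 1), c(0.5, 0.5))
  expect_equal(h$pooled, 0.5)
  expect_equal(h$Q, 2.0)
  expect_equal(h$df, 1L)
  expect_equal(h$I2, 50)
  ## identical estimates: no heterogeneity at all
  h0 <- heterogeneity(c(0.3, 0.3, 0.3), c(0.2, 0.5, 1))
  expect_equal(h0$Q, 0)
  expect_equal(h0$I2, 0)
  expect_equal(h0$tau2, 0)
  expect_error(heterogeneity(0.3, 0.2), "2 estimates")
  expect_error(heterogeneity(c(0, 1), c(0.5, -1)), "positive")
})

test_that("heterogeneity agrees with brute force on random inputs", {
  set.seed(1)
  for (r in 1:100) {
    k <- sample(2:12, 1)
    y <- rnorm(k); se <- runif(k, 0.1, 2)
    h <- heterogeneity(y, se)
    ## independent direct evaluation
    w <- 1 / se^2
    yh <- sum(w * y) / sum(w)
    Q <- sum(w * (y - yh)^2)
    expect_lt(abs(h$Q - Q), 1e-12)
    expect_lt(abs(h$I2 - max(0, (Q - (k - 1)) / Q) * 100), 1e-12)
    expect_lt(abs(h$tau2 - max(0, (Q - (k - 1)) /
                                 (sum(w) - sum(w^2) / sum(w)))), 1e-12)
  }
})

test_that("heterogeneity scales as Q ~ 1/c^2 and matches metafor", {
  set.seed(2)
  y <- rnorm(6); se <- runif(6, 0.2, 1)
  h1 <- heterogeneity(y, se)
  h2 <- heterogeneity(y, 3 * se)
  expect_equal(h2$Q, h1$Q / 9, tolerance = 1e-12)
  skip_if_not_installed("metafor")
  rm <- metafor::rma(yi = y, sei = se, method = "DL")
  expect_equal(h1$Q, unname(rm$QE), tolerance = 1e-8)
  expect_equal(h1$tau2, unname(rm$tau2), tolerance = 1e-8)
})

test_that("pairwise estimates: single trial pools to itself, duplicates gain sqrt(2)", {
  gen <- generate_network(generator_config(
    treatments = c("A", "B"), reference = "A",
    trials = list(c("A", "B")), n_per_arm = 120L,
    baseline_shape_range = c(1, 1), baseline_rate_range = c(0.5, 0.5),
    beta = c(B = -0.3), alpha = 0, trial_mean_range = c(1, 1),
    within_sd = 0.5, ordinal = FALSE, admin_time = 4, dropout_rate = 0,
    seed = 1))
  pe1 <- pairwise_estimates(gen$data, c("A", "B"), n_knots = 0)
  expect_equal(pe1$pooled$estimate, pe1$trials$estimate[1], tolerance = 1e-4)

  ## duplicate the trial: same pooled estimate, SE reduced by sqrt(2)
  rec2 <- gen$data$records; rec2$trial <- "T98"
  dat2 <- ipd_dataset(rbind(gen$data$records, rec2))
  pe2 <- pairwise_estimates(dat2, c("A", "B"), n_knots = 0)
  expect_equal(pe2$pooled$estimate, pe1$pooled$estimate, tolerance = 1e-3)
  expect_equal(pe2$pooled$se, pe1$pooled$se / sqrt(2), tolerance = 0.02)
  fd <- forest_data(pe2)
  expect_equal(nrow(fd), 3L)
  expect_error(pairwise_estimates(gen$data, c("A", "Z")), "no trial")
})

test_that("pooled pairwise estimates recover the generating log hazard ratio", {
  gen <- generate_network(generator_config(
    treatments = c("A", "B"), reference = "A",
    trials = rep(list(c("A", "B")), 5L), n_per_arm = 150L,
    baseline_shape_range = c(0.9, 1.2), baseline_rate_range = c(0.4, 0.8),
    beta = c(B = -0.3), alpha = 0, trial_mean_range = c(1, 1),
    within_sd = 0.5, ordinal = FALSE, admin_time = 4, dropout_rate = 0.05,
    seed = 1))
  pe <- pairwise_estimates(gen$data, c("A", "B"), n_knots = 0)
  expect_lt(abs(pe$pooled$estimate + 0.3), 2 * pe$pooled$se)
})

test_that("PH screening detects a strong time-varying effect and needs phi", {
  gen <- generate_network(generator_config(
    treatments = c("A", "B"), reference = "A",
    trials = rep(list(c("A", "B")), 2L), n_per_arm = 250L,
    baseline_shape_range = c(1, 1), baseline_rate_range = c(0.6, 0.8),
    beta = c(B = 0), alpha = 0, phi = c(B = 0.6),
    trial_mean_range = c(1, 1), within_sd = 0.5, ordinal = FALSE,
    admin_time = 4, dropout_rate = 0, seed = 1))
  mlph <- pairwise_ph_test(gen$data, c("A", "B"), n_knots = 0)
  expect_lt(mlph$p, 0.05)
  des <- build_design(gen$data, build_network(gen$data, "A"),
                      nma_config(n_knots = 0, ph_interactions = TRUE))
  fit <- fit_nma(des, settings = fast_settings())
  gp <- global_ph_test(fit)
  expect_equal(gp$df, 1L)
  expect_lt(gp$p, 0.05)
  ## a fit without phi cannot be tested
  fit0 <- fit_nma(build_design(gen$data, build_network(gen$data, "A"),
                               nma_config(n_knots = 0)),
                  settings = fast_settings(burn = 100L, iter = 150L))
  expect_error(global_ph_test(fit0), "ph_interactions")
})

test_that("linearity test sums per-trial Wald statistics and excludes 2-level trials", {
  base <- generator_config(
    treatments = c("A", "B"), reference = "A",
    trials = rep(list(c("A", "B")), 3L), n_per_arm = 200L,
    baseline_shape_range = c(1, 1), baseline_rate_range = c(0.5, 0.7),
    beta = c(B = -0.2), alpha = 0.5, trial_mean_range = c(0.8, 1.2),
    within_sd = 0.8, ordinal = TRUE, admin_time = 4, dropout_rate = 0,
    seed = 1)
  gen <- generate_network(base)
  lt <- linearity_test(gen$data, "stage", n_knots = 0)
  expect_equal(lt$df, nrow(lt$per_trial))
  expect_true(lt$p > 0 && lt$p <= 1)

  ## a strongly convex effect (middle level + 1.0) is detected
  rec <- gen$data$records
  conv <- rec$stage == 1
  rec$time <- ifelse(conv & rec$event == 1, rec$time * exp(-1), rec$time)
  datc <- ipd_dataset(rec, covariates = list(stage = c(0, 2)))
  ltc <- linearity_test(datc, "stage", n_knots = 0)
  expect_lt(ltc$p, 0.05)

  ## trials observing only 2 levels are excluded from the sum
  rec2 <- gen$data$records
  rec2$stage[rec2$trial == "T01" & rec2$stage == 2] <- 1
  dat2 <- ipd_dataset(rec2, covariates = list(stage = c(0, 2)))
  lt2 <- linearity_test(dat2, "stage", n_knots = 0)
  expect_equal(lt2$df, lt$df - 1L)
  expect_false("T01" %in% lt2$per_trial$trial)

  rec3 <- gen$data$records
  rec3$stage[rec3$stage == 2] <- 1
  expect_error(linearity_test(ipd_dataset(rec3,
                                          covariates = list(stage = c(0, 2))),
                              "stage", levels = c(0, 1, 2)), "3 covariate")
})

test_that("agreement applies the half-SE rule with an inclusive boundary", {
  ## published-table arithmetic: within 0.176, across 0.165 with CrI
  ## (-0.279, 0.584): SE_across ~ 0.220, |diff| = 0.011 <= 0.110 -> agree
  tab <- data.frame(contrast = "B",
                    within = 0.176, within_lower = -0.069,
                    within_upper = 0.417,
                    across = 0.165, across_lower = -0.279,
                    across_upper = 0.584)
  ag <- agreement(tab)
  expect_equal(ag$se_across, 0.2202, tolerance = 1e-3)
  expect_equal(ag$verdict, "agree")
  expect_equal(attr(ag, "overall"), "agree")

  ## identical estimates agree regardless of the SE
  tab2 <- transform(tab, across = within, across_lower = within,
                    across_upper = within)
  expect_equal(agreement(tab2)$verdict, "agree")

  ## exact boundary counts as agreement; epsilon beyond does not
  se_b <- (tab$across_upper - tab$across_lower) / (2 * qnorm(0.975))
  tab3 <- transform(tab, within = across + 0.5 * se_b)
  expect_equal(agreement(tab3)$verdict, "agree")
  tab4 <- transform(tab, within = across + 0.5 * se_b + 1e-9)
  expect_equal(agreement(tab4)$verdict, "disagree")

  ## verdict invariant to jointly rescaling the covariate (z -> 3z scales
  ## every interaction and SE by 1/3)
  tab5 <- tab
  for (cc in setdiff(names(tab), "contrast")) tab5[[cc]] <- tab[[cc]] / 3
  expect_equal(agreement(tab5)$verdict, agreement(tab)$verdict)

  ## alternative SE bases remain available
  expect_s3_class(agreement(tab, se_basis = "pooled"),
                  "agreement_assessment")
  ## combined-mode fits are rejected
  fitc <- tiny_fit(interaction_mode = "combined")
  expect_error(agreement(fitc), "separated")
})

test_that("loop split rejects loops absent from the network", {
  gen <- generate_network(triangle_config(trials_per_edge = 1L,
                                          n_per_arm = 25L))
  net <- build_network(gen$data, "A")
  expect_error(direct_indirect_split(gen$data, net, c("A", "B", "D"),
                                     settings = fast_settings()),
               "not in the network")
})
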