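#' Subset an IPD dataset
#'
#' @param dataset an `ipd_data`.
#' @param trials optional trial ids to keep.
#' @param treatments optional treatment arms to keep (trials reduced to
#'   those arms; trials left with fewer than 2 arms are dropped).
#' @param complete_cases optional covariate name: drop records with a
#'   missing value of that covariate (trials left without 2 arms are
#'   dropped).
#' @return A new `ipd_data`.
#' @export
subset_ipd <- function(dataset, trials = NULL, treatments = NULL,
                       complete_cases = NULL) {
  stopifnot(inherits(dataset, "ipd_data"))
  rec <- dataset$records
  if (!is.null(trials)) rec <- rec[rec$trial %in% trials, , drop = FALSE]
  if (!is.null(treatments)) {
    rec <- rec[rec$treatment %in% treatments, , drop = FALSE]
  }
  if (!is.null(complete_cases)) {
    rec <- rec[!is.na(rec[[complete_cases]]), , drop = FALSE]
  }
  keep <- names(which(vapply(split(rec$treatment, rec$trial),
                             function(a) length(unique(a)) >= 2L,
                             logical(1))))
  rec <- rec[rec$trial %in% keep, , drop = FALSE]
  if (nrow(rec) == 0L) stop("subset leaves no analysable trial")
  ipd_dataset(rec, covariates = dataset$covariates,
              treatments = intersect(dataset$treatments,
                                     unique(rec$treatment)))
}

## maximum-likelihood fit of one pairwise design; returns the logHR for the
## contrast first -> second and its standard error
pairwise_ml <- function(dataset, comparison, n_knots = 2L,
                        ph_interactions = FALSE) {
  net <- build_network(dataset, reference = comparison[1])
  cfg <- nma_config(treatment_effects = "fixed", n_knots = n_knots,
                    ph_interactions = ph_interactions)
  design <- build_design(dataset, net, cfg)
  fit <- fit_nma_ml(design)
  bcol <- paste0("beta[", comparison[2], "]")
  i <- match(bcol, names(fit$coef))
  list(estimate = unname(fit$coef[i]), se = sqrt(fit$vcov[i, i]),
       fit = fit, design = design)
}

#' Per-trial and pooled estimates for one pairwise comparison
#'
#' Each qualifying trial (restricted to the two arms of interest) gets its
#' own flexible parametric fit; the pooled estimate comes from the one-stage
#' fixed-treatment-effect model over those trials (trial-specific baseline
#' splines, common log hazard ratio).  The default estimation mode is
#' maximum likelihood with Wald intervals; `method = "bayes"` uses the
#' posterior sampler instead.
#'
#' @param dataset an `ipd_data`.
#' @param comparison length-2 character vector `(a, b)`; the log hazard
#'   ratio reported is for `b` versus `a`.
#' @param n_knots internal knots per trial (small trials fall back to 0).
#' @param method `"ml"` or `"bayes"`.
#' @param settings,priors used when `method = "bayes"`.
#' @return Object of class `pairwise_estimates`: list with `comparison`,
#'   `trials` (data.frame: trial, estimate, se, lower, upper) and `pooled`.
#' @export
pairwise_estimates <- function(dataset, comparison, n_knots = 2L,
                               method = c("ml", "bayes"),
                               settings = NULL, priors = prior_spec()) {
  stopifnot(inherits(dataset, "ipd_data"), length(comparison) == 2L)
  method <- match.arg(method)
  has_both <- vapply(dataset$trials, function(a) all(comparison %in% a),
                     logical(1))
  if (!any(has_both)) {
    stop("no trial compares ", comparison[1], " and ", comparison[2])
  }
  sub <- subset_ipd(dataset, trials = names(which(has_both)),
                    treatments = comparison)
  per_trial <- lapply(names(sub$trials), function(tid) {
    one <- subset_ipd(sub, trials = tid)
    pm <- pairwise_ml(one, comparison, n_knots = n_knots)
    data.frame(trial = tid, estimate = pm$estimate, se = pm$se,
               lower = pm$estimate - 1.96 * pm$se,
               upper = pm$estimate + 1.96 * pm$se,
               stringsAsFactors = FALSE)
  })
  trials_df <- do.call(rbind, per_trial)

  if (method == "ml") {
    pm <- pairwise_ml(sub, comparison, n_knots = n_knots)
    pooled <- list(estimate = pm$estimate, se = pm$se,
                   lower = pm$estimate - 1.96 * pm$se,
                   upper = pm$estimate + 1.96 * pm$se)
  } else {
    net <- build_network(sub, reference = comparison[1])
    cfg <- nma_config(treatment_effects = "fixed", n_knots = n_knots)
    fit <- fit_nma(build_design(sub, net, cfg), priors = priors,
                   settings = settings)
    ps <- posterior_summary(fit, paste0("beta[", comparison[2], "]"))
    pooled <- list(estimate = ps$mean, se = ps$sd, lower = ps$lower,
                   upper = ps$upper)
  }
  structure(list(comparison = comparison, trials = trials_df,
                 pooled = pooled),
            class = "pairwise_estimates")
}

#' @export
print.pairwise_estimates <- function(x, ...) {
  cat("Pairwise comparison ", x$comparison[1], " vs ", x$comparison[2],
      " (", nrow(x$trials), " trials)\n", sep = "")
  print(x$trials, digits = 3)
  cat(sprintf("pooled logHR %.3f (%.3f, %.3f)\n", x$pooled$estimate,
              x$pooled$lower, x$pooled$upper))
  invisible(x)
}

#' Forest-plot data for a pairwise comparison
#'
#' @param x a [pairwise_estimates()] object.
#' @param path optional CSV path; when supplied the table is also written.
#' @return data.frame: `trial`, `estimate`, `lower`, `upper`, `weight`
#'   (inverse variance), with the pooled row labelled `"pooled"`.
#' @export
forest_data <- function(x, path = NULL) {
  stopifnot(inherits(x, "pairwise_estimates"))
  df <- rbind(
    data.frame(trial = x$trials$trial, estimate = x$trials$estimate,
               lower = x$trials$lower, upper = x$trials$upper,
               weight = 1 / x$trials$se^2, stringsAsFactors = FALSE),
    data.frame(trial = "pooled", estimate = x$pooled$estimate,
               lower = x$pooled$lower, upper = x$pooled$upper,
               weight = 1 / x$pooled$se^2, stringsAsFactors = FALSE)
  )
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Inverse-variance heterogeneity statistics
#'
#' Cochran's Q with its chi-squared p-value, \eqn{I^2 = \max\{0, (Q -
#' df)/Q\} \times 100} and the DerSimonian-Laird moment estimator
#' \eqn{\tau^2 = \max\{0, (Q - df) / (\sum w_i - \sum w_i^2 / \sum w_i)\}}
#' from per-trial estimates and standard errors.
#'
#' @param y numeric vector of per-trial estimates (e.g. log hazard ratios).
#' @param se positive standard errors, same length.
#' @return Object of class `heterogeneity`: list with `Q`, `df`, `p`, `I2`
#'   (percent), `tau2`, `pooled` (fixed-effect inverse-variance mean) and
#'   the inputs.
#' @export
heterogeneity <- function(y, se) {
  if (length(y) < 2L) stop("heterogeneity needs at least 2 estimates")
  if (length(se) != length(y) || any(se <= 0)) {
    stop("se must be positive and match y in length")
  }
  w <- 1 / se^2
  yhat <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yhat)^2)
  df <- length(y) - 1L
  I2 <- max(0, (Q - df) / Q) * 100
  if (Q == 0) I2 <- 0
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  structure(list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE),
                 I2 = I2, tau2 = tau2, pooled = yhat, y = y, se = se),
            class = "heterogeneity")
}

#' @export
print.heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran Q = %.2f on %d df (p = %.3f); I2 = %.1f%%; tau2 = %.4f\n",
              x$Q, x$df, x$p, x$I2, x$tau2))
  invisible(x)
}

#' Global Wald test of non-proportional hazards
#'
#' From a fit that includes treatment-by-ln(time) coefficients \eqn{\phi},
#' the Wald statistic \eqn{\hat\phi^\top V(\hat\phi)^{-1} \hat\phi} is
#' computed from the posterior mean and posterior covariance of \eqn{\phi},
#' with `df = dim(phi)` and a chi-squared p-value.  A non-significant result
#' supports continuing under proportional hazards.
#'
#' @param fit an `nma_fit` whose design was built with
#'   `ph_interactions = TRUE`.
#' @return List with `chisq`, `df`, `p`.
#' @export
global_ph_test <- function(fit) {
  stopifnot(inherits(fit, "nma_fit"))
  if (!fit$design$config$ph_interactions) {
    stop("fit has no treatment-ln(time) coefficients; rebuild the design ",
         "with ph_interactions = TRUE")
  }
  phi <- draws_matrix(fit, paste0("phi[", fit$design$nonref, "]"))
  m <- colMeans(phi)
  V <- stats::cov(phi)
  stat <- drop(t(m) %*% solve(V) %*% m)
  list(chisq = stat, df = ncol(phi),
       p = stats::pchisq(stat, ncol(phi), lower.tail = FALSE))
}

#' Wald test of non-proportional hazards for one pairwise comparison
#'
#' Maximum-likelihood analogue of [global_ph_test()] restricted to the
#' trials of one comparison (1 df); used in preliminary per-comparison
#' screening.
#'
#' @inheritParams pairwise_estimates
#' @return List with `chisq`, `df`, `p`.
#' @export
pairwise_ph_test <- function(dataset, comparison, n_knots = 2L) {
  has_both <- vapply(dataset$trials, function(a) all(comparison %in% a),
                     logical(1))
  if (!any(has_both)) {
    stop("no trial compares ", comparison[1], " and ", comparison[2])
  }
  sub <- subset_ipd(dataset, trials = names(which(has_both)),
                    treatments = comparison)
  pm <- pairwise_ml(sub, comparison, n_knots = n_knots,
                    ph_interactions = TRUE)
  pcol <- paste0("phi[", comparison[2], "]")
  i <- match(pcol, names(pm$fit$coef))
  stat <- pm$fit$coef[i]^2 / pm$fit$vcov[i, i]
  list(chisq = unname(stat), df = 1L,
       p = stats::pchisq(unname(stat), 1L, lower.tail = FALSE))
}

#' Test of linearity for a 3-level ordered covariate
#'
#' For every trial with patients observed at all three levels, the linear
#' coding is augmented with a free offset for the middle level and a 1-df
#' Wald test of that offset is computed from a trial-specific flexible
#' parametric fit.  Because trials are independent the chi-squared
#' statistics are summed to give an overall test of the linearity
#' assumption; trials covering fewer than three levels are excluded.
#'
#' @param dataset an `ipd_data`.
#' @param covariate covariate name (ordered, exactly 3 distinct levels
#'   overall).
#' @param levels the 3 ordered level values; default the sorted distinct
#'   observed values.
#' @param n_knots internal knots per trial (with small-trial fallback).
#' @return List with `chisq` (summed), `df` (number of qualifying trials),
#'   `p`, and `per_trial` (data.frame of trial-level statistics).
#' @export
linearity_test <- function(dataset, covariate, levels = NULL, n_knots = 2L) {
  stopifnot(inherits(dataset, "ipd_data"))
  z_all <- dataset$records[[covariate]]
  if (is.null(levels)) levels <- sort(unique(z_all[!is.na(z_all)]))
  if (length(levels) != 3L) stop("linearity test needs exactly 3 levels")
  rows <- list()
  for (tid in names(dataset$trials)) {
    rec <- dataset$records[dataset$records$trial == tid, , drop = FALSE]
    rec <- rec[!is.na(rec[[covariate]]), , drop = FALSE]
    if (!all(levels %in% rec[[covariate]])) next
    w <- lin_trial_wald(rec, covariate, levels, n_knots)
    rows[[length(rows) + 1L]] <- data.frame(trial = tid, chisq = w,
                                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    stop("no trial has patients observed at all 3 covariate levels")
  }
  per_trial <- do.call(rbind, rows)
  stat <- sum(per_trial$chisq)
  df <- nrow(per_trial)
  list(chisq = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       per_trial = per_trial)
}

## single-trial Wald chi-squared (1 df) for the middle-level offset
lin_trial_wald <- function(rec, covariate, levels, n_knots) {
  x <- log(rec$time); d <- rec$event
  ev <- x[d == 1]
  distinct <- length(unique(ev))
  K <- if (distinct < 4L) 0L else min(n_knots, distinct - 2L)
  kn <- if (distinct >= 2L) select_knots(ev, K) else {
    structure(list(boundary = range(x) + c(-0.1, 0.1), internal = numeric(0)),
              class = "knot_set")
  }
  B <- rcs_basis(x, kn); Bd <- rcs_basis_deriv(x, kn)
  arms <- sort(unique(rec$treatment))
  Xtr <- vapply(arms[-1], function(a) as.numeric(rec$treatment == a),
                numeric(nrow(rec)))
  z <- rec[[covariate]]
  mid <- as.numeric(z == levels[2])
  X <- cbind(int = 1, B, Xtr, z = z, mid = mid)
  Xd <- X * 0; Xd[, 1 + seq_len(ncol(B))] <- Bd
  init <- rep(0, ncol(X))
  init[1] <- log(max(sum(d), 0.5) / sum(exp(x))); init[2] <- 1
  fit <- rp_ml(X, Xd, x, d, init = init)
  i <- ncol(X)
  unname(fit$coef[i]^2 / fit$vcov[i, i])
}

#' Direct, indirect and network evidence for a treatment loop
#'
#' Refits the model with an inconsistency parameter \eqn{\omega} attached to
#' the loop's closing edge.  Trials forming that edge then estimate the
#' direct effect (consistency contrast plus \eqn{\omega}) while the rest of
#' the network estimates the indirect effect, so that per draw
#' \eqn{direct - indirect = \omega} by construction.  The network estimate
#' comes from the \eqn{\omega}-free fit.
#'
#' @param dataset an `ipd_data`.
#' @param network an `nma_network` containing the loop.
#' @param loop character vector of treatments forming the loop.
#' @param config base [nma_config()] (its `inconsistency` field is set
#'   internally).
#' @param priors,settings passed to [fit_nma()].
#' @return List with `edge`, per-evidence summaries (`direct`, `indirect`,
#'   `network`, each mean + 95% CrI), `omega` summary, and the two fits.
#' @export
direct_indirect_split <- function(dataset, network, loop,
                                  config = nma_config(),
                                  priors = prior_spec(),
                                  settings = mcmc_settings()) {
  known <- vapply(network$loops, function(l) setequal(l, loop), logical(1))
  if (!any(known)) {
    stop("loop ", paste(loop, collapse = "-"), " is not in the network")
  }
  cfg_omega <- config; cfg_omega$inconsistency <- list(list(loop = loop))
  cfg_plain <- config; cfg_plain$inconsistency <- NULL

  des_w <- build_design(dataset, network, cfg_omega)
  fit_w <- fit_nma(des_w, priors = priors, settings = settings)
  fit_0 <- fit_nma(build_design(dataset, network, cfg_plain),
                   priors = priors, settings = settings)

  edge <- des_w$loops[[1]]$edge
  wts <- contrast_weights(network, edge[1], edge[2])
  bw <- beta_draws(fit_w)
  ind <- drop(bw %*% wts)
  om <- draws_matrix(fit_w, grep("^omega\\[", fit_w$par_names, value = TRUE))
  direct <- ind + om[, 1]
  b0 <- beta_draws(fit_0)
  netd <- drop(b0 %*% wts)

  summ <- function(v) {
    c(mean = mean(v), lower = unname(stats::quantile(v, 0.025)),
      upper = unname(stats::quantile(v, 0.975)))
  }
  list(edge = edge,
       direct = summ(direct), indirect = summ(ind), network = summ(netd),
       omega = c(summ(om[, 1]), sd = stats::sd(om[, 1])),
       fit_omega = fit_w, fit_network = fit_0)
}

#' Agreement of within- and across-trial interactions
#'
#' Applies the half-standard-error criterion: for each contrast the
#' within-trial estimate \eqn{\hat\delta_{Ak}} agrees with the across-trial
#' estimate \eqn{\hat\delta_{Bk}} if their absolute difference is at most
#' half the standard error of the across-trial estimate (boundary counts as
#' agreement).  Standard errors are backed out of the 95% CrI widths as
#' `(upper - lower) / (2 * 1.96)`.  Alternatives attaching the half-SE to
#' the within estimate or to a pooled SE are available via `se_basis`.
#'
#' @param x an `nma_fit` from a separated-interaction model, or a
#'   data.frame with columns `contrast`, `within`, `within_lower`,
#'   `within_upper`, `across`, `across_lower`, `across_upper`.
#' @param se_basis which SE the half-SE threshold uses.
#' @return Object of class `agreement_assessment`: data.frame with the
#'   paired estimates, SEs, `difference`, `threshold` and `verdict`
#'   (`"agree"`/`"disagree"`); attribute `overall` is `"agree"` iff every
#'   contrast agrees.
#' @export
agreement <- function(x, se_basis = c("across", "within", "pooled")) {
  se_basis <- match.arg(se_basis)
  if (inherits(x, "nma_fit")) {
    if (x$design$config$interaction_mode != "separated") {
      stop("agreement assessment needs a separated-interaction fit")
    }
    nonref <- x$design$nonref
    sa <- posterior_summary(x, paste0("deltaA[", nonref, "]"))
    sb <- posterior_summary(x, paste0("deltaB[", nonref, "]"))
    x <- data.frame(contrast = nonref,
                    within = sa$mean, within_lower = sa$lower,
                    within_upper = sa$upper,
                    across = sb$mean, across_lower = sb$lower,
                    across_upper = sb$upper, stringsAsFactors = FALSE)
  }
  need <- c("contrast", "within", "within_lower", "within_upper",
            "across", "across_lower", "across_upper")
  if (!all(need %in% names(x))) {
    stop("agreement input must have columns ", paste(need, collapse = ", "))
  }
  se_a <- (x$within_upper - x$within_lower) / (2 * stats::qnorm(0.975))
  se_b <- (x$across_upper - x$across_lower) / (2 * stats::qnorm(0.975))
  se_use <- switch(se_basis,
                   across = se_b,
                   within = se_a,
                   pooled = sqrt((se_a^2 + se_b^2) / 2))
  diffs <- abs(x$within - x$across)
  thr <- 0.5 * se_use
  out <- data.frame(contrast = x$contrast,
                    within = x$within, se_within = se_a,
                    across = x$across, se_across = se_b,
                    difference = diffs, threshold = thr,
                    verdict = ifelse(diffs <= thr, "agree", "disagree"),
                    stringsAsFactors = FALSE)
  structure(out, class = c("agreement_assessment", "data.frame"),
            overall = if (all(out$verdict == "agree")) "agree" else "disagree")
}

#' @export
print.agreement_assessment <- function(x, ...) {
  print.data.frame(x, digits = 3)
  cat("overall:", attr(x, "overall"), "\n")
  invisible(x)
}
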