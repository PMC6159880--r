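#' Pooled draw matrix
#'
#' @param fit an `nma_fit`.
#' @param pars optional character vector of parameter names.
#' @return Matrix with all chains stacked (columns = parameters).
#' @export
draws_matrix <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "nma_fit"))
  m <- do.call(rbind, fit$draws)
  if (!is.null(pars)) {
    missing <- setdiff(pars, colnames(m))
    if (length(missing)) {
      stop("parameter(s) not monitored: ", paste(missing, collapse = ", "))
    }
    m <- m[, pars, drop = FALSE]
  }
  m
}

#' Posterior summaries (mean and equal-tailed 95% credible interval)
#'
#' @param fit an `nma_fit`.
#' @param pars optional subset of parameter names.
#' @param prob interval mass (default 0.95, equal-tailed percentiles).
#' @return data.frame with columns `parameter`, `mean`, `sd`, `lower`,
#'   `upper`.
#' @export
posterior_summary <- function(fit, pars = NULL, prob = 0.95) {
  m <- draws_matrix(fit, pars)
  m <- m[, colnames(m) != "deviance", drop = FALSE]
  a <- (1 - prob) / 2
  data.frame(
    parameter = colnames(m),
    mean = colMeans(m),
    sd = apply(m, 2, stats::sd),
    lower = apply(m, 2, stats::quantile, probs = a),
    upper = apply(m, 2, stats::quantile, probs = 1 - a),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Deviance information criterion
#'
#' \eqn{\bar D} is the posterior mean deviance, \eqn{p_D = \bar D -
#' D(\bar\theta)} the effective number of parameters (deviance at the
#' posterior mean of the sampled parameters, latent imputed covariates
#' included), and \eqn{DIC = \bar D + p_D}.  Smaller is better; differences
#' under about 5 should not be over-interpreted.  A negative \eqn{p_D} is
#' reported as computed, with a flag, not corrected.
#'
#' @param fit an `nma_fit`.
#' @return List with `DIC`, `pD`, `Dbar`, `negative_pD` (logical flag).
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "nma_fit"))
  dev <- draws_matrix(fit)[, "deviance"]
  dic_from_deviance(dev, fit$D_at_mean)
}

#' @rdname dic
#' @param deviance_draws numeric vector of per-draw deviances.
#' @param deviance_at_mean deviance evaluated at the posterior mean of the
#'   parameters.
#' @export
dic_from_deviance <- function(deviance_draws, deviance_at_mean) {
  Dbar <- mean(deviance_draws)
  pD <- Dbar - deviance_at_mean
  list(DIC = Dbar + pD, pD = pD, Dbar = Dbar, negative_pD = pD < 0)
}

## draws of the basic treatment-effect parameters (q columns, named by
## treatment); works for both FTE (design columns) and RTE (hyper-means)
beta_draws <- function(fit) {
  nonref <- fit$design$nonref
  draws_matrix(fit, paste0("beta[", nonref, "]"))
}

#' All pairwise treatment contrasts through the consistency equations
#'
#' For every pair of treatments the contrast a -> b is computed per draw as
#' \eqn{\beta_b - \beta_a} (with \eqn{\beta} of the reference fixed at 0)
#' and summarised.  Per draw the identity
#' \eqn{\beta_c - \beta_b = (\beta_c - \beta_a) - (\beta_b - \beta_a)} holds
#' exactly, so all non-basic contrasts are consistent by construction.
#'
#' @param fit an `nma_fit`.
#' @return data.frame with columns `from`, `to`, `mean`, `sd`, `lower`,
#'   `upper` (95% equal-tailed CrI) for every ordered pair `from` before
#'   `to` in the declared treatment order.
#' @export
derived_contrasts <- function(fit) {
  stopifnot(inherits(fit, "nma_fit"))
  trts <- fit$design$network$treatments
  ref <- fit$design$network$reference
  B <- beta_draws(fit)
  eff <- cbind(0, B)
  colnames(eff) <- c(ref, fit$design$nonref)
  eff <- eff[, trts, drop = FALSE]
  out <- list()
  for (i in seq_along(trts)) {
    for (j in seq_along(trts)) {
      if (j <= i) next
      cd <- eff[, trts[j]] - eff[, trts[i]]
      out[[length(out) + 1L]] <- data.frame(
        from = trts[i], to = trts[j],
        mean = mean(cd), sd = stats::sd(cd),
        lower = stats::quantile(cd, 0.025),
        upper = stats::quantile(cd, 0.975),
        row.names = NULL, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Ecological bias per treatment contrast
#'
#' In the separated parameterisation the difference between the across-trial
#' and within-trial interaction coefficients, \eqn{\delta_{Bk} -
#' \delta_{Ak}}, quantifies the ecological bias affecting interaction `k`.
#' Summarised per draw with mean and 95% CrI.
#'
#' @param fit an `nma_fit` from a separated-interaction model.
#' @return data.frame: `contrast`, `mean`, `sd`, `lower`, `upper`.
#' @export
ecological_bias <- function(fit) {
  stopifnot(inherits(fit, "nma_fit"))
  if (fit$design$config$interaction_mode != "separated") {
    stop("ecological bias is defined only for the separated ",
         "interaction parameterisation")
  }
  nonref <- fit$design$nonref
  dA <- draws_matrix(fit, paste0("deltaA[", nonref, "]"))
  dB <- draws_matrix(fit, paste0("deltaB[", nonref, "]"))
  out <- lapply(seq_along(nonref), function(k) {
    dd <- dB[, k] - dA[, k]
    data.frame(contrast = nonref[k], mean = mean(dd), sd = stats::sd(dd),
               lower = stats::quantile(dd, 0.025),
               upper = stats::quantile(dd, 0.975),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Treatment ranking probabilities per covariate level
#'
#' At each requested covariate level \eqn{z^*} the per-draw effect of each
#' treatment versus the reference is \eqn{\beta_k + \delta_k z^*} (combined
#' parameterisation), \eqn{\beta_k + \delta_{Ak} z^*} (separated: the
#' patient-level, within-trial interaction is the clinically relevant one),
#' or \eqn{\beta_k} when no interaction is fitted.  Treatments are ranked
#' per draw (rank 1 = lowest log hazard ratio = most effective) and the
#' probability of each rank is reported; each row sums to 1.
#'
#' @param fit an `nma_fit`.
#' @param covariate_levels numeric vector of covariate values at which to
#'   rank; a single 0 reproduces the no-interaction ranking.
#' @return Named list (one element per level) of probability matrices,
#'   treatments by rank.
#' @export
rank_treatments <- function(fit, covariate_levels = 0) {
  stopifnot(inherits(fit, "nma_fit"))
  cfg <- fit$design$config
  if (length(covariate_levels) > 1L && cfg$covariate_mode == "none") {
    stop("multiple covariate levels need a model with covariate or ",
         "interaction terms")
  }
  nonref <- fit$design$nonref
  trts <- fit$design$network$treatments
  B <- beta_draws(fit)
  D <- NULL
  if (cfg$interaction_mode == "separated") {
    D <- draws_matrix(fit, paste0("deltaA[", nonref, "]"))
  } else if (cfg$interaction_mode == "combined") {
    D <- draws_matrix(fit, paste0("delta[", nonref, "]"))
  }
  out <- list()
  for (z in covariate_levels) {
    eff <- B
    if (!is.null(D)) eff <- B + z * D
    eff <- cbind(0, eff)
    colnames(eff) <- c(fit$design$network$reference, nonref)
    eff <- eff[, trts, drop = FALSE]
    rk <- t(apply(eff, 1, rank, ties.method = "first"))
    pm <- matrix(0, length(trts), length(trts),
                 dimnames = list(trts, paste0("rank", seq_along(trts))))
    for (i in seq_along(trts)) {
      pm[i, ] <- tabulate(rk[, i], nbins = length(trts)) / nrow(rk)
    }
    out[[paste0("z=", format(z))]] <- pm
  }
  out
}

#' Convergence diagnostics: split-Rhat and effective sample size
#'
#' Each chain is split in half; the potential scale reduction factor
#' \eqn{\hat R} compares between- and within-sequence variance, and the
#' effective sample size uses the pooled autocorrelation with Geyer
#' initial-positive-sequence truncation.  Parameters with
#' \eqn{\hat R > 1.05} are flagged.
#'
#' @param fit an `nma_fit` (at least 2 chains).
#' @param rhat_limit flag threshold.
#' @return data.frame: `parameter`, `rhat`, `ess`, `flagged`.
#' @export
convergence <- function(fit, rhat_limit = 1.05) {
  stopifnot(inherits(fit, "nma_fit"))
  if (length(fit$draws) < 2L) stop("convergence checking needs >= 2 chains")
  pars <- setdiff(fit$par_names, "deviance")
  out <- data.frame(parameter = pars, rhat = NA_real_, ess = NA_real_,
                    flagged = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(pars)) {
    seqs <- split_sequences(lapply(fit$draws, function(m) m[, pars[i]]))
    out$rhat[i] <- split_rhat(seqs)
    out$ess[i] <- ess_acf(lapply(fit$draws, function(m) m[, pars[i]]))
  }
  out$flagged <- !is.na(out$rhat) & out$rhat > rhat_limit
  out
}

split_sequences <- function(chains) {
  unlist(lapply(chains, function(v) {
    h <- length(v) %/% 2L
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
}

split_rhat <- function(seqs) {
  m <- length(seqs); n <- length(seqs[[1]])
  means <- vapply(seqs, mean, numeric(1))
  vars <- vapply(seqs, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(if (B <= 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_acf <- function(chains) {
  n <- length(chains[[1]]); m <- length(chains)
  rho_sum <- 0
  for (v in chains) {
    if (stats::sd(v) == 0) next
    ac <- stats::acf(v, lag.max = min(n - 1L, 200L), plot = FALSE,
                     demean = TRUE)$acf[-1]
    ## Geyer: stop at first negative pair sum
    s <- 0
    for (t in seq(1, length(ac) - 1, by = 2)) {
      pair <- ac[t] + ac[t + 1]
      if (is.na(pair) || pair < 0) break
      s <- s + pair
    }
    rho_sum <- rho_sum + s
  }
  rho <- rho_sum / m
  m * n / (1 + 2 * rho)
}

#' Export posterior draws as long CSV
#'
#' Columns `chain`, `iter`, `parameter`, `value`.
#'
#' @param fit an `nma_fit`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "nma_fit"))
  rows <- list()
  for (ch in seq_along(fit$draws)) {
    m <- fit$draws[[ch]]
    rows[[ch]] <- data.frame(
      chain = ch,
      iter = rep(seq_len(nrow(m)), times = ncol(m)),
      parameter = rep(colnames(m), each = nrow(m)),
      value = as.vector(m)
    )
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
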