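#' MCMC sampler settings
#'
#' Defaults mirror a conventional long run of general-purpose Gibbs software
#' (2 chains, 20,000 burn-in, 20,000 retained iterations); analyses in the
#' test suite and the vignette use far smaller runs.  At least 2 chains are
#' required so that split-Rhat convergence checking is possible.
#'
#' @param n_burnin adaptation/burn-in iterations discarded per chain.
#' @param n_iter retained iterations per chain (before thinning).
#' @param n_chains number of chains, `>= 2`.
#' @param thin keep every `thin`-th retained iteration.
#' @param seed integer seed; identical settings + seed give bit-identical
#'   draws.
#' @return Object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_burnin = 20000L, n_iter = 20000L, n_chains = 2L,
                          thin = 1L, seed = 1L) {
  stopifnot(n_burnin >= 0, n_iter > 0, thin >= 1)
  if (n_chains < 2L) stop("n_chains must be >= 2")
  structure(list(n_burnin = as.integer(n_burnin), n_iter = as.integer(n_iter),
                 n_chains = as.integer(n_chains), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

## ---- adaptive random-walk machinery -------------------------------------

## coord_scale sets the initial per-coordinate proposal SDs so that a
## tightly-prior-constrained coefficient cannot stall the whole block
ad_new <- function(d, scale0 = 0.1, coord_scale = NULL) {
  if (is.null(coord_scale)) coord_scale <- rep(1, d)
  list(d = d, ls = log(scale0), cnt = 0, mu = numeric(d),
       M2 = matrix(0, d, d), L = diag(coord_scale, nrow = d),
       target = if (d == 1L) 0.44 else 0.234)
}

ad_propose <- function(a, cur) {
  cur + exp(a$ls) * drop(a$L %*% stats::rnorm(a$d))
}

ad_learn <- function(a, val, accp) {
  a$cnt <- a$cnt + 1
  a$ls <- a$ls + (a$cnt^-0.6) * (accp - a$target)
  dlt <- val - a$mu
  a$mu <- a$mu + dlt / a$cnt
  a$M2 <- a$M2 + outer(dlt, val - a$mu)
  if (a$cnt > 2 * a$d + 20 && a$cnt %% 25 == 0) {
    S <- a$M2 / (a$cnt - 1) + diag(1e-8, a$d)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (!is.null(ch)) a$L <- t(ch)
  }
  a
}

## rows log likelihood (no validity guard beyond the caller's)
ll_rows <- function(eta, detadx, x, d) {
  ev <- d == 1
  if (any(detadx[ev] <= 0)) return(-Inf)
  val <- sum(eta[ev] + log(detadx[ev]) - x[ev]) - sum(exp(eta))
  if (!is.finite(val)) -Inf else val
}

log_trunc_norm <- function(z, mu, sig, a, b) {
  stats::dnorm(z, mu, sig, log = TRUE) -
    log(stats::pnorm(b, mu, sig) - stats::pnorm(a, mu, sig))
}

#' Fit a one-stage IPD NMA model by MCMC
#'
#' Posterior sampling over a [build_design()] layout with the priors of
#' [prior_spec()], using an adaptive blocked random-walk Metropolis sampler:
#' one block per trial (spline coefficients plus any trial-level effects),
#' one block for the global coefficients, conjugate Gibbs steps for
#' random-effect hyper-means and the Wishart-prior precision, and vectorised
#' elementwise updates for latent imputed covariate values.  Proposal
#' covariances adapt during burn-in only and are frozen afterwards.  States
#' with an invalid likelihood (non-monotone cumulative hazard at an event
#' time) are never retained: such proposals are rejected.
#'
#' @param design an `nma_design`.
#' @param priors an [prior_spec()] object.
#' @param settings an [mcmc_settings()] object.
#' @return Object of class `nma_fit` with per-chain draw matrices (columns
#'   named after parameters plus `deviance`), latent-covariate posterior
#'   means and thinned draws, acceptance rates, and the quantities needed by
#'   [dic()].
#' @export
fit_nma <- function(design, priors = prior_spec(), settings = mcmc_settings()) {
  stopifnot(inherits(design, "nma_design"), inherits(priors, "nma_priors"),
            inherits(settings, "mcmc_settings"))
  cfg <- design$config
  P <- nrow(design$par)
  q <- design$q
  J <- length(design$trial_ids)
  n <- design$n
  xv <- design$x; dv <- design$d
  sd0 <- sqrt(priors$location_var)

  ## per-column prior sd (used for non-hierarchical columns)
  prior_sd <- rep(sd0, P)
  names(prior_sd) <- design$par$name
  if (!is.null(priors$beta_sd)) {
    for (nm in names(priors$beta_sd)) {
      hit <- which(design$par$name == nm)
      if (length(hit)) prior_sd[hit] <- priors$beta_sd[[nm]]
    }
  }

  rte <- cfg$treatment_effects == "random"
  rand_alpha <- cfg$covariate_mode == "random_trial"
  rand_delta <- cfg$interaction_mode == "separated" &&
    cfg$interaction_structure == "random_trial"
  impute <- cfg$imputation == "truncated_normal" && any(design$z_missing)
  if (any(design$z_missing) && cfg$imputation != "truncated_normal" &&
      cfg$covariate_mode != "none") {
    stop("design has missing covariate values; set imputation = ",
         "'truncated_normal' or restrict to complete cases before fitting")
  }

  V0 <- priors$wishart_scale
  if (is.null(V0)) V0 <- diag(q)
  df0 <- priors$wishart_df
  if (is.null(df0)) df0 <- q

  ## ---- blocks ----
  blocks <- list()
  for (j in seq_len(J)) {
    cols <- design$groups$gamma[[j]]
    if (cfg$covariate_mode %in% c("fixed_trial", "random_trial")) {
      cols <- c(cols, design$groups$alpha[j])
    }
    if (rte) cols <- c(cols, design$groups$b[[j]])
    if (rand_delta) cols <- c(cols, design$groups$delta_a_trial[[j]])
    blocks[[length(blocks) + 1L]] <- list(cols = cols, trial = j,
                                          rows = which(design$trial_idx == j))
  }
  gcols <- integer(0)
  if (!rte) gcols <- c(gcols, design$groups$beta)
  if (cfg$covariate_mode == "common") gcols <- c(gcols, design$groups$alpha)
  if (cfg$interaction_mode == "separated" && !rand_delta) {
    gcols <- c(gcols, design$groups$delta_a)
  }
  if (cfg$interaction_mode == "separated") {
    gcols <- c(gcols, design$groups$delta_b)
  }
  if (cfg$interaction_mode == "combined") gcols <- c(gcols, design$groups$delta)
  gcols <- c(gcols, design$groups$omega, design$groups$phi)
  if (length(gcols) > 0L) {
    blocks[[length(blocks) + 1L]] <- list(cols = gcols, trial = NA_integer_,
                                          rows = seq_len(n))
  }

  ## block prior evaluator: returns log prior of the block's values
  block_groups <- lapply(blocks, function(bl) design$par$group[bl$cols])
  block_prior <- function(bi, vals, hyp) {
    gr <- block_groups[[bi]]
    cols <- blocks[[bi]]$cols
    lp <- 0
    plain <- gr %in% c("gamma", "beta", "alpha", "delta_a", "delta_b",
                       "delta", "omega", "phi")
    if (blocks[[bi]]$trial %in% seq_len(J) || is.na(blocks[[bi]]$trial)) {
      if (rand_alpha) {
        ia <- gr == "alpha"
        if (any(ia)) {
          lp <- lp + sum(stats::dnorm(vals[ia], hyp$alpha, hyp$sd_alpha,
                                      log = TRUE))
          plain[ia] <- FALSE
        }
      }
      if (any(plain)) {
        lp <- lp + sum(stats::dnorm(vals[plain], 0, prior_sd[cols[plain]],
                                    log = TRUE))
      }
      ib <- gr == "b"
      if (any(ib)) {
        r <- vals[ib] - hyp$beta
        lp <- lp + 0.5 * determinant(hyp$Prec)$modulus -
          0.5 * drop(t(r) %*% hyp$Prec %*% r)
      }
      idt <- gr == "delta_a_trial"
      if (any(idt)) {
        lp <- lp + sum(stats::dnorm(vals[idt], hyp$delta_a, hyp$sd_delta,
                                    log = TRUE))
      }
    }
    lp
  }

  ## hyper draw column names
  hyper_names <- character(0)
  if (rte) hyper_names <- c(hyper_names,
                            paste0("beta[", design$nonref, "]"),
                            paste0("sd_b[", design$nonref, "]"))
  if (rand_alpha) hyper_names <- c(hyper_names, "alpha", "sd_alpha")
  if (rand_delta) hyper_names <- c(hyper_names,
                                   paste0("deltaA[", design$nonref, "]"),
                                   "sd_deltaA")
  miss_idx <- which(design$z_missing)
  miss_trials <- sort(unique(design$trial_idx[miss_idx]))
  if (impute) hyper_names <- c(hyper_names,
                               paste0("zmean[", design$trial_ids[miss_trials],
                                      "]"))
  all_names <- c(design$par$name, hyper_names, "deviance")

  n_keep <- settings$n_iter %/% settings$thin
  chains <- vector("list", settings$n_chains)
  latent_draws <- vector("list", settings$n_chains)
  accept_tot <- numeric(length(blocks)); accept_n <- 0

  theta0 <- rp_ml_init(design)

  for (chain in seq_len(settings$n_chains)) {
    set.seed((settings$seed * 1009L + chain * 7919L) %% 2147483647L)

    ## jittered initial values, retried until the likelihood is finite
    theta <- theta0
    Xz <- design  # carries current z in X
    for (try in 1:50) {
      ## jitter scaled down for coordinates with deliberately tight priors
      cand <- theta0 + stats::rnorm(P, 0, pmin(0.05 / try, prior_sd))
      eta <- drop(Xz$X %*% cand)
      detadx <- drop(Xz$Xd %*% cand)
      if (is.finite(ll_rows(eta, detadx, xv, dv))) { theta <- cand; break }
      if (try == 50) stop("could not find a valid initial state")
    }
    eta <- drop(Xz$X %*% theta)
    detadx <- drop(Xz$Xd %*% theta)

    hyp <- list(beta = numeric(q), Prec = diag(q),
                alpha = 0, sd_alpha = 0.5 * priors$sd_upper,
                delta_a = numeric(q), sd_delta = 0.25 * priors$sd_upper)
    zcur <- Xz$z
    imu <- isig <- NULL
    if (impute) {
      a <- design$bounds[1]; b <- design$bounds[2]
      imu <- ifelse(is.na(design$zbar), mean(c(a, b)), design$zbar)
      isig <- rep((b - a) / 4, J)
    }

    ads <- lapply(blocks, function(bl) {
      ad_new(length(bl$cols),
             coord_scale = pmin(prior_sd[bl$cols], 1))
    })
    ad_z <- list(ls = log(0.2), cnt = 0)
    ad_imp <- if (impute) lapply(seq_len(J), function(j) ad_new(2, 0.2))

    keep <- matrix(NA_real_, n_keep, length(all_names),
                   dimnames = list(NULL, all_names))
    lkeep <- if (impute) matrix(NA_real_, n_keep, length(miss_idx))
    ki <- 0L
    total <- settings$n_burnin + settings$n_iter
    adapting <- TRUE

    for (it in seq_len(total)) {
      adapting <- it <= settings$n_burnin

      ## ---- blocked MH over linear-predictor parameters ----
      for (bi in seq_along(blocks)) {
        bl <- blocks[[bi]]
        cur <- theta[bl$cols]
        prop <- ad_propose(ads[[bi]], cur)
        dth <- prop - cur
        Xb <- Xz$X[bl$rows, bl$cols, drop = FALSE]
        eta_new <- eta[bl$rows] + drop(Xb %*% dth)
        Xdb <- design$Xd[bl$rows, bl$cols, drop = FALSE]
        det_new <- detadx[bl$rows] + drop(Xdb %*% dth)
        ll_new <- ll_rows(eta_new, det_new, xv[bl$rows], dv[bl$rows])
        lr <- -Inf
        if (is.finite(ll_new)) {
          ll_old <- ll_rows(eta[bl$rows], detadx[bl$rows],
                            xv[bl$rows], dv[bl$rows])
          lr <- ll_new - ll_old +
            block_prior(bi, prop, hyp) - block_prior(bi, cur, hyp)
        }
        accp <- if (is.finite(lr)) min(1, exp(lr)) else 0
        if (stats::runif(1) < accp) {
          theta[bl$cols] <- prop
          eta[bl$rows] <- eta_new
          detadx[bl$rows] <- det_new
          cur <- prop
        }
        if (adapting) ads[[bi]] <- ad_learn(ads[[bi]], cur, accp)
        if (!adapting) accept_tot[bi] <- accept_tot[bi] + accp
      }
      if (!adapting) accept_n <- accept_n + 1

      ## ---- conjugate Gibbs for hierarchical hyper-parameters ----
      if (rte) {
        bmat <- matrix(theta[unlist(design$groups$b)], nrow = J, ncol = q,
                       byrow = TRUE)
        A <- J * hyp$Prec + diag(q) / priors$location_var
        Ainv <- chol2inv(chol(A))
        m <- Ainv %*% (hyp$Prec %*% colSums(bmat))
        hyp$beta <- drop(m + t(chol(Ainv)) %*% stats::rnorm(q))
        R <- sweep(bmat, 2, hyp$beta)
        Spost <- solve(solve(V0) + crossprod(R))
        hyp$Prec <- stats::rWishart(1, df0 + J, Spost)[, , 1]
      }
      if (rand_alpha) {
        av <- theta[design$groups$alpha]
        prec <- J / hyp$sd_alpha^2 + 1 / priors$location_var
        hyp$alpha <- stats::rnorm(1, sum(av) / hyp$sd_alpha^2 / prec,
                                  sqrt(1 / prec))
        ## uniform(0, sd_upper) prior on the SD, random-walk on log sd
        s_prop <- hyp$sd_alpha * exp(stats::rnorm(1, 0, 0.2))
        if (s_prop < priors$sd_upper) {
          lr <- sum(stats::dnorm(av, hyp$alpha, s_prop, log = TRUE)) -
            sum(stats::dnorm(av, hyp$alpha, hyp$sd_alpha, log = TRUE)) +
            log(s_prop) - log(hyp$sd_alpha)
          if (log(stats::runif(1)) < lr) hyp$sd_alpha <- s_prop
        }
      }
      if (rand_delta) {
        dmat <- matrix(theta[unlist(design$groups$delta_a_trial)],
                       nrow = J, ncol = q, byrow = TRUE)
        for (k in seq_len(q)) {
          prec <- J / hyp$sd_delta^2 + 1 / priors$location_var
          hyp$delta_a[k] <- stats::rnorm(
            1, sum(dmat[, k]) / hyp$sd_delta^2 / prec, sqrt(1 / prec))
        }
        s_prop <- hyp$sd_delta * exp(stats::rnorm(1, 0, 0.2))
        if (s_prop < priors$sd_upper) {
          lr <- sum(stats::dnorm(dmat, rep(hyp$delta_a, each = J), s_prop,
                                 log = TRUE)) -
            sum(stats::dnorm(dmat, rep(hyp$delta_a, each = J), hyp$sd_delta,
                             log = TRUE)) +
            log(s_prop) - log(hyp$sd_delta)
          if (log(stats::runif(1)) < lr) hyp$sd_delta <- s_prop
        }
      }

      ## ---- latent missing covariates: vectorised elementwise MH ----
      if (impute) {
        a <- design$bounds[1]; b <- design$bounds[2]
        gz <- design_z_slope(Xz, theta)[miss_idx]
        zc <- zcur[miss_idx]
        zp <- zc + exp(ad_z$ls) * stats::rnorm(length(miss_idx))
        inb <- zp >= a & zp <= b
        tj <- design$trial_idx[miss_idx]
        e_old <- eta[miss_idx]
        e_new <- e_old + gz * (zp - zc)
        dll <- dv[miss_idx] * (e_new - e_old) - (exp(e_new) - exp(e_old)) +
          stats::dnorm(zp, imu[tj], isig[tj], log = TRUE) -
          stats::dnorm(zc, imu[tj], isig[tj], log = TRUE)
        accp <- ifelse(inb, pmin(1, exp(dll)), 0)
        acc <- stats::runif(length(miss_idx)) < accp
        if (any(acc)) {
          zcur[miss_idx[acc]] <- zp[acc]
          eta[miss_idx[acc]] <- e_new[acc]
          Xz <- design_set_z(Xz, zcur)
        }
        if (adapting) {
          ad_z$cnt <- ad_z$cnt + 1
          ad_z$ls <- ad_z$ls + (ad_z$cnt^-0.6) * (mean(accp) - 0.44)
        }

        ## trial-level imputation hyper-parameters (mu_j, sigma_j),
        ## informed by observed and current imputed values alike
        for (j in miss_trials) {
          zj <- zcur[design$trial_idx == j]
          cur2 <- c(imu[j], log(isig[j]))
          prop2 <- ad_propose(ad_imp[[j]], cur2)
          mu_p <- prop2[1]; sig_p <- exp(prop2[2])
          lr <- -Inf
          if (sig_p > 1e-3 && sig_p < 2 * (b - a)) {
            lr <- sum(log_trunc_norm(zj, mu_p, sig_p, a, b)) -
              sum(log_trunc_norm(zj, imu[j], isig[j], a, b)) +
              stats::dnorm(mu_p, mean(c(a, b)), b - a, log = TRUE) -
              stats::dnorm(imu[j], mean(c(a, b)), b - a, log = TRUE) +
              log(sig_p) - log(isig[j])   # Jacobian of log-sd walk
          }
          accp2 <- if (is.finite(lr)) min(1, exp(lr)) else 0
          if (stats::runif(1) < accp2) {
            imu[j] <- mu_p; isig[j] <- sig_p
            cur2 <- prop2
          }
          if (adapting) ad_imp[[j]] <- ad_learn(ad_imp[[j]], cur2, accp2)
        }
      }

      ## ---- retain ----
      if (it > settings$n_burnin &&
          (it - settings$n_burnin) %% settings$thin == 0L) {
        ki <- ki + 1L
        dev <- -2 * ll_rows(eta, detadx, xv, dv)
        hv <- numeric(0)
        if (rte) hv <- c(hv, hyp$beta, sqrt(diag(chol2inv(chol(hyp$Prec)))))
        if (rand_alpha) hv <- c(hv, hyp$alpha, hyp$sd_alpha)
        if (rand_delta) hv <- c(hv, hyp$delta_a, hyp$sd_delta)
        if (impute) {
          zm <- vapply(miss_trials, function(j) {
            mean(zcur[design$trial_idx == j])
          }, numeric(1))
          hv <- c(hv, zm)
        }
        keep[ki, ] <- c(theta, hv, dev)
        if (impute) lkeep[ki, ] <- zcur[miss_idx]
      }
    }
    chains[[chain]] <- keep
    if (impute) latent_draws[[chain]] <- lkeep
  }

  ## pooled posterior means for DIC's plug-in deviance
  pooled <- do.call(rbind, chains)
  theta_bar <- pooled[, design$par$name, drop = FALSE]
  theta_bar <- colMeans(theta_bar)
  z_bar <- design$z
  latent <- NULL
  if (impute) {
    lm <- colMeans(do.call(rbind, latent_draws))
    z_bar[miss_idx] <- lm
    latent <- list(post_mean = lm, idx = miss_idx, draws = latent_draws)
  }
  Dm <- design_set_z(design, z_bar)
  eta_bar <- drop(Dm$X %*% theta_bar)
  det_bar <- drop(Dm$Xd %*% theta_bar)
  D_at_mean <- -2 * ll_rows(eta_bar, det_bar, xv, dv)

  structure(list(
    draws = chains, par_names = all_names, design = design, priors = priors,
    settings = settings, latent = latent,
    D_at_mean = D_at_mean,
    accept = if (accept_n > 0) accept_tot / accept_n else rep(NA_real_,
                                                              length(blocks))
  ), class = "nma_fit")
}

#' @export
print.nma_fit <- function(x, ...) {
  cat("NMA posterior fit: ", length(x$draws), " chains x ",
      nrow(x$draws[[1]]), " retained draws, ",
      length(x$par_names) - 1L, " monitored parameters\n", sep = "")
  d <- dic(x)
  cat(sprintf("DIC = %.1f (pD = %.1f, Dbar = %.1f)\n", d$DIC, d$pD, d$Dbar))
  invisible(x)
}
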