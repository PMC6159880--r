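#' Log cumulative hazard under the flexible parametric model
#'
#' Evaluates \eqn{\eta(t) = s(\ln t) + lp + \phi_{lp}\,\ln t}, where `s` is
#' the trial's restricted cubic spline (intercept `gamma[1]`, then one
#' coefficient per basis column) and `lp` collects all time-constant linear
#' predictor terms (treatment, covariate, interaction, inconsistency).  The
#' optional `phi_lp` is the record's treatment-by-ln(time) coefficient, used
#' for proportional-hazards testing.
#'
#' @param t positive time(s).
#' @param gamma spline coefficients, length `K + 2` (intercept first).
#' @param knots a [select_knots()] `knot_set`.
#' @param lp time-constant linear predictor contribution (scalar or vector).
#' @param phi_lp coefficient on `ln t` beyond the spline (scalar or vector).
#' @return Numeric vector of log cumulative hazards.
#' @export
rp_log_cumhaz <- function(t, gamma, knots, lp = 0, phi_lp = 0) {
  stopifnot(all(t > 0))
  x <- log(t)
  B <- rcs_basis(x, knots)
  if (length(gamma) != ncol(B) + 1L) {
    stop("gamma must have length K + 2 (intercept + basis coefficients)")
  }
  gamma[1] + drop(B %*% gamma[-1]) + lp + phi_lp * x
}

#' Model survival function on a time grid
#'
#' \eqn{S(t) = \exp\{-\exp(\eta(t))\}}; non-increasing in `t` whenever the
#' monotonicity condition \eqn{d\eta/d\ln t > 0} holds.
#'
#' @param t positive, ascending time grid.
#' @inheritParams rp_log_cumhaz
#' @return Numeric vector of survival probabilities.
#' @export
rp_survival <- function(t, gamma, knots, lp = 0, phi_lp = 0) {
  if (any(diff(t) < 0)) stop("time grid must be ascending")
  exp(-exp(rp_log_cumhaz(t, gamma, knots, lp = lp, phi_lp = phi_lp)))
}

## Core censored-survival log likelihood on the log cumulative hazard scale.
## eta = ln H(t); detadx = d eta / d ln t must be positive at event times
## (monotone cumulative hazard); violations are reported as an invalid flag,
## never a silent NaN -- samplers treat invalid as rejection.
## Returns list(value, valid).
rp_loglik_core <- function(eta, detadx, x, d) {
  ev <- d == 1
  if (any(detadx[ev] <= 0) || any(!is.finite(eta))) {
    return(list(value = -Inf, valid = FALSE))
  }
  H <- exp(eta)
  val <- sum(eta[ev] + log(detadx[ev]) - x[ev]) - sum(H)
  if (!is.finite(val)) return(list(value = -Inf, valid = FALSE))
  list(value = val, valid = TRUE)
}

#' Censored-survival log likelihood of a model design at given parameters
#'
#' Computes \eqn{\sum_i d_i\{\eta_i + \ln(d\eta/dx)_i - x_i\} - e^{\eta_i}}
#' with \eqn{x_i = \ln t_i}, i.e. the full parametric likelihood of the
#' one-stage model.  If the monotonicity condition fails at any observed
#' event time the likelihood is flagged invalid (`valid = FALSE`,
#' `value = -Inf`) rather than returning `NaN`.
#'
#' @param design a [build_design()] object.
#' @param theta named (or positional) numeric vector over the design's
#'   parameter columns (`design$par$name`).
#' @param z optional replacement covariate vector (observed + imputed), used
#'   when the design carries latent missing covariates.
#' @return List with `value` (log likelihood) and `valid` (logical).
#' @export
nma_loglik <- function(design, theta, z = NULL) {
  stopifnot(inherits(design, "nma_design"))
  X <- design$X
  if (!is.null(z)) X <- design_set_z(design, z)$X
  if (!is.null(names(theta))) theta <- theta[design$par$name]
  eta <- drop(X %*% theta)
  detadx <- drop(design$Xd %*% theta)
  rp_loglik_core(eta, detadx, design$x, design$d)
}

## Maximum likelihood fit of an arbitrary (X, Xd) Royston-Parmar design.
## Used for per-trial forest-plot estimates, pooled pairwise fits, Wald
## tests, and as the independent optimiser in posterior-vs-MLE checks.
rp_ml <- function(X, Xd, x, d, init = NULL, hessian = TRUE) {
  p <- ncol(X)
  if (is.null(init)) init <- rep(0, p)
  nll <- function(th) {
    eta <- drop(X %*% th)
    detadx <- drop(Xd %*% th)
    ll <- rp_loglik_core(eta, detadx, x, d)
    if (!ll$valid) return(1e10)
    -ll$value
  }
  grad <- function(th) {
    eta <- drop(X %*% th)
    detadx <- drop(Xd %*% th)
    if (any(detadx[d == 1] <= 0)) return(rep(0, p))
    w <- ifelse(d == 1, 1 / detadx, 0)
    -(drop(crossprod(X, d - exp(eta))) + drop(crossprod(Xd, w * d)))
  }
  fit <- stats::optim(init, nll, gr = grad, method = "BFGS",
                      control = list(maxit = 500), hessian = hessian)
  vcov <- NULL
  if (hessian) {
    vcov <- tryCatch(solve(fit$hessian), error = function(e) {
      matrix(NA_real_, p, p)
    })
  }
  list(coef = stats::setNames(fit$par, colnames(X)), vcov = vcov,
       loglik = -fit$value, convergence = fit$convergence)
}

## Starting values that always satisfy the monotonicity constraint: per-trial
## exponential fit (gamma_x = 1, intercept = log(total events / total time)),
## all other coefficients 0.
rp_ml_init <- function(design) {
  th <- rep(0, nrow(design$par))
  names(th) <- design$par$name
  for (j in seq_along(design$trial_ids)) {
    rows <- design$trial_idx == j
    rate <- max(sum(design$d[rows]), 0.5) / sum(exp(design$x[rows]))
    cols <- design$groups$gamma[[j]]
    th[cols[1]] <- log(rate)   # intercept
    th[cols[2]] <- 1           # coefficient on x
  }
  th
}

#' Maximum likelihood fit of a non-hierarchical NMA design
#'
#' Direct numerical optimisation of [nma_loglik()] over the design's
#' parameter columns.  Only available for designs without random effects or
#' latent imputation (those require the posterior sampler, [fit_nma()]).
#' Serves as the frequentist mode for per-trial and pooled pairwise
#' estimates, and as an independent cross-check on posterior means.
#'
#' @param design a [build_design()] object.
#' @param hessian compute the observed-information variance matrix?
#' @return List with `coef`, `vcov`, `loglik`, `convergence`.
#' @export
fit_nma_ml <- function(design, hessian = TRUE) {
  stopifnot(inherits(design, "nma_design"))
  if (design$config$treatment_effects != "fixed" ||
      design$config$covariate_mode == "random_trial" ||
      design$config$interaction_structure == "random_trial") {
    stop("maximum likelihood fitting requires a non-hierarchical design")
  }
  if (any(design$z_missing)) {
    stop("design has missing covariate values; use fit_nma() with ",
         "imputation or restrict to complete cases")
  }
  rp_ml(design$X, design$Xd, design$x, design$d, init = rp_ml_init(design),
        hessian = hessian)
}
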