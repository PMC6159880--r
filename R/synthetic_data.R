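#' Configuration of the synthetic IPD network generator
#'
#' Describes a connected multi-treatment network of two- and three-arm
#' trials with trial-specific Weibull baseline hazards, a bounded
#' patient-level covariate whose distribution (and mean) varies by trial,
#' and independently controllable within-trial (`delta_a`) and across-trial
#' (`delta_b`) interaction effects, loop inconsistency, proportional-hazards
#' violation, censoring and covariate missingness.  The defaults emulate the
#' structure of a published cervical-cancer overall-survival network:
#' 4 treatments, 37 trials (2 of them three-arm) and roughly 5,900 patients
#' with about 40% events, and an ordinal severity covariate coded 0/1/2
#' whose trial means vary.  Covariate missingness (including a fully
#' missing trial) is added either through `missing_rates` /
#' `fully_missing_trial` or post hoc with [apply_missingness()].
#'
#' @param treatments character vector of treatment labels.
#' @param reference reference treatment (earliest in `treatments` by
#'   convention).
#' @param trials list of character vectors: the arms of each trial.
#' @param n_per_arm patients per arm (scalar or per-trial vector).
#' @param baseline_shape_range,baseline_rate_range per-trial Weibull shape
#'   and rate are drawn uniformly from these ranges; the baseline log
#'   cumulative hazard is \eqn{p_j \ln(\lambda_j t)}.
#' @param beta named numeric: true basic-parameter log hazard ratios versus
#'   the reference (one per non-reference treatment).
#' @param covariate covariate name.
#' @param bounds covariate support (inclusive).
#' @param trial_mean_range per-trial latent covariate means are drawn
#'   uniformly from this range.
#' @param within_sd within-trial SD of the covariate around its trial mean
#'   (truncated to `bounds`).
#' @param ordinal round covariate values to the nearest integer in
#'   `bounds` (severity-stage coding)?
#' @param alpha true common covariate main effect (log hazard scale).
#' @param delta_a,delta_b named numeric per non-reference treatment: true
#'   within-trial and across-trial interaction coefficients.  The
#'   generating linear predictor follows the separated parameterisation
#'   (within terms centred at the realised trial mean, across terms using
#'   the realised trial mean), so setting `delta_a == delta_b` is exactly
#'   the combined parameterisation.
#' @param omega named list loop-edge inconsistency offsets: names of the
#'   form `"A/B"` add `omega` to the `A -> B` contrast in trials comparing
#'   exactly A and B.
#' @param phi named numeric per non-reference treatment:
#'   treatment-by-ln(time) coefficients (0 = proportional hazards).
#' @param admin_time administrative censoring time.
#' @param dropout_rate fraction of patients with an additional uniform
#'   (0, admin_time) dropout censoring time.
#' @param missing_rates scalar or per-trial vector of MCAR covariate
#'   missingness rates (applied at generation; see [apply_missingness()]
#'   for post-hoc masking).
#' @param fully_missing_trial index (or trial id) of one trial whose
#'   covariate is missing for every patient, or `NULL`.
#' @param seed integer seed.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(
    treatments = c("RT", "CTRT", "CT+RT", "CT+S"),
    reference = treatments[1],
    trials = NULL,
    n_per_arm = 80L,
    baseline_shape_range = c(0.9, 1.3),
    baseline_rate_range = c(0.07, 0.13),
    beta = NULL,
    covariate = "stage",
    bounds = c(0, 2),
    trial_mean_range = c(0.4, 1.6),
    within_sd = 0.6,
    ordinal = TRUE,
    alpha = 0.55,
    delta_a = NULL,
    delta_b = NULL,
    omega = NULL,
    phi = NULL,
    admin_time = 5,
    dropout_rate = 0.1,
    missing_rates = 0,
    fully_missing_trial = NULL,
    seed = 1L) {
  if (is.null(trials)) {
    trials <- c(
      rep(list(c("RT", "CTRT")), 16L),
      rep(list(c("RT", "CT+RT")), 10L),
      rep(list(c("RT", "CT+S")), 5L),
      rep(list(c("CT+RT", "CT+S")), 4L),
      rep(list(c("RT", "CT+RT", "CT+S")), 2L)
    )
  }
  nonref <- setdiff(treatments, reference)
  named0 <- function(v) {
    if (is.null(v)) return(stats::setNames(rep(0, length(nonref)), nonref))
    out <- stats::setNames(rep(0, length(nonref)), nonref)
    bad <- setdiff(names(v), nonref)
    if (length(bad)) {
      stop("effect declared for unknown contrast(s): ",
           paste(bad, collapse = ", "))
    }
    out[names(v)] <- v
    out
  }
  if (is.null(beta)) {
    beta <- stats::setNames(rep(0, length(nonref)), nonref)
    defaults <- c("CTRT" = -0.2, "CT+RT" = 0.1, "CT+S" = -0.4)
    hit <- intersect(names(defaults), nonref)
    beta[hit] <- defaults[hit]
  } else beta <- named0(beta)
  cfg <- structure(list(
    treatments = treatments, reference = reference, trials = trials,
    n_per_arm = n_per_arm,
    baseline_shape_range = baseline_shape_range,
    baseline_rate_range = baseline_rate_range,
    beta = beta, covariate = covariate, bounds = bounds,
    trial_mean_range = trial_mean_range, within_sd = within_sd,
    ordinal = ordinal, alpha = alpha,
    delta_a = named0(delta_a), delta_b = named0(delta_b),
    omega = omega, phi = named0(phi),
    admin_time = admin_time, dropout_rate = dropout_rate,
    missing_rates = missing_rates,
    fully_missing_trial = fully_missing_trial,
    seed = as.integer(seed)
  ), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  arms <- unique(unlist(cfg$trials))
  unknown <- setdiff(arms, cfg$treatments)
  if (length(unknown)) {
    stop("trial arms use undeclared treatment(s): ",
         paste(unknown, collapse = ", "))
  }
  if (any(cfg$n_per_arm <= 0)) stop("n_per_arm must be positive")
  if (any(cfg$missing_rates < 0) || any(cfg$missing_rates > 1)) {
    stop("missing rates must lie in [0, 1]")
  }
  if (cfg$bounds[1] >= cfg$bounds[2]) stop("covariate bounds must be ordered")
  if (!is.null(cfg$omega)) {
    for (nm in names(cfg$omega)) {
      edge <- strsplit(nm, "/", fixed = TRUE)[[1]]
      hit <- vapply(cfg$trials, function(a) setequal(a, edge), logical(1))
      if (!any(hit)) {
        stop("omega declared for edge ", nm,
             " but no trial compares exactly these treatments")
      }
    }
  }
  invisible(cfg)
}

## truncated normal draws by inversion
rtruncn <- function(n, mean, sd, a, b) {
  lo <- stats::pnorm(a, mean, sd); hi <- stats::pnorm(b, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

#' Generate a synthetic IPD network with known truth
#'
#' Per trial: a Weibull baseline (shape, rate) and a latent covariate mean
#' are drawn from the configured ranges; patient covariates are truncated
#' normal around the trial mean (optionally rounded to an ordinal coding);
#' event times are drawn by inverse transform from the cumulative hazard
#' \deqn{H(t) = (\lambda_j t)^{p_j} t^{\phi\cdot trt} \exp(lp)} whose log
#' equals the separated-parameterisation linear predictor at the configured
#' true effects, the across-trial term using the realised trial mean of the
#' covariate; administrative and uniform-dropout censoring are applied; and
#' the configured covariate missingness is masked.  Fully seeded and
#' reproducible.
#'
#' @param config a [generator_config()].
#' @return List with `data` (an [ipd_dataset()]) and `truth` (class
#'   `truth_record`: every generating parameter, including the realised
#'   per-trial baselines and covariate means).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  trts <- config$treatments
  nonref <- setdiff(trts, config$reference)
  Jn <- length(config$trials)
  npa <- rep(config$n_per_arm, length.out = Jn)
  shp <- stats::runif(Jn, config$baseline_shape_range[1],
                      config$baseline_shape_range[2])
  rte <- stats::runif(Jn, config$baseline_rate_range[1],
                      config$baseline_rate_range[2])
  mus <- stats::runif(Jn, config$trial_mean_range[1],
                      config$trial_mean_range[2])
  a <- config$bounds[1]; b <- config$bounds[2]

  recs <- list(); realised <- list()
  for (j in seq_len(Jn)) {
    arms <- config$trials[[j]]
    nj <- npa[j] * length(arms)
    trt <- rep(arms, each = npa[j])
    z <- rtruncn(nj, mus[j], config$within_sd, a, b)
    if (config$ordinal) z <- pmin(b, pmax(a, round(z)))
    zbar <- mean(z)

    ## mapped treatment pattern relative to the trial's baseline arm
    base_arm <- arms[which.min(match(arms, trts))]
    pat <- matrix(0, nj, length(nonref), dimnames = list(NULL, nonref))
    for (k in nonref) {
      pat[, k] <- as.numeric(trt == k) - as.numeric(base_arm == k)
    }
    lp <- drop(pat %*% config$beta) +
      config$alpha * (z - zbar) +
      drop(pat %*% config$delta_a) * (z - zbar) +
      drop(pat %*% config$delta_b) * zbar
    if (!is.null(config$omega)) {
      for (nm in names(config$omega)) {
        edge <- strsplit(nm, "/", fixed = TRUE)[[1]]
        if (setequal(arms, edge)) {
          hi <- order(match(edge, trts))[2]
          lp <- lp + config$omega[[nm]] *
            (as.numeric(trt == edge[hi]) - as.numeric(base_arm == edge[hi]))
        }
      }
    }
    phi_i <- drop(pat %*% config$phi)

    ## H(t) = (lambda t)^p * t^phi * exp(lp); inverse transform with E~Exp(1)
    E <- stats::rexp(nj)
    tev <- (E * exp(-lp) / rte[j]^shp[j])^(1 / (shp[j] + phi_i))
    cens <- rep(config$admin_time, nj)
    drop_i <- stats::runif(nj) < config$dropout_rate
    cens[drop_i] <- stats::runif(sum(drop_i), 0, config$admin_time)
    time <- pmax(pmin(tev, cens), 1e-8)
    event <- as.numeric(tev <= cens)

    recs[[j]] <- data.frame(trial = sprintf("T%02d", j), treatment = trt,
                            time = time, event = event, z = z,
                            stringsAsFactors = FALSE)
    realised[[j]] <- data.frame(trial = sprintf("T%02d", j), shape = shp[j],
                                rate = rte[j], mu = mus[j], zbar = zbar,
                                stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, recs)
  names(rec)[names(rec) == "z"] <- config$covariate

  ## covariate missingness
  rates <- rep(config$missing_rates, length.out = Jn)
  fm <- config$fully_missing_trial
  if (!is.null(fm)) {
    if (is.character(fm)) fm <- match(fm, sprintf("T%02d", seq_len(Jn)))
    rates[fm] <- 1
  }
  if (any(rates > 0)) {
    tid <- match(rec$trial, sprintf("T%02d", seq_len(Jn)))
    mask <- stats::runif(nrow(rec)) < rates[tid]
    rec[[config$covariate]][mask] <- NA_real_
  }

  covspec <- stats::setNames(list(list(bounds = config$bounds)),
                             config$covariate)
  data <- ipd_dataset(rec, covariates = covspec, treatments = trts)
  truth <- structure(c(unclass(config),
                       list(realised = do.call(rbind, realised))),
                     class = "truth_record")
  list(data = data, truth = truth)
}

#' @export
print.truth_record <- function(x, ...) {
  cat("Synthetic-network truth record: ", length(x$trials), " trials, ",
      length(x$treatments), " treatments\n", sep = "")
  cat("beta:", paste(names(x$beta), format(x$beta), sep = "=",
                     collapse = ", "), "\n")
  cat("delta_a:", paste(format(x$delta_a), collapse = ", "),
      " delta_b:", paste(format(x$delta_b), collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a truth record to JSON
#'
#' Round-trips losslessly through [jsonlite::write_json()] /
#' [jsonlite::read_json()].
#'
#' @param truth a `truth_record`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  tr <- unclass(truth)
  ## keep names of effect vectors through the JSON round trip
  for (f in c("beta", "delta_a", "delta_b", "phi")) {
    tr[[f]] <- as.list(tr[[f]])
  }
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Mask covariate values to emulate missing data
#'
#' `MCAR` masks uniformly at the trial's rate; `MAR_arm` doubles the rate
#' (capped at 1) on non-baseline arms so that missingness depends on the
#' randomised arm.  Optionally one trial is rendered fully missing.  All
#' other fields are untouched.
#'
#' @param dataset an `ipd_data`.
#' @param covariate covariate name.
#' @param mechanism `"MCAR"` or `"MAR_arm"`.
#' @param rates scalar or named per-trial vector of masking rates in
#'   `[0, 1]`.
#' @param fully_missing optional trial id to mask completely.
#' @param seed integer seed.
#' @return A new `ipd_data` with masked covariate values.
#' @export
apply_missingness <- function(dataset, covariate,
                              mechanism = c("MCAR", "MAR_arm"),
                              rates = 0, fully_missing = NULL, seed = 1L) {
  stopifnot(inherits(dataset, "ipd_data"))
  mechanism <- match.arg(mechanism)
  if (any(rates < 0) || any(rates > 1)) stop("rates must lie in [0, 1]")
  set.seed(as.integer(seed))
  rec <- dataset$records
  ids <- names(dataset$trials)
  rate_vec <- if (!is.null(names(rates))) {
    out <- stats::setNames(rep(0, length(ids)), ids)
    out[names(rates)] <- rates
    out
  } else stats::setNames(rep(rates, length.out = length(ids)), ids)
  p <- rate_vec[rec$trial]
  if (mechanism == "MAR_arm") {
    base_arm <- vapply(dataset$trials, function(a) {
      a[which.min(match(a, dataset$treatments))]
    }, character(1))
    nonbase <- rec$treatment != base_arm[rec$trial]
    p[nonbase] <- pmin(1, 2 * p[nonbase])
  }
  if (!is.null(fully_missing)) p[rec$trial %in% fully_missing] <- 1
  mask <- stats::runif(nrow(rec)) < p
  rec[[covariate]][mask] <- NA_real_
  ipd_dataset(rec, covariates = dataset$covariates,
              treatments = dataset$treatments)
}
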