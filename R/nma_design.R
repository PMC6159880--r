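#' Modelling choices for a one-stage IPD NMA
#'
#' Collects every modelling decision needed to turn a dataset and network
#' into a fittable design: fixed vs random treatment effects, how the
#' patient-level covariate enters (not at all, as a common effect, a fixed
#' trial-level effect, or a random trial-level effect), whether
#' treatment-covariate interactions are omitted, fitted as two effects that
#' separate the within-trial and across-trial components, or as a single
#' effect combining them, whether the (within-trial) interaction
#' coefficients are common across trials or random trial-level, which
#' treatment loops receive an inconsistency parameter, whether
#' treatment-by-ln(time) terms are added for proportional-hazards testing,
#' and how missing covariate values are handled.
#'
#' In the separated parameterisation the covariate main effect and the
#' within-trial interaction columns are centred at the trial mean
#' \eqn{\bar z_j}; in the combined parameterisation the raw covariate enters.
#' The across-trial interaction columns carry \eqn{trt_k \bar z_j}.
#'
#' @param treatment_effects `"fixed"` or `"random"` (trial-level effects drawn
#'   from a multivariate normal with Wishart-prior precision).
#' @param covariate name of the patient-level covariate, or `NULL`.
#' @param covariate_mode `"none"`, `"common"`, `"fixed_trial"` or
#'   `"random_trial"`.
#' @param interaction_mode `"none"`, `"separated"` or `"combined"`.
#' @param interaction_structure `"common"` or `"random_trial"` (within-trial
#'   interaction coefficients random across trials around a common mean).
#' @param inconsistency list of loops to receive an inconsistency parameter;
#'   each element either a character vector of treatments forming the loop,
#'   or a list with `loop` (character vector) and optionally `edge`
#'   (length-2 character: the direct edge the parameter attaches to; default
#'   is the loop edge with fewest trials).
#' @param ph_interactions add treatment-by-ln(time) coefficients
#'   \eqn{\phi_k}?
#' @param imputation `"off"` or `"truncated_normal"` (Bayesian imputation of
#'   missing covariate values from trial-specific truncated normal
#'   distributions).
#' @param trial_means `"from_data"`, or a named numeric vector supplying
#'   \eqn{\bar z_j} per trial (the two-pass route for trials with missing
#'   covariate data).
#' @param n_knots default number of internal spline knots per trial; trials
#'   with fewer than 4 distinct event times fall back to 0 (Weibull form).
#' @return An object of class `nma_config`.
#' @export
nma_config <- function(treatment_effects = c("fixed", "random"),
                       covariate = NULL,
                       covariate_mode = c("none", "common", "fixed_trial",
                                          "random_trial"),
                       interaction_mode = c("none", "separated", "combined"),
                       interaction_structure = c("common", "random_trial"),
                       inconsistency = NULL,
                       ph_interactions = FALSE,
                       imputation = c("off", "truncated_normal"),
                       trial_means = "from_data",
                       n_knots = 2L) {
  cfg <- list(
    treatment_effects = match.arg(treatment_effects),
    covariate = covariate,
    covariate_mode = match.arg(covariate_mode),
    interaction_mode = match.arg(interaction_mode),
    interaction_structure = match.arg(interaction_structure),
    inconsistency = inconsistency,
    ph_interactions = isTRUE(ph_interactions),
    imputation = match.arg(imputation),
    trial_means = trial_means,
    n_knots = as.integer(n_knots)
  )
  if (cfg$covariate_mode != "none" && is.null(cfg$covariate)) {
    stop("covariate_mode requires a covariate name")
  }
  if (cfg$interaction_mode != "none" && cfg$covariate_mode == "none") {
    stop("an interaction requires covariate_mode != 'none'")
  }
  structure(cfg, class = "nma_config")
}

#' @export
print.nma_config <- function(x, ...) {
  cat("NMA model configuration:\n")
  for (f in c("treatment_effects", "covariate", "covariate_mode",
              "interaction_mode", "interaction_structure", "ph_interactions",
              "imputation", "n_knots")) {
    cat("  ", f, " = ", paste(format(x[[f]]), collapse = ","), "\n", sep = "")
  }
  cat("  inconsistency loops = ", length(x$inconsistency), "\n", sep = "")
  invisible(x)
}

#' Prior specification
#'
#' Noninformative normal priors (mean 0, variance `location_var`) on all
#' location parameters (spline coefficients, treatment effects, covariate and
#' interaction effects, inconsistency and PH coefficients).  Random
#' treatment effects use a Wishart prior on the between-trial precision
#' matrix (degrees of freedom = dimension, identity scale, by default);
#' scalar random-effect standard deviations use Uniform(0, `sd_upper`).
#' Imputation hyper-parameters get weakly informative priors on the
#' covariate's scale.
#'
#' @param location_var prior variance of location parameters.
#' @param wishart_df,wishart_scale Wishart prior for the RTE precision;
#'   defaults: df = number of basic parameters, scale = identity.
#' @param sd_upper upper bound of the uniform prior on scalar random-effect
#'   SDs.
#' @param beta_sd optional named overrides: a tight prior on specific
#'   parameters (list name -> sd), mainly for degenerate-input testing.
#' @return Object of class `nma_priors`.
#' @export
prior_spec <- function(location_var = 1000, wishart_df = NULL,
                       wishart_scale = NULL, sd_upper = 2, beta_sd = NULL) {
  structure(list(location_var = location_var, wishart_df = wishart_df,
                 wishart_scale = wishart_scale, sd_upper = sd_upper,
                 beta_sd = beta_sd),
            class = "nma_priors")
}

#' Build the concrete parameter layout and design columns for a model
#'
#' Translates an [nma_config()] into parameter blocks and per-record design
#' columns: one restricted-cubic-spline block per trial (intercept included),
#' treatment columns that are indicators for non-reference arms mapped
#' through the consistency equations (within each trial the baseline arm's
#' pattern is subtracted, so a trial comparing b vs c contributes the
#' pattern \eqn{\beta_c - \beta_b}), covariate and interaction columns per
#' the chosen parameterisation, an inconsistency column (+/-1) only for
#' records in trials forming the closing edge of a declared loop, and
#' treatment-by-ln(time) columns when requested.
#'
#' @param dataset an [ipd_dataset()].
#' @param network an [build_network()] `nma_network`.
#' @param config an [nma_config()].
#' @return Object of class `nma_design` holding the design matrices `X`
#'   (values) and `Xd` (derivatives with respect to `ln t`), the parameter
#'   table `par`, column-group indices `groups`, knot sets, covariate state
#'   (including which records carry a latent missing value) and references
#'   to the inputs.
#' @export
build_design <- function(dataset, network, config) {
  stopifnot(inherits(dataset, "ipd_data"), inherits(network, "nma_network"),
            inherits(config, "nma_config"))
  rec <- dataset$records
  n <- nrow(rec)
  trial_ids <- names(dataset$trials)
  J <- length(trial_ids)
  trial_idx <- match(rec$trial, trial_ids)
  x <- log(rec$time)
  d <- rec$event
  nonref <- setdiff(network$treatments, network$reference)
  q <- length(nonref)

  ## per-trial baseline arm: the arm earliest in the declared treatment order
  baseline_arm <- vapply(dataset$trials, function(arms) {
    arms[which.min(match(arms, network$treatments))]
  }, character(1))

  ## raw and consistency-mapped treatment patterns
  raw <- matrix(0, n, q, dimnames = list(NULL, nonref))
  for (k in seq_len(q)) raw[, k] <- as.numeric(rec$treatment == nonref[k])
  base_pat <- matrix(0, J, q, dimnames = list(trial_ids, nonref))
  for (k in seq_len(q)) {
    base_pat[, k] <- as.numeric(baseline_arm == nonref[k])
  }
  tmap <- raw - base_pat[trial_idx, , drop = FALSE]

  ## spline knots and bases
  knots <- vector("list", J); names(knots) <- trial_ids
  Kj <- integer(J)
  for (j in seq_len(J)) {
    rows <- trial_idx == j
    ev_x <- x[rows & d == 1]
    distinct <- length(unique(ev_x))
    if (distinct < 2L) {
      ## no spline support (0 or 1 distinct event times): fall back to the
      ## Weibull form, whose basis needs no knots; boundaries only recorded
      rg <- range(x[rows])
      if (diff(rg) == 0) rg <- rg + c(-0.5, 0.5)
      Kj[j] <- 0L
      knots[[j]] <- structure(list(boundary = rg, internal = numeric(0)),
                              class = "knot_set")
    } else {
      Kj[j] <- if (distinct < 4L) 0L else min(config$n_knots, distinct - 2L)
      knots[[j]] <- select_knots(ev_x, Kj[j])
    }
  }

  ## covariate state
  covariate <- config$covariate
  zv <- rep(NA_real_, n); z_missing <- rep(FALSE, n)
  bounds <- c(-Inf, Inf); zbar <- stats::setNames(rep(NA_real_, J), trial_ids)
  if (!is.null(covariate)) {
    if (!covariate %in% names(dataset$covariates)) {
      stop("covariate '", covariate, "' not declared in the dataset")
    }
    zv <- rec[[covariate]]
    z_missing <- is.na(zv)
    bounds <- dataset$covariates[[covariate]]$bounds
    obs_mean <- tapply(zv[!z_missing], rec$trial[!z_missing], mean)
    zbar[names(obs_mean)] <- as.numeric(obs_mean)
    if (is.numeric(config$trial_means)) {
      supplied <- config$trial_means
      zbar[names(supplied)] <- supplied
    }
    if (config$interaction_mode == "separated" && anyNA(zbar)) {
      bad <- trial_ids[is.na(zbar)]
      stop("separated interactions need a trial mean for every trial, but ",
           "the covariate is fully missing in: ",
           paste(bad, collapse = ", "),
           ". Fit the combined model with imputation first and supply ",
           "effective_trial_means() via config$trial_means (two-pass ",
           "procedure).")
    }
    if (any(z_missing) && config$imputation == "off" &&
        config$covariate_mode != "none") {
      ## complete-case handling is the caller's job; latent handling needs
      ## imputation on.  Initialise missing z at the trial mean so designs
      ## remain computable, but flag them.
      zv[z_missing] <- ifelse(is.na(zbar[trial_idx[z_missing]]),
                              mean(bounds[is.finite(bounds)]),
                              zbar[trial_idx[z_missing]])
    }
    if (config$imputation == "truncated_normal") {
      if (!all(is.finite(bounds))) {
        stop("truncated-normal imputation requires finite covariate bounds")
      }
      init <- ifelse(is.na(zbar[trial_idx]), mean(bounds),
                     zbar[trial_idx])
      zv[z_missing] <- init[z_missing]
    }
  }

  ## assemble parameter table and columns
  par_name <- character(0); par_group <- character(0); par_trial <- character(0)
  cols <- list()   # list of n-vectors (values); derivatives assembled after
  dcols <- list()
  zdep_col <- integer(0); zdep_B <- list(); zdep_A0 <- list()

  add_col <- function(name, group, trial, value, deriv = NULL,
                      zB = NULL, zA0 = NULL) {
    par_name <<- c(par_name, name)
    par_group <<- c(par_group, group)
    par_trial <<- c(par_trial, trial)
    cols[[length(cols) + 1L]] <<- value
    dcols[[length(dcols) + 1L]] <<- if (is.null(deriv)) numeric(n) else deriv
    if (!is.null(zB)) {
      zdep_col <<- c(zdep_col, length(cols))
      zdep_B[[length(zdep_B) + 1L]] <<- zB
      zdep_A0[[length(zdep_A0) + 1L]] <<- if (is.null(zA0)) numeric(n) else zA0
    }
  }

  groups <- list(gamma = vector("list", J))
  for (j in seq_len(J)) {
    rows <- trial_idx == j
    B <- rcs_basis(x, knots[[j]]); Bd <- rcs_basis_deriv(x, knots[[j]])
    first <- length(cols) + 1L
    add_col(sprintf("gamma[%s,0]", trial_ids[j]), "gamma", trial_ids[j],
            as.numeric(rows))
    for (m in seq_len(ncol(B))) {
      add_col(sprintf("gamma[%s,%d]", trial_ids[j], m), "gamma",
              trial_ids[j], as.numeric(rows) * B[, m],
              deriv = as.numeric(rows) * Bd[, m])
    }
    groups$gamma[[j]] <- first:length(cols)
  }

  if (config$treatment_effects == "fixed") {
    first <- length(cols) + 1L
    for (k in seq_len(q)) {
      add_col(sprintf("beta[%s]", nonref[k]), "beta", NA_character_,
              tmap[, k])
    }
    groups$beta <- first:length(cols)
  } else {
    groups$b <- vector("list", J)
    for (j in seq_len(J)) {
      rows <- trial_idx == j
      first <- length(cols) + 1L
      for (k in seq_len(q)) {
        add_col(sprintf("b[%s,%s]", trial_ids[j], nonref[k]), "b",
                trial_ids[j], as.numeric(rows) * tmap[, k])
      }
      groups$b[[j]] <- first:length(cols)
    }
  }

  centred <- config$interaction_mode == "separated"
  zc_off <- if (centred) -zbar[trial_idx] else rep(0, n)  # additive offset
  if (config$covariate_mode == "common") {
    add_col("alpha", "alpha", NA_character_, zv + zc_off,
            zB = rep(1, n), zA0 = zc_off)
    groups$alpha <- length(cols)
  } else if (config$covariate_mode %in% c("fixed_trial", "random_trial")) {
    first <- length(cols) + 1L
    for (j in seq_len(J)) {
      ind <- as.numeric(trial_idx == j)
      add_col(sprintf("alpha[%s]", trial_ids[j]), "alpha", trial_ids[j],
              ind * (zv + zc_off), zB = ind, zA0 = ind * zc_off)
    }
    groups$alpha <- first:length(cols)
  }

  if (config$interaction_mode == "separated") {
    if (config$interaction_structure == "common") {
      first <- length(cols) + 1L
      for (k in seq_len(q)) {
        add_col(sprintf("deltaA[%s]", nonref[k]), "delta_a", NA_character_,
                tmap[, k] * (zv - zbar[trial_idx]),
                zB = tmap[, k], zA0 = -tmap[, k] * zbar[trial_idx])
      }
      groups$delta_a <- first:length(cols)
    } else {
      groups$delta_a_trial <- vector("list", J)
      for (j in seq_len(J)) {
        rows <- trial_idx == j
        first <- length(cols) + 1L
        for (k in seq_len(q)) {
          v <- as.numeric(rows) * tmap[, k]
          add_col(sprintf("deltaA[%s,%s]", trial_ids[j], nonref[k]),
                  "delta_a_trial", trial_ids[j],
                  v * (zv - zbar[trial_idx]),
                  zB = v, zA0 = -v * zbar[trial_idx])
        }
        groups$delta_a_trial[[j]] <- first:length(cols)
      }
    }
    first <- length(cols) + 1L
    for (k in seq_len(q)) {
      add_col(sprintf("deltaB[%s]", nonref[k]), "delta_b", NA_character_,
              tmap[, k] * zbar[trial_idx])
    }
    groups$delta_b <- first:length(cols)
  } else if (config$interaction_mode == "combined") {
    first <- length(cols) + 1L
    for (k in seq_len(q)) {
      add_col(sprintf("delta[%s]", nonref[k]), "delta", NA_character_,
              tmap[, k] * zv, zB = tmap[, k])
    }
    groups$delta <- first:length(cols)
  }

  loops_spec <- normalize_loops(config$inconsistency, network)
  if (length(loops_spec) > 0L) {
    first <- length(cols) + 1L
    for (l in seq_along(loops_spec)) {
      sp <- loops_spec[[l]]
      a <- sp$edge[1]; b <- sp$edge[2]
      in_edge_trial <- vapply(dataset$trials, function(arms) {
        setequal(arms, c(a, b))
      }, logical(1))
      if (!any(in_edge_trial)) {
        stop("inconsistency loop ", paste(sp$loop, collapse = "-"),
             ": no trial compares exactly ", a, " vs ", b)
      }
      w_raw <- as.numeric(rec$treatment == b)
      w_base <- as.numeric(baseline_arm == b)[trial_idx]
      w <- ifelse(in_edge_trial[trial_idx], w_raw - w_base, 0)
      add_col(sprintf("omega[%s]", paste(sp$loop, collapse = "-")),
              "omega", NA_character_, w)
    }
    groups$omega <- first:length(cols)
  }

  if (config$ph_interactions) {
    first <- length(cols) + 1L
    for (k in seq_len(q)) {
      add_col(sprintf("phi[%s]", nonref[k]), "phi", NA_character_,
              tmap[, k] * x, deriv = tmap[, k])
    }
    groups$phi <- first:length(cols)
  }

  X <- do.call(cbind, cols); dimnames(X) <- list(NULL, par_name)
  Xd <- do.call(cbind, dcols); dimnames(Xd) <- list(NULL, par_name)

  design <- structure(list(
    X = X, Xd = Xd,
    par = data.frame(name = par_name, group = par_group, trial = par_trial,
                     stringsAsFactors = FALSE),
    groups = groups,
    n = n, x = x, d = d,
    trial_idx = trial_idx, trial_ids = trial_ids, treatment = rec$treatment,
    tmap = tmap, baseline_arm = baseline_arm,
    knots = knots, K = Kj,
    nonref = nonref, q = q,
    covariate = covariate, z = zv, z_missing = z_missing,
    zbar = zbar, bounds = bounds,
    zdep = list(cols = zdep_col,
                B = if (length(zdep_col)) do.call(cbind, zdep_B) else NULL,
                A0 = if (length(zdep_col)) do.call(cbind, zdep_A0) else NULL),
    loops = loops_spec,
    config = config, network = network, dataset = dataset
  ), class = "nma_design")
  design
}

## resolve loop declarations to (loop, closing edge)
normalize_loops <- function(inconsistency, network) {
  if (is.null(inconsistency) || length(inconsistency) == 0L) return(list())
  lapply(inconsistency, function(sp) {
    if (is.character(sp)) sp <- list(loop = sp)
    loop <- sp$loop
    known <- vapply(network$loops, function(l) setequal(l, loop), logical(1))
    if (!any(known)) {
      stop("declared loop ", paste(loop, collapse = "-"),
           " is not a loop of this network")
    }
    if (is.null(sp$edge)) {
      ## default closing edge: the loop edge supported by fewest trials
      ed <- network$edges
      cand <- lapply(seq_along(loop), function(i) {
        sort(c(loop[i], loop[i %% length(loop) + 1L]))
      })
      ntr <- vapply(cand, function(e) {
        hit <- ed$treatA == e[1] & ed$treatB == e[2]
        if (any(hit)) ed$n_trials[hit] else Inf
      }, numeric(1))
      sp$edge <- cand[[which.min(ntr)]]
    }
    ## orient the edge along the declared treatment order
    sp$edge <- sp$edge[order(match(sp$edge, network$treatments))]
    list(loop = loop, edge = sp$edge)
  })
}

#' @export
print.nma_design <- function(x, ...) {
  cat("NMA design: ", x$n, " records, ", length(x$trial_ids), " trials, ",
      nrow(x$par), " parameter columns\n", sep = "")
  print(table(x$par$group))
  invisible(x)
}

## replace the covariate vector (observed + imputed) and refresh the
## z-dependent design columns; X[, zcols] = A0 + z * B
design_set_z <- function(design, z) {
  if (length(design$zdep$cols) > 0L) {
    design$X[, design$zdep$cols] <- design$zdep$A0 + z * design$zdep$B
  }
  design$z <- z
  design
}

## d eta / d z_i at current coefficients, for vectorised latent updates
design_z_slope <- function(design, theta) {
  if (length(design$zdep$cols) == 0L) return(numeric(design$n))
  drop(design$zdep$B %*% theta[design$zdep$cols])
}

#' Activate latent-variable imputation of missing covariate values
#'
#' Each missing covariate value becomes a latent variable with a
#' \eqn{Normal(\mu_j, \sigma_j^2)} prior truncated to the covariate bounds;
#' the trial-level hyper-parameters \eqn{\mu_j, \sigma_j} receive weakly
#' informative priors and are informed by the observed values.  If the
#' dataset has no missing values the design is returned unchanged.
#'
#' @param design an [build_design()] object.
#' @param bounds optional length-2 numeric overriding the covariate bounds.
#' @return The design with `config$imputation = "truncated_normal"` and an
#'   `impute` element (`latent_idx`: record indices carrying a latent value).
#' @export
attach_imputation <- function(design, bounds = NULL) {
  stopifnot(inherits(design, "nma_design"))
  if (!any(design$z_missing)) return(design)
  if (!is.null(bounds)) design$bounds <- bounds
  if (!all(is.finite(design$bounds))) {
    stop("imputation requires declared finite covariate bounds")
  }
  design$config$imputation <- "truncated_normal"
  design$impute <- list(latent_idx = which(design$z_missing),
                        bounds = design$bounds)
  design
}

#' Effective trial means of a covariate after imputation
#'
#' For a fully observed trial this is the observed mean; for a partially
#' missing trial the count-weighted average of the observed mean and the
#' mean of the posterior means of the imputed values; for a fully missing
#' trial the mean of the posterior means of the imputed values.  These are
#' the \eqn{\bar z_j} to supply to the separated-interaction model in the
#' two-pass procedure.
#'
#' @param x an `nma_fit` from a model with imputation, or an `ipd_data`.
#' @param imputed when `x` is an `ipd_data`: numeric vector of posterior
#'   means for the missing values, in record order.
#' @param covariate covariate name (required for the `ipd_data` form).
#' @return Named numeric vector, one entry per trial.
#' @export
effective_trial_means <- function(x, imputed = NULL, covariate = NULL) {
  if (inherits(x, "nma_fit")) {
    design <- x$design
    z <- design$z
    if (any(design$z_missing)) {
      if (is.null(x$latent$post_mean)) {
        stop("fit carries missing covariates but no latent draws; ",
             "fit with imputation = 'truncated_normal'")
      }
      z[design$z_missing] <- x$latent$post_mean
    }
    trial <- design$trial_ids[design$trial_idx]
    return(tapply_named(z, trial, design$trial_ids))
  }
  stopifnot(inherits(x, "ipd_data"))
  if (is.null(covariate)) stop("covariate name required")
  z <- x$records[[covariate]]
  miss <- is.na(z)
  if (any(miss)) {
    if (is.null(imputed) || length(imputed) != sum(miss)) {
      stop("supply one posterior-mean imputed value per missing record")
    }
    z[miss] <- imputed
  }
  tapply_named(z, x$records$trial, names(x$trials))
}

tapply_named <- function(z, trial, ids) {
  m <- tapply(z, factor(trial, levels = ids), mean)
  stats::setNames(as.numeric(m), ids)
}

#' Dump the design columns for auditing
#'
#' @param design an `nma_design`.
#' @return The design matrix with named columns (one row per record), as a
#'   data.frame prefixed by trial, treatment, time and event.
#' @export
design_matrix <- function(design) {
  stopifnot(inherits(design, "nma_design"))
  cbind(data.frame(trial = design$trial_ids[design$trial_idx],
                   treatment = design$treatment,
                   time = exp(design$x), event = design$d),
        as.data.frame(design$X))
}

#' Serialise / read a model configuration as plain text
#'
#' `key = value` lines; list-valued fields are comma-separated; declared
#' inconsistency loops are written as `A,B,C|A,B` (loop | closing edge)
#' separated by `;`.
#'
#' @param config an `nma_config`.
#' @param path file path.
#' @return `write_config`: `path` invisibly. `read_config`: an `nma_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "nma_config"))
  fmt_means <- if (is.numeric(config$trial_means)) {
    paste(names(config$trial_means), config$trial_means, sep = ":",
          collapse = ",")
  } else config$trial_means
  ## loops need a network to normalise; serialise the raw declaration
  fmt_loops <- paste(vapply(config$inconsistency, function(sp) {
    if (is.character(sp)) sp <- list(loop = sp)
    paste0(paste(sp$loop, collapse = ","),
           if (!is.null(sp$edge)) paste0("|", paste(sp$edge, collapse = ",")))
  }, character(1)), collapse = ";")
  lines <- c(
    paste("treatment_effects =", config$treatment_effects),
    paste("covariate =", if (is.null(config$covariate)) "" else config$covariate),
    paste("covariate_mode =", config$covariate_mode),
    paste("interaction_mode =", config$interaction_mode),
    paste("interaction_structure =", config$interaction_structure),
    paste("inconsistency =", fmt_loops),
    paste("ph_interactions =", config$ph_interactions),
    paste("imputation =", config$imputation),
    paste("trial_means =", fmt_means),
    paste("n_knots =", config$n_knots)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(p) {
    if (length(p) < 2L) "" else paste(p[-1L], collapse = "=")
  }, character(1)))
  g <- function(k) vals[match(k, keys)]
  inc <- NULL
  if (nzchar(g("inconsistency"))) {
    inc <- lapply(strsplit(g("inconsistency"), ";", fixed = TRUE)[[1]],
                  function(s) {
                    parts <- strsplit(s, "|", fixed = TRUE)[[1]]
                    sp <- list(loop = strsplit(parts[1], ",")[[1]])
                    if (length(parts) > 1L) {
                      sp$edge <- strsplit(parts[2], ",")[[1]]
                    }
                    sp
                  })
  }
  tm <- g("trial_means")
  if (grepl(":", tm, fixed = TRUE)) {
    pieces <- strsplit(strsplit(tm, ",")[[1]], ":")
    tm <- stats::setNames(as.numeric(vapply(pieces, `[[`, character(1), 2L)),
                          vapply(pieces, `[[`, character(1), 1L))
  }
  nma_config(
    treatment_effects = g("treatment_effects"),
    covariate = if (nzchar(g("covariate"))) g("covariate") else NULL,
    covariate_mode = g("covariate_mode"),
    interaction_mode = g("interaction_mode"),
    interaction_structure = g("interaction_structure"),
    inconsistency = inc,
    ph_interactions = as.logical(g("ph_interactions")),
    imputation = g("imputation"),
    trial_means = tm,
    n_knots = as.integer(g("n_knots"))
  )
}
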