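#' Construct an IPD survival dataset
#'
#' Bundles patient-level survival records (one row per patient) with the
#' trial/arm structure and covariate metadata needed by the network
#' meta-analysis models.  Each record carries a trial identifier, a treatment
#' label, a positive follow-up time, an event indicator (1 = event,
#' 0 = censored) and optionally patient-level covariates in which missing
#' values are allowed (`NA`).
#'
#' @param data data.frame with columns `trial`, `treatment`, `time`, `event`
#'   plus one column per declared covariate.
#' @param covariates named list of covariate metadata; each element is a list
#'   with `bounds` (length-2 numeric, inclusive support of the covariate) and
#'   optionally `coding` (free-text note, e.g. `"linear 0/1/2"`).  A bare
#'   numeric length-2 vector is accepted as shorthand for `bounds`.
#' @param treatments optional character vector declaring the admissible
#'   treatment labels and their ordering (used to order basic parameters);
#'   when supplied, unknown labels in the data are an error.
#' @return An object of class `ipd_data`: a list with elements `records`
#'   (validated data.frame), `trials` (named list mapping trial id to its set
#'   of treatments), `treatments` (ordered labels) and `covariates`
#'   (metadata list).
#' @seealso [read_ipd()], [build_network()], [trial_summaries()]
#' @export
ipd_dataset <- function(data, covariates = NULL, treatments = NULL) {
  required <- c("trial", "treatment", "time", "event")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("malformed input: missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  covariates <- normalize_covariate_spec(covariates)
  for (cv in names(covariates)) {
    if (!cv %in% names(data)) {
      stop("declared covariate '", cv, "' not found in the data")
    }
  }
  rec <- data.frame(
    trial = as.character(data$trial),
    treatment = as.character(data$treatment),
    time = as.numeric(data$time),
    event = as.numeric(data$event),
    stringsAsFactors = FALSE
  )
  for (cv in names(covariates)) rec[[cv]] <- as.numeric(data[[cv]])

  bad_time <- which(!is.finite(rec$time) | rec$time <= 0)
  if (length(bad_time) > 0L) {
    stop("validation error: non-positive or non-finite time in row(s) ",
         paste(utils::head(bad_time, 5L), collapse = ", "))
  }
  bad_event <- which(!(rec$event %in% c(0, 1)))
  if (length(bad_event) > 0L) {
    stop("validation error: event indicator not in {0,1} in row(s) ",
         paste(utils::head(bad_event, 5L), collapse = ", "))
  }
  if (!is.null(treatments)) {
    unknown <- setdiff(unique(rec$treatment), treatments)
    if (length(unknown) > 0L) {
      stop("unknown treatment label(s): ", paste(unknown, collapse = ", "))
    }
  } else {
    treatments <- unique(rec$treatment)
  }
  for (cv in names(covariates)) {
    b <- covariates[[cv]]$bounds
    obs <- rec[[cv]][!is.na(rec[[cv]])]
    if (length(obs) > 0L && (any(obs < b[1]) || any(obs > b[2]))) {
      stop("covariate '", cv, "' has observed values outside declared bounds [",
           b[1], ", ", b[2], "]")
    }
  }
  if (nrow(rec) == 0L) stop("dataset is empty")

  trials <- lapply(split(rec$treatment, rec$trial), unique)
  structure(
    list(records = rec, trials = trials, treatments = treatments,
         covariates = covariates),
    class = "ipd_data"
  )
}

normalize_covariate_spec <- function(covariates) {
  if (is.null(covariates)) return(list())
  if (is.character(covariates)) {
    covariates <- stats::setNames(
      rep(list(list(bounds = c(-Inf, Inf))), length(covariates)), covariates)
  }
  out <- lapply(covariates, function(cv) {
    if (is.numeric(cv) && length(cv) == 2L) cv <- list(bounds = cv)
    if (is.null(cv$bounds)) cv$bounds <- c(-Inf, Inf)
    if (cv$bounds[1] >= cv$bounds[2]) stop("covariate bounds must be ordered")
    cv
  })
  out
}

#' Read an IPD survival dataset from a long CSV file
#'
#' The only ingest format is a long CSV, one patient per row, with header
#' columns `trial`, `treatment`, `time`, `event` and optionally one column per
#' covariate.  Missing covariate values may be encoded as an empty field or as
#' `NA`; they are preserved as missing, not dropped.
#'
#' @param path path to the CSV file.
#' @inheritParams ipd_dataset
#' @return An [ipd_dataset()] object.
#' @export
read_ipd <- function(path, covariates = NULL, treatments = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  required <- c("trial", "treatment", "time", "event")
  if (!all(required %in% names(df))) {
    stop("malformed header: expected columns ",
         paste(required, collapse = ", "))
  }
  ipd_dataset(df, covariates = covariates, treatments = treatments)
}

#' Write an IPD dataset to CSV
#'
#' @param x an `ipd_data` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ipd <- function(x, path) {
  stopifnot(inherits(x, "ipd_data"))
  utils::write.csv(x$records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.ipd_data <- function(x, ...) {
  nev <- sum(x$records$event)
  cat("IPD survival dataset: ", nrow(x$records), " patients, ",
      length(x$trials), " trials, ", length(x$treatments), " treatments, ",
      nev, " events\n", sep = "")
  if (length(x$covariates) > 0L) {
    cat("covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.ipd_data <- function(x, ...) x$records

#' Resolve multi-arm trials before analysis
#'
#' Multi-arm trials can either share a single baseline spline across all arms
#' (`"share_control"`, the default: the dataset is returned unchanged and the
#' one-stage likelihood handles the induced correlation through the shared
#' baseline), or be split into separate unconfounded pseudo-trials
#' (`"unconfounded_split"`), which requires a user-supplied assignment of arms
#' to sub-trials because the design knowledge needed is not in the data.
#'
#' @param dataset an `ipd_data` object.
#' @param policy `"share_control"` or `"unconfounded_split"`.
#' @param assignment for `"unconfounded_split"`: a named list, one element per
#'   trial to split, each a named list mapping new sub-trial ids to character
#'   vectors of arms.  The arm sets must partition the trial's arms: an arm
#'   (and hence a patient) may appear in exactly one sub-trial.
#' @return A new `ipd_data` object; patient and event counts are conserved.
#' @export
split_multiarm <- function(dataset,
                           policy = c("share_control", "unconfounded_split"),
                           assignment = NULL) {
  stopifnot(inherits(dataset, "ipd_data"))
  policy <- match.arg(policy)
  if (policy == "share_control") return(dataset)
  if (is.null(assignment)) {
    stop("unconfounded_split requires an arm-to-subtrial assignment")
  }
  rec <- dataset$records
  for (tid in names(assignment)) {
    if (!tid %in% names(dataset$trials)) {
      stop("assignment refers to unknown trial '", tid, "'")
    }
    arms_here <- dataset$trials[[tid]]
    amap <- assignment[[tid]]
    all_arms <- unlist(amap, use.names = FALSE)
    if (anyDuplicated(all_arms)) {
      stop("assignment for trial '", tid,
           "' reuses an arm in two sub-trials; a patient may appear only once")
    }
    if (!setequal(all_arms, arms_here)) {
      stop("assignment for trial '", tid, "' must cover all of its arms")
    }
    idx <- rec$trial == tid
    newid <- rep(NA_character_, sum(idx))
    trt <- rec$treatment[idx]
    for (sub in names(amap)) newid[trt %in% amap[[sub]]] <- sub
    rec$trial[idx] <- newid
  }
  ipd_dataset(rec, covariates = dataset$covariates,
              treatments = dataset$treatments)
}

#' Build the treatment network from an IPD dataset
#'
#' Verifies that the comparison graph is connected, sets up the basic
#' parameters (one reference-to-treatment contrast per non-reference
#' treatment), the consistency map expressing any contrast a->b as
#' \eqn{\beta_b - \beta_a} (with \eqn{\beta_{ref} \equiv 0}), and enumerates
#' the fundamental treatment loops of the comparison graph.
#'
#' @param dataset an `ipd_data` object (after the multi-arm policy has been
#'   applied).
#' @param reference reference treatment label; must occur in at least one
#'   trial.
#' @return An object of class `nma_network` with elements `treatments`
#'   (ordered, reference first), `reference`, `basic_parameters` (data.frame
#'   of reference -> treatment contrasts), `loops` (list of treatment cycles)
#'   and `edges` (comparison-level summary used for network plots).
#' @export
build_network <- function(dataset, reference) {
  stopifnot(inherits(dataset, "ipd_data"))
  treatments <- dataset$treatments
  if (!reference %in% treatments ||
      !any(vapply(dataset$trials, function(a) reference %in% a, logical(1)))) {
    stop("reference treatment '", reference, "' absent from the network")
  }
  treatments <- c(reference, setdiff(treatments, reference))

  ## comparison edges with trial / patient weights
  edge_list <- list()
  for (tid in names(dataset$trials)) {
    arms <- sort(dataset$trials[[tid]])
    if (length(arms) < 2L) {
      stop("trial '", tid, "' has fewer than 2 distinct treatments")
    }
    cmb <- utils::combn(arms, 2L)
    for (k in seq_len(ncol(cmb))) {
      key <- paste(cmb[1, k], cmb[2, k], sep = "\r")
      n_pat <- sum(dataset$records$trial == tid &
                     dataset$records$treatment %in% cmb[, k])
      if (is.null(edge_list[[key]])) {
        edge_list[[key]] <- c(n_trials = 0, n_patients = 0)
      }
      edge_list[[key]] <- edge_list[[key]] + c(1, n_pat)
    }
  }
  ek <- do.call(rbind, strsplit(names(edge_list), "\r", fixed = TRUE))
  edges <- data.frame(
    treatA = ek[, 1], treatB = ek[, 2],
    n_trials = vapply(edge_list, `[[`, numeric(1), "n_trials"),
    n_patients = vapply(edge_list, `[[`, numeric(1), "n_patients"),
    row.names = NULL, stringsAsFactors = FALSE
  )

  g <- igraph::graph_from_data_frame(edges[, c("treatA", "treatB")],
                                     directed = FALSE,
                                     vertices = treatments)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    parts <- split(names(comp$membership), comp$membership)
    stop("network is disconnected; components: ",
         paste(vapply(parts, paste, character(1), collapse = "+"),
               collapse = " | "))
  }

  basic <- data.frame(
    from = reference,
    to = setdiff(treatments, reference),
    parameter = paste0("beta[", setdiff(treatments, reference), "]"),
    stringsAsFactors = FALSE
  )

  loops <- fundamental_loops(g)

  structure(
    list(treatments = treatments, reference = reference,
         basic_parameters = basic, loops = loops, edges = edges),
    class = "nma_network"
  )
}

## Fundamental cycles: spanning tree + one cycle per non-tree edge.
fundamental_loops <- function(g) {
  g <- igraph::simplify(g)
  tr <- igraph::mst(g)
  tree_ends <- igraph::as_edgelist(tr)
  all_ends <- igraph::as_edgelist(g)
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  extra <- which(!(key(all_ends) %in% key(tree_ends)))
  loops <- list()
  for (e in extra) {
    a <- all_ends[e, 1]; b <- all_ends[e, 2]
    p <- igraph::shortest_paths(tr, from = a, to = b)$vpath[[1]]
    loops[[length(loops) + 1L]] <- names(p)
  }
  loops
}

#' @export
print.nma_network <- function(x, ...) {
  cat("NMA network: ", length(x$treatments), " treatments (reference ",
      x$reference, "), ", nrow(x$basic_parameters), " basic parameters, ",
      length(x$loops), " loop(s)\n", sep = "")
  print(x$edges)
  invisible(x)
}

#' Expansion of a treatment contrast into basic parameters
#'
#' Returns the vector of weights on the basic parameters
#' \eqn{\beta_2, \ldots, \beta_{q+1}} that expresses the contrast
#' `from -> to` through the consistency equations
#' (\eqn{\beta_{to} - \beta_{from}}, with the reference fixed at 0).
#'
#' @param network an `nma_network`.
#' @param from,to treatment labels.
#' @return Named numeric vector of length `q`.
#' @export
contrast_weights <- function(network, from, to) {
  stopifnot(inherits(network, "nma_network"))
  nonref <- setdiff(network$treatments, network$reference)
  w <- stats::setNames(numeric(length(nonref)), nonref)
  if (to %in% nonref) w[to] <- w[to] + 1
  if (from %in% nonref) w[from] <- w[from] - 1
  w
}

#' Edge-list summary of the comparison network
#'
#' @param network an `nma_network`.
#' @return data.frame with columns `treatA`, `treatB`, `n_trials`,
#'   `n_patients`, suitable for plotting a network diagram elsewhere.
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "nma_network"))
  network$edges
}

#' Per-trial summaries of size, events and a covariate's distribution
#'
#' The trial mean is computed over observed values only; trials in which the
#' covariate is missing for every patient are flagged (`all_missing`), since
#' their mean is undefined until imputation supplies one.
#'
#' @param dataset an `ipd_data` object.
#' @param covariate covariate name declared in the dataset.
#' @return data.frame with one row per trial: `trial`, `n`, `events`,
#'   per-arm counts collapsed into `arms`, `mean` (NA when all missing),
#'   `sd`, `missing_frac`, `all_missing`, `n_levels` (distinct observed
#'   values).
#' @export
trial_summaries <- function(dataset, covariate) {
  stopifnot(inherits(dataset, "ipd_data"))
  if (!covariate %in% names(dataset$covariates)) {
    stop("covariate '", covariate, "' not declared in the dataset")
  }
  rec <- dataset$records
  out <- lapply(names(dataset$trials), function(tid) {
    r <- rec[rec$trial == tid, , drop = FALSE]
    z <- r[[covariate]]
    obs <- z[!is.na(z)]
    tab <- table(r$treatment)
    data.frame(
      trial = tid,
      n = nrow(r),
      events = sum(r$event),
      arms = paste(names(tab), tab, sep = ":", collapse = ";"),
      mean = if (length(obs)) mean(obs) else NA_real_,
      sd = if (length(obs) > 1L) stats::sd(obs) else NA_real_,
      missing_frac = mean(is.na(z)),
      all_missing = all(is.na(z)),
      n_levels = length(unique(obs)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
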