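#' Select knots for the restricted cubic spline baseline
#'
#' Boundary knots are placed at the minimum and maximum of the uncensored log
#' event times; internal knots at equally spaced centiles of the same values
#' (K = 1: median; K = 2: 33rd/67th centiles; and so on).
#'
#' @param log_event_times numeric vector of log event (uncensored) times.
#' @param n_internal number of internal knots, `K >= 0`.
#' @return An object of class `knot_set`: list with `boundary` (length 2) and
#'   `internal` (length `K`, strictly increasing, strictly inside the
#'   boundary).
#' @export
select_knots <- function(log_event_times, n_internal = 0L) {
  x <- log_event_times[is.finite(log_event_times)]
  distinct <- sort(unique(x))
  if (length(distinct) < 2L) {
    stop("fewer than 2 distinct uncensored event times; ",
         "the trial cannot support a baseline spline")
  }
  if (n_internal > length(distinct) - 2L) {
    stop("n_internal must be <= number of distinct event times - 2")
  }
  boundary <- range(distinct)
  internal <- numeric(0)
  if (n_internal > 0L) {
    probs <- seq_len(n_internal) / (n_internal + 1)
    internal <- as.numeric(stats::quantile(x, probs = probs, type = 7))
    if (any(internal <= boundary[1]) || any(internal >= boundary[2]) ||
        any(diff(internal) <= 0)) {
      stop("internal knot centiles collide with the boundary; ",
           "reduce n_internal")
    }
  }
  structure(list(boundary = boundary, internal = internal),
            class = "knot_set")
}

#' @export
print.knot_set <- function(x, ...) {
  cat("knots on ln(t): boundary [", format(x$boundary[1]), ", ",
      format(x$boundary[2]), "], ", length(x$internal), " internal",
      if (length(x$internal)) paste0(" (", paste(format(x$internal),
                                                 collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Restricted cubic spline basis on the log-time scale
#'
#' Basis for the baseline log cumulative hazard \eqn{s(x)}, `x = ln t`.  The
#' first component is `x` itself; component `m` (for internal knot
#' \eqn{k_m}) is
#' \deqn{(x-k_m)_+^3 - \lambda_m (x-k_{min})_+^3 - (1-\lambda_m)(x-k_{max})_+^3}
#' with \eqn{\lambda_m = (k_{max}-k_m)/(k_{max}-k_{min})}, which constrains
#' the spline to be linear beyond the boundary knots.  The intercept is
#' carried by the linear predictor, not the basis.
#'
#' @param x numeric vector on the `ln t` scale.
#' @param knots a `knot_set`.
#' @return Matrix `length(x)` by `K + 1`.
#' @export
rcs_basis <- function(x, knots) {
  stopifnot(inherits(knots, "knot_set"))
  kmin <- knots$boundary[1]; kmax <- knots$boundary[2]
  K <- length(knots$internal)
  out <- matrix(0, nrow = length(x), ncol = K + 1L)
  out[, 1L] <- x
  if (K > 0L) {
    pl3 <- function(u) pmax(u, 0)^3
    for (m in seq_len(K)) {
      km <- knots$internal[m]
      lam <- (kmax - km) / (kmax - kmin)
      out[, m + 1L] <- pl3(x - km) - lam * pl3(x - kmin) -
        (1 - lam) * pl3(x - kmax)
    }
  }
  colnames(out) <- c("x", if (K > 0L) paste0("v", seq_len(K)))
  out
}

#' Analytic derivative of the restricted cubic spline basis
#'
#' Exact derivative of each [rcs_basis()] component with respect to
#' `x = ln t`; needed because the hazard involves \eqn{ds/dx}.  The
#' derivative of the linear component is 1; cubic components have derivative
#' \eqn{3(x-k_m)_+^2 - 3\lambda_m (x-k_{min})_+^2 - 3(1-\lambda_m)(x-k_{max})_+^2},
#' constant beyond the boundary knots.
#'
#' @inheritParams rcs_basis
#' @return Matrix `length(x)` by `K + 1`.
#' @export
rcs_basis_deriv <- function(x, knots) {
  stopifnot(inherits(knots, "knot_set"))
  kmin <- knots$boundary[1]; kmax <- knots$boundary[2]
  K <- length(knots$internal)
  out <- matrix(0, nrow = length(x), ncol = K + 1L)
  out[, 1L] <- 1
  if (K > 0L) {
    pl2 <- function(u) pmax(u, 0)^2
    for (m in seq_len(K)) {
      km <- knots$internal[m]
      lam <- (kmax - km) / (kmax - kmin)
      out[, m + 1L] <- 3 * pl2(x - km) - 3 * lam * pl2(x - kmin) -
        3 * (1 - lam) * pl2(x - kmax)
    }
  }
  colnames(out) <- c("x", if (K > 0L) paste0("v", seq_len(K)))
  out
}
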