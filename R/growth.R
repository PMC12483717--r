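#' Declarative specification of a piecewise polynomial growth trajectory
#'
#' Describes a multiphase growth function on the time-since-origin scale:
#' the number of phases, the order of continuity imposed at each knot
#' (\code{-1} = discontinuous jump, \code{0} = zero-order continuity, i.e.
#' adjacent phases meet at the knot), and which parameters carry random
#' effects.  Each phase is a degree-one polynomial (the linear--linear family
#' and its single-phase/multi-knot generalizations); zero-order continuity at
#' a knot eliminates the following phase's intercept, which is then derived
#' from the remaining parameters rather than freely estimated.
#'
#' Parameters are classified as *linear* when the first partial derivative of
#' the trajectory with respect to the parameter does not involve the
#' parameter itself (intercepts, slopes) and *nonlinear* otherwise
#' (changepoints, whose derivative involves the changepoint through the
#' regime indicator).
#'
#' @param n_phases integer >= 1; number of linear phases.
#' @param continuity integer order of continuity at each knot: scalar or
#'   length `n_phases - 1` vector with entries `-1` (discontinuous) or `0`
#'   (zero-order).  Ignored when `n_phases == 1`.
#' @param time_origin chronological age (months) mapped to time 0; the
#'   default 18 months matches assessment designs that start at 1.5 years.
#' @param random character vector naming the free parameters that carry
#'   random effects; defaults to all free parameters.
#' @return An object of class `"growth_spec"`.
#' @examples
#' growth_spec()                      # linear-linear, zero-order continuity
#' growth_spec(continuity = -1)      # unconstrained two-phase model
#' growth_spec(n_phases = 1)         # straight line
#' @seealso [classify_linearity()], [n_free_growth_params()], [growth_basis()]
#' @export
growth_spec <- function(n_phases = 2L, continuity = 0L, time_origin = 18,
                        random = NULL) {
  n_phases <- as.integer(n_phases)
  if (n_phases < 1L) stop("n_phases must be >= 1")
  n_knots <- n_phases - 1L
  if (n_knots > 0L) {
    continuity <- as.integer(rep_len(continuity, n_knots))
    if (any(!continuity %in% c(-1L, 0L)))
      stop("continuity must be -1 (discontinuous) or 0 (zero-order) per knot; ",
           "degree-one phases admit no higher order")
  } else {
    continuity <- integer(0)
  }

  # enumerate free parameters: phase-1 intercept & slope, then per later
  # phase a slope plus (only if the preceding knot is discontinuous) an
  # intercept; each knot contributes one nonlinear changepoint
  nm <- c("intercept", "slope1")
  tag <- c("linear", "linear")
  if (n_phases > 1L) {
    for (ph in 2:n_phases) {
      if (continuity[ph - 1L] == -1L) {
        nm <- c(nm, paste0("intercept", ph))
        tag <- c(tag, "linear")
      }
      nm <- c(nm, paste0("slope", ph))
      tag <- c(tag, "linear")
    }
    cp <- if (n_knots == 1L) "changepoint" else paste0("changepoint", seq_len(n_knots))
    nm <- c(nm, cp)
    tag <- c(tag, rep("nonlinear", n_knots))
  }
  names(tag) <- nm
  if (is.null(random)) random <- nm
  if (!all(random %in% nm))
    stop("unknown random-effect parameter(s): ",
         paste(setdiff(random, nm), collapse = ", "))
  structure(list(n_phases = n_phases, continuity = continuity,
                 time_origin = time_origin, params = nm, linearity = tag,
                 random = random),
            class = "growth_spec")
}

#' @export
print.growth_spec <- function(x, ...) {
  cat("Piecewise growth specification:", x$n_phases, "degree-1 phase(s)\n")
  if (length(x$continuity))
    cat("  continuity at knot(s):",
        paste(ifelse(x$continuity == 0L, "zero-order", "discontinuous"),
              collapse = ", "), "\n")
  cat("  time origin:", x$time_origin, "months\n")
  cat("  free parameters (", length(x$params), "): ",
      paste0(x$params, " [", x$linearity, "]", collapse = ", "), "\n", sep = "")
  cat("  random effects:", paste(x$random, collapse = ", "), "\n")
  invisible(x)
}

#' Linear/nonlinear classification of free growth parameters
#'
#' Applies the derivative-inclusion rule: a parameter is linear iff
#' \eqn{\partial f / \partial \theta} does not involve \eqn{\theta}.  For
#' piecewise degree-one trajectories all intercepts and slopes are linear and
#' all changepoints are nonlinear.
#'
#' @param spec a [growth_spec()].
#' @return Named character vector of `"linear"` / `"nonlinear"` tags, one per
#'   free parameter.
#' @examples
#' table(classify_linearity(growth_spec(continuity = -1)))  # 4 linear, 1 nonlinear
#' table(classify_linearity(growth_spec()))                 # 3 linear, 1 nonlinear
#' @export
classify_linearity <- function(spec) {
  stopifnot(inherits(spec, "growth_spec"))
  spec$linearity
}

#' Number of freely estimated growth parameters
#'
#' Counts per-individual free growth parameters after continuity
#' eliminations: 5 for the unconstrained linear--linear model, 4 under
#' zero-order continuity, 2 for a single line.
#'
#' @param spec a [growth_spec()].
#' @return Integer count.
#' @export
n_free_growth_params <- function(spec) {
  stopifnot(inherits(spec, "growth_spec"))
  length(spec$params)
}

#' Growth parameters of the continuity-constrained linear--linear trajectory
#'
#' Bundles the four free parameters of the zero-order-continuity
#' linear--linear model: log rate per unit exposure at the time origin
#' (`intercept`), pre-changepoint slope per month (`slope1`),
#' post-changepoint slope per month (`slope2`), and the changepoint in months
#' since the origin (`changepoint`, >= 0).  The phase-2 intercept is never
#' free: continuity fixes it at `intercept + slope1 * changepoint`.
#'
#' @param intercept,slope1,slope2 real coefficients.
#' @param changepoint nonnegative changepoint (months since origin).
#' @return Named numeric vector of class `"growth_params"`.
#' @examples
#' p <- growth_params(-5.8, 0.25, 0, 10)
#' phase2_intercept(p)   # -5.8 + 0.25 * 10
#' @export
growth_params <- function(intercept, slope1, slope2, changepoint) {
  x <- c(intercept = unname(intercept), slope1 = unname(slope1),
         slope2 = unname(slope2), changepoint = unname(changepoint))
  if (any(!is.finite(x))) stop("growth parameters must be finite")
  if (changepoint < 0) stop("changepoint must be >= 0 (months since origin)")
  structure(x, class = "growth_params")
}

#' @rdname growth_params
#' @param params a `"growth_params"` vector.
#' @export
phase2_intercept <- function(params) {
  unname(params[["intercept"]] + params[["slope1"]] * params[["changepoint"]])
}

#' Evaluate the linear--linear trajectory
#'
#' \eqn{f(t) = \beta_0 + \beta_1 \min(t, \gamma) + \beta_2^{*} \max(0, t - \gamma)}
#' on the log-rate scale: slope `slope1` before the changepoint, `slope2`
#' after, continuous at the knot by construction.
#'
#' @param t times in months since the origin; must be >= 0 (ages before the
#'   origin are outside the model's support).
#' @param params a [growth_params()] vector.
#' @return Numeric vector `f(t)`.
#' @export
growth_value <- function(t, params) {
  stopifnot(inherits(params, "growth_params"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be nonnegative (months since the time origin)")
  g <- params[["changepoint"]]
  unname(params[["intercept"]] + params[["slope1"]] * pmin(t, g) +
           params[["slope2"]] * pmax(0, t - g))
}

#' First-order factor-loading basis of the linear--linear SLCM
#'
#' Rows are assessment times, columns the first partial derivatives of the
#' trajectory with respect to the free parameters, evaluated at the
#' population values: `1`, `min(t, changepoint)`, `max(0, t - changepoint)`,
#' and `(slope1 - slope2) * 1(t > changepoint)` for the changepoint column
#' (the random changepoint deviation is centered at zero).  At `t` exactly
#' equal to the changepoint the indicator takes its left value (0),
#' consistent with `max(0, t - changepoint) = 0` there.
#'
#' @param times vector of times >= 0 (months since origin).
#' @param params population [growth_params()].
#' @param random character vector of columns to keep, default all four.
#' @return Matrix `length(times) x length(random)`.
#' @export
growth_basis <- function(times, params,
                         random = c("intercept", "slope1", "slope2",
                                    "changepoint")) {
  stopifnot(inherits(params, "growth_params"))
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be nonnegative (months since the time origin)")
  g <- params[["changepoint"]]
  after <- times > g
  full <- cbind(intercept = rep(1, length(times)),
                slope1 = pmin(times, g),
                slope2 = pmax(0, times - g),
                changepoint = (params[["slope1"]] - params[["slope2"]]) * after)
  bad <- setdiff(random, colnames(full))
  if (length(bad)) stop("unknown basis column(s): ", paste(bad, collapse = ", "))
  full[, random, drop = FALSE]
}
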