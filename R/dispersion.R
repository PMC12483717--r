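#' Population trajectory for time-varying NB2 dispersion parameters
#'
#' The occasion-specific NB2 dispersion parameters \eqn{\phi_w} are
#' population quantities (shared across individuals at each occasion).  They
#' may be left `"free"` (one parameter per occasion), or constrained to a
#' parametric trajectory over time:
#' \describe{
#'   \item{loglinear}{\eqn{\phi(t) = \exp(\delta_0 + \delta_1 t)}; `coeffs`
#'     = `c(d0, d1)` on the log scale.}
#'   \item{expdecay}{exponential decay with a nonzero asymptote,
#'     \eqn{\phi(t) = \delta_3 + (\delta_1 - \delta_3)\,\delta_2^{t}};
#'     `coeffs` = `c(level, decay, asymptote)` with `level` the dispersion at
#'     the time origin (`t = 0`), `decay` in (0, 1), and
#'     `0 < asymptote < level`, so that \eqn{\phi} is strictly decreasing and
#'     positive with \eqn{\phi(0) =} `level` and limit `asymptote`.}
#' }
#'
#' @param form `"free"`, `"loglinear"`, or `"expdecay"`.
#' @param coeffs numeric coefficients: length 0 for `"free"` (the per-bin
#'   values are held by the model fit, not here), 2 for `"loglinear"`,
#'   3 for `"expdecay"`.
#' @return Object of class `"dispersion_trajectory"`.
#' @examples
#' dispersion_trajectory("expdecay", c(level = 2.5, decay = 0.9, asymptote = 0.2))
#' @export
dispersion_trajectory <- function(form = c("expdecay", "loglinear", "free"),
                                  coeffs = numeric(0)) {
  form <- match.arg(form)
  coeffs <- unname(as.numeric(coeffs))
  if (form == "free") {
    if (length(coeffs) != 0L) stop("'free' takes no coefficients")
  } else if (form == "loglinear") {
    if (length(coeffs) != 2L || any(!is.finite(coeffs)))
      stop("'loglinear' needs 2 finite coefficients (log-scale intercept, slope)")
    names(coeffs) <- c("log_level", "log_slope")
  } else {
    if (length(coeffs) != 3L || any(!is.finite(coeffs)))
      stop("'expdecay' needs 3 coefficients (level, decay, asymptote)")
    names(coeffs) <- c("level", "decay", "asymptote")
    if (coeffs[3L] <= 0 || coeffs[1L] <= coeffs[3L])
      stop("'expdecay' requires level > asymptote > 0")
    if (coeffs[2L] <= 0 || coeffs[2L] >= 1)
      stop("'expdecay' decay factor must lie strictly in (0, 1)")
  }
  structure(list(form = form, coeffs = coeffs),
            class = "dispersion_trajectory")
}

#' @export
print.dispersion_trajectory <- function(x, ...) {
  cat("Dispersion trajectory:", x$form, "\n")
  if (length(x$coeffs)) print(x$coeffs)
  invisible(x)
}

#' Evaluate a dispersion trajectory
#'
#' @param traj a [dispersion_trajectory()] of form `"loglinear"` or
#'   `"expdecay"` (the `"free"` form has no trajectory to evaluate).
#' @param times nonnegative times (months since origin).
#' @return Vector of strictly positive dispersions \eqn{\phi(t)}.
#' @export
dispersion_at <- function(traj, times) {
  stopifnot(inherits(traj, "dispersion_trajectory"))
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be nonnegative")
  switch(traj$form,
         free = stop("'free' dispersion has no trajectory; per-occasion values live in the fit"),
         loglinear = exp(traj$coeffs[[1L]] + traj$coeffs[[2L]] * times),
         expdecay = traj$coeffs[[3L]] +
           (traj$coeffs[[1L]] - traj$coeffs[[3L]]) * traj$coeffs[[2L]]^times)
}

#' Number of freely estimated dispersion parameters
#'
#' Constraining the W occasion-specific dispersions to a trajectory reduces
#' the free count from W to the trajectory's coefficient length.
#'
#' @param traj a [dispersion_trajectory()].
#' @param W number of unique measurement occasions (>= 1).
#' @return Integer: `W` for `"free"`, 2 for `"loglinear"`, 3 for `"expdecay"`.
#' @export
n_dispersion_params <- function(traj, W) {
  stopifnot(inherits(traj, "dispersion_trajectory"))
  W <- as.integer(W)
  if (W < 1L) stop("W must be >= 1")
  switch(traj$form, free = W, loglinear = 2L, expdecay = 3L)
}
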