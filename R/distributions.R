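#' Counting-process distribution specification
#'
#' Constructs a specification of the conditional count distribution used by the
#' measurement model: Poisson (equidispersed) or NB2, the negative binomial
#' with quadratic variance function \eqn{Var(Y) = \mu + \phi \mu^2}.  The
#' dispersion is parameterized as the \eqn{\phi} of the quadratic variance
#' function, so the classical negative binomial "size" is \code{1/phi};
#' Poisson is the limiting distribution as \eqn{\phi \to 0}.
#'
#' @param family `"poisson"` or `"nb2"`.
#' @param dispersion positive dispersion \eqn{\phi}; required for `"nb2"`,
#'   must be absent (`NULL`) for `"poisson"`.
#' @return An object of class `"count_family"` with elements `family` and
#'   `dispersion`.
#' @examples
#' count_family("nb2", dispersion = 0.5)
#' count_family("poisson")
#' @export
count_family <- function(family = c("poisson", "nb2"), dispersion = NULL) {
  family <- match.arg(family)
  if (family == "nb2") {
    if (is.null(dispersion))
      stop("'nb2' requires a dispersion parameter")
    if (!is.numeric(dispersion) || length(dispersion) != 1L ||
        !is.finite(dispersion) || dispersion <= 0)
      stop("dispersion must be a single finite positive number")
  } else if (!is.null(dispersion)) {
    stop("'poisson' must not carry a dispersion parameter")
  }
  structure(list(family = family, dispersion = dispersion),
            class = "count_family")
}

.check_count_args <- function(y, mu) {
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y)))
    stop("y must contain nonnegative integers")
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("mu must be strictly positive")
}

#' NB2 probability mass function
#'
#' Density of the negative binomial distribution in the mean--dispersion
#' parameterization: mean `mu`, variance `mu + phi * mu^2`.  Computed in log
#' space via `lgamma`; equivalently `dnbinom(y, size = 1/phi, mu = mu)`.
#'
#' @param y vector of nonnegative integer counts.
#' @param mu positive mean.
#' @param phi positive dispersion.
#' @param log logical; return log-probabilities?
#' @return Probabilities (or log-probabilities) recycled over the inputs.
#' @examples
#' dnb2(3, mu = 2, phi = 0.5)        # = 1/8
#' sum(dnb2(0:500, mu = 2, phi = 0.5))
#' @export
dnb2 <- function(y, mu, phi, log = FALSE) {
  .check_count_args(y, mu)
  if (any(!is.finite(phi)) || any(phi <= 0))
    stop("phi must be strictly positive")
  r <- 1 / phi
  lp <- lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
    r * (base::log(r) - base::log(r + mu)) +
    y * (base::log(mu) - base::log(r + mu))
  if (log) lp else exp(lp)
}

#' Poisson log probability mass function
#'
#' Thin wrapper over [stats::dpois()] with the same argument checking as
#' [dnb2()], provided so both members of the measurement-model comparison
#' battery share one calling convention.
#'
#' @inheritParams dnb2
#' @return Probabilities (or log-probabilities).
#' @export
dpois_count <- function(y, mu, log = FALSE) {
  .check_count_args(y, mu)
  stats::dpois(y, lambda = mu, log = log)
}

#' Count log-density under a family specification
#'
#' @inheritParams dnb2
#' @param spec a [count_family()] specification.
#' @return Log-probabilities (or probabilities with `log = FALSE`).
#' @export
dcount <- function(y, mu, spec, log = FALSE) {
  stopifnot(inherits(spec, "count_family"))
  if (spec$family == "poisson") dpois_count(y, mu, log = log)
  else dnb2(y, mu, spec$dispersion, log = log)
}

#' Model-implied variance function
#'
#' Returns the conditional variance implied by the family: `mu` for Poisson,
#' `mu + phi * mu^2` for NB2 (quadratic variance).
#'
#' @param mu positive mean(s).
#' @param spec a [count_family()] specification.
#' @return Variances, same length as `mu`.
#' @examples
#' count_variance(2, count_family("nb2", 0.5))  # 4
#' @export
count_variance <- function(mu, spec) {
  stopifnot(inherits(spec, "count_family"))
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be strictly positive")
  if (spec$family == "poisson") mu else mu + spec$dispersion * mu^2
}

#' Sample counts from a family specification
#'
#' Poisson draws use [stats::rpois()]; NB2 draws use the gamma--Poisson
#' mixture construction (a gamma-distributed rate multiplier with mean 1 and
#' variance `phi`, then a Poisson draw), whose marginal is NB2(`mu`, `phi`).
#' Randomness comes from the R session RNG; seed with [set.seed()].
#'
#' @param n number of draws.
#' @param mu positive mean (scalar or length `n`).
#' @param spec a [count_family()] specification.
#' @return Integer vector of `n` counts.
#' @export
rcount <- function(n, mu, spec) {
  stopifnot(inherits(spec, "count_family"))
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be strictly positive")
  if (spec$family == "poisson") return(stats::rpois(n, mu))
  rnb2(n, mu, spec$dispersion)
}

#' @rdname rcount
#' @param phi positive NB2 dispersion (scalar or length `n`).
#' @export
rnb2 <- function(n, mu, phi) {
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be strictly positive")
  if (any(!is.finite(phi)) || any(phi <= 0)) stop("phi must be strictly positive")
  r <- 1 / phi
  lambda <- mu * stats::rgamma(n, shape = r, rate = r)
  stats::rpois(n, lambda)
}
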