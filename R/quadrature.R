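#' Gauss--Hermite rule
#'
#' Nodes and weights of the n-point Gauss--Hermite rule for weight function
#' \eqn{e^{-x^2}}, computed by the Golub--Welsch eigendecomposition of the
#' Jacobi matrix.  `v = w / sqrt(pi)` are the probabilists' weights: they sum
#' to one and integrate a standard normal exactly via nodes `sqrt(2) * x`.
#'
#' @param n number of nodes (>= 1).
#' @return List with `nodes`, `weights`, and normalized `v`.
#' @keywords internal
gauss_hermite <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi), v = 1))
  off <- sqrt(seq_len(n - 1L) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  w <- sqrt(pi) * e$vectors[1L, ord]^2
  list(nodes = e$values[ord], weights = w, v = w / sqrt(pi))
}

#' Quadrature settings for the marginal likelihood
#'
#' @param nodes integration points per dimension (default 7; 15 reproduces
#'   heavier desktop-software defaults).
#' @param adaptive center and scale the grid at each individual's posterior
#'   mode (default) or at the prior?
#' @param prune drop tensor-grid nodes whose product of normalized
#'   Gauss--Hermite weights falls below this threshold.
#' @return List of class `"slcm_quad"`.
#' @export
slcm_quad <- function(nodes = 7L, adaptive = TRUE, prune = 1e-10) {
  nodes <- as.integer(nodes)
  stopifnot(nodes >= 1L, prune >= 0)
  structure(list(nodes = nodes, adaptive = isTRUE(adaptive), prune = prune),
            class = "slcm_quad")
}

# pruned tensor-product node tables for dimensions 1..d
.node_tables <- function(quad, d) {
  gh <- gauss_hermite(quad$nodes)
  logv1 <- log(gh$v)
  lapply(seq_len(max(d, 1L)), function(rho) {
    idx <- as.matrix(do.call(expand.grid, rep(list(seq_len(quad$nodes)), rho)))
    z <- matrix(gh$nodes[idx], ncol = rho)
    logv <- rowSums(matrix(logv1[idx], ncol = rho))
    keep <- if (quad$prune > 0) logv > log(quad$prune) else rep(TRUE, length(logv))
    list(z = t(z[keep, , drop = FALSE]), logv = logv[keep])
  })
}

# draw from N(0, T) allowing singular T
.rmvnorm0 <- function(n, Tmat) {
  d <- nrow(Tmat)
  if (d == 0L) return(matrix(0, n, 0))
  e <- eigen(Tmat, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  z <- matrix(stats::rnorm(n * d), n, d)
  z %*% (t(e$vectors) * sqrt(lam))
}
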