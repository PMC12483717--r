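#' Bin repeated count assessments into age windows
#'
#' Implements the cross-sectionalizing step of the analysis pipeline: ages
#' are binned into half-open windows `[origin + k*width, origin + (k+1)*width)`,
#' assessments below the minimum-exposure floor are dropped first, and when an
#' individual has more than one surviving assessment in a window one is
#' selected uniformly at random so that each individual contributes at most
#' one record per window.  Bins are coded by the window's lower bound minus
#' the origin, so with the defaults the bin times are 0, 3, ..., 51 months.
#'
#' Randomness (the within-window selection) uses the session RNG; call
#' [set.seed()] beforehand for reproducibility.
#'
#' @param data data frame with columns `id`, `age_months`, `count`,
#'   `exposure` (see [read_long_counts()]).
#' @param bin_width window width in months (default 3).
#' @param origin youngest supported age in months (default 18).
#' @param max_age exclusive upper age limit in months (default 72).
#' @param min_exposure minimum number of sampled units for an assessment to
#'   be analyzed (default 25).
#' @return A data frame of class `"binned_counts"` with columns `id`, `t`
#'   (bin time, months since origin), `count`, `exposure`, carrying
#'   attributes `origin`, `bin_width`, `max_age`, `min_exposure`, and
#'   `n_dropped` (a named vector counting age-range rejections, exposure
#'   drops, and within-window deduplications).
#' @examples
#' d <- data.frame(id = c(1, 1, 2), age_months = c(19, 20.5, 30),
#'                 count = c(2, 3, 7), exposure = c(100, 120, 90))
#' set.seed(1)
#' bin_counts(d)
#' @export
bin_counts <- function(data, bin_width = 3, origin = 18, max_age = 72,
                       min_exposure = 25) {
  req <- c("id", "age_months", "count", "exposure")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(data$count < 0 | data$count != round(data$count)))
    stop("counts must be nonnegative integers")
  if (any(data$exposure <= 0)) stop("exposures must be positive")

  out_of_range <- data$age_months < origin | data$age_months >= max_age
  if (any(out_of_range))
    warning(sum(out_of_range), " record(s) with age outside [", origin, ", ",
            max_age, ") rejected")
  d <- data[!out_of_range, req, drop = FALSE]

  low_exp <- d$exposure < min_exposure
  d <- d[!low_exp, , drop = FALSE]

  d$t <- floor((d$age_months - origin) / bin_width) * bin_width
  # uniform random selection among an individual's records within a window
  n0 <- nrow(d)
  if (n0 > 1L) {
    ord <- sample.int(n0)           # random tie-break, seed-dependent
    d <- d[ord, , drop = FALSE]
    keep <- !duplicated(d[, c("id", "t")])
    d <- d[keep, , drop = FALSE]
  }
  n_dedup <- n0 - nrow(d)
  d <- d[order(d$id, d$t), c("id", "t", "count", "exposure")]
  rownames(d) <- NULL
  structure(d,
            origin = origin, bin_width = bin_width, max_age = max_age,
            min_exposure = min_exposure,
            n_dropped = c(age_range = sum(out_of_range),
                          exposure = sum(low_exp), dedup = n_dedup),
            class = c("binned_counts", "data.frame"))
}

#' Empirical dispersion summary per age bin
#'
#' Sample mean and unbiased sample variance of the raw counts within each
#' bin, with an empirical dispersion flag: `"over"` when variance > mean,
#' `"under"` when variance < mean, `"equi"` at equality, `NA` when the
#' variance is undefined (single record).
#'
#' @param binned a [bin_counts()] result (or any data frame with `t` and
#'   `count`).
#' @return Data frame with columns `t`, `n`, `mean`, `var`, `dispersion`.
#' @export
dispersion_summary <- function(binned) {
  stopifnot(all(c("t", "count") %in% names(binned)))
  ts <- sort(unique(binned$t))
  out <- do.call(rbind, lapply(ts, function(tw) {
    y <- binned$count[binned$t == tw]
    v <- if (length(y) > 1L) stats::var(y) else NA_real_
    data.frame(t = tw, n = length(y), mean = mean(y), var = v)
  }))
  out$dispersion <- ifelse(is.na(out$var), NA_character_,
                           ifelse(out$var > out$mean, "over",
                                  ifelse(out$var < out$mean, "under", "equi")))
  out
}

#' Fit a single-bin count GLM with exposure offset
#'
#' Intercept-only Poisson or NB2 regression of the counts in one age bin,
#' with the log exposure entering the linear predictor as an offset whose
#' coefficient is fixed at one: `log mu_i = log u_i + intercept`.  Poisson
#' fits use [stats::glm()]; NB2 fits use [MASS::glm.nb()] and report the
#' dispersion as `phi = 1/theta`.  When the NB2 dispersion is unidentified
#' (e.g. all-zero counts) a Poisson-degenerate fit is returned with a
#' warning.
#'
#' @param count nonnegative integer counts.
#' @param exposure positive exposures.
#' @param family `"poisson"` or `"nb2"`.
#' @param t optional bin time label carried into the result.
#' @return Object of class `"bin_glm"`: list with `t`, `family`, `intercept`
#'   (log rate per unit exposure), `dispersion` (`NA` for Poisson),
#'   `loglik`, `n`, `k` (free parameters: 1 Poisson, 2 NB2), `aic`, `bic`,
#'   `mu` (fitted means), `count`, `exposure`, `converged`.
#' @export
fit_bin_glm <- function(count, exposure, family = c("poisson", "nb2"),
                        t = NA_real_) {
  family <- match.arg(family)
  if (any(count < 0 | count != round(count)))
    stop("counts must be nonnegative integers")
  if (any(exposure <= 0)) stop("exposures must be positive")
  n <- length(count)
  off <- log(exposure)
  converged <- TRUE
  dispersion <- NA_real_

  if (family == "poisson") {
    fit <- suppressWarnings(
      stats::glm(count ~ 1 + offset(off), family = stats::poisson()))
    intercept <- unname(stats::coef(fit)[1L])
    converged <- fit$converged
    k <- 1L
  } else {
    nb <- tryCatch(
      suppressWarnings(MASS::glm.nb(count ~ 1 + offset(off))),
      error = function(e) NULL)
    if (is.null(nb) || !is.finite(nb$theta) || nb$theta <= 0) {
      warning("NB2 dispersion unidentified in this bin; ",
              "returning Poisson-degenerate fit")
      return(fit_bin_glm(count, exposure, "poisson", t = t))
    }
    intercept <- unname(stats::coef(nb)[1L])
    dispersion <- 1 / nb$theta
    converged <- nb$converged
    k <- 2L
  }

  mu <- exp(off + intercept)
  loglik <- if (family == "poisson") sum(stats::dpois(count, mu, log = TRUE))
            else sum(dnb2(count, mu, dispersion, log = TRUE))
  structure(list(t = t, family = family, intercept = intercept,
                 dispersion = dispersion, loglik = loglik, n = n, k = k,
                 aic = -2 * loglik + 2 * k, bic = -2 * loglik + k * log(n),
                 mu = mu, count = count, exposure = exposure,
                 converged = converged),
            class = "bin_glm")
}

#' Pearson goodness-of-fit statistic of a bin fit
#'
#' \eqn{X^2 = \sum_i (y_i - \hat\mu_i)^2 / V(\hat\mu_i)} with the
#' model-implied variance function, compared against `df = n - k`.  Under a
#' correctly specified model the ratio is near one; a Poisson fit to
#' overdispersed counts inflates it.
#'
#' @param fit a [fit_bin_glm()] result.
#' @return List with `statistic` and `df`.
#' @export
pearson_statistic <- function(fit) {
  stopifnot(inherits(fit, "bin_glm"))
  spec <- if (fit$family == "poisson") count_family("poisson")
          else count_family("nb2", fit$dispersion)
  v <- count_variance(fit$mu, spec)
  list(statistic = sum((fit$count - fit$mu)^2 / v), df = fit$n - fit$k)
}

#' Marginal Kullback--Leibler divergence of a bin fit
#'
#' Divergence of the bin's empirical count distribution \eqn{\hat p} from the
#' model-implied marginal \eqn{q(y) = n^{-1}\sum_i p(y; \hat\mu_i, \hat\phi)},
#' which averages the fitted pmf over the bin's record-level exposures.  The
#' support runs from 0 to the maximum observed count and is extended until
#' the model marginal's cumulative mass exceeds `1 - 1e-9`; `q` is floored at
#' `1e-300` (with a warning) should an observed count receive zero mass.
#'
#' @param fit a [fit_bin_glm()] result.
#' @return Nonnegative divergence (nats); zero iff the distributions agree on
#'   the support.
#' @export
marginal_kld <- function(fit) {
  stopifnot(inherits(fit, "bin_glm"))
  y <- fit$count
  y_max <- max(y)
  pmf_at <- function(yy) {
    if (fit$family == "poisson")
      mean(stats::dpois(yy, fit$mu))
    else
      mean(dnb2(yy, fit$mu, fit$dispersion))
  }
  support <- 0:y_max
  q <- vapply(support, pmf_at, numeric(1))
  cum <- sum(q)
  yy <- y_max
  while (cum < 1 - 1e-9 && yy < y_max + 100000L) {
    yy <- yy + 1L
    cum <- cum + pmf_at(yy)
  }
  phat <- tabulate(y + 1L, nbins = y_max + 1L) / length(y)
  obs <- phat > 0
  qo <- q[obs]
  if (any(qo <= 0)) {
    warning("model marginal assigns zero mass to an observed count; flooring")
    qo <- pmax(qo, 1e-300)
  }
  sum(phat[obs] * (log(phat[obs]) - log(qo)))
}

#' Fit the Poisson/NB2 battery across age bins
#'
#' Fits each requested family to every bin via [fit_bin_glm()] and collects
#' the selection diagnostics: log-likelihood, AIC, BIC, Pearson statistic and
#' degrees of freedom, and marginal KLD.
#'
#' @param binned a [bin_counts()] data frame (columns `t`, `count`,
#'   `exposure`).
#' @param families character subset of `c("poisson", "nb2")`.
#' @param min_n smallest bin size to fit (default 5); smaller bins are
#'   skipped with a warning.
#' @return Data frame of class `"bin_fits"`, one row per (bin, family).
#' @seealso [select_count_family()]
#' @export
fit_bins <- function(binned, families = c("poisson", "nb2"), min_n = 5L) {
  stopifnot(all(c("t", "count", "exposure") %in% names(binned)))
  families <- match.arg(families, c("poisson", "nb2"), several.ok = TRUE)
  ts <- sort(unique(binned$t))
  rows <- list()
  for (tw in ts) {
    sel <- binned$t == tw
    if (sum(sel) < min_n) {
      warning("bin t = ", tw, " has fewer than ", min_n, " records; skipped")
      next
    }
    for (fam in families) {
      f <- fit_bin_glm(binned$count[sel], binned$exposure[sel], fam, t = tw)
      ps <- pearson_statistic(f)
      rows[[length(rows) + 1L]] <- data.frame(
        t = tw, family = f$family, n = f$n, k = f$k,
        intercept = f$intercept, dispersion = f$dispersion,
        loglik = f$loglik, aic = f$aic, bic = f$bic,
        pearson = ps$statistic, df = ps$df, kld = marginal_kld(f),
        converged = f$converged)
    }
  }
  if (!length(rows)) stop("no bin was large enough to fit")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("bin_fits", "data.frame")
  out
}

#' Measurement-model selection report
#'
#' Compares paired Poisson and NB2 bin fits on the four-part battery: KLD,
#' Pearson-to-df alignment, AIC, and BIC.  The NB2 family is recommended
#' when it wins on a majority of bins by AIC and its Pearson/df ratio is
#' closer to one on a majority of bins.
#'
#' @param binfits a [fit_bins()] result containing both families.
#' @return List of class `"family_selection"`: `per_bin` (wide comparison
#'   table), `share_nb2_aic`, `share_nb2_bic`, `share_nb2_kld`,
#'   `share_nb2_pearson` (fractions of bins where NB2 wins each criterion),
#'   and `recommendation`.
#' @export
select_count_family <- function(binfits) {
  stopifnot(inherits(binfits, "data.frame"))
  if (!nrow(binfits)) stop("empty bin-fit table")
  po <- binfits[binfits$family == "poisson", ]
  nb <- binfits[binfits$family == "nb2", ]
  ts <- intersect(po$t, nb$t)
  skipped <- setdiff(unique(binfits$t), ts)
  if (length(skipped))
    warning("bin(s) without a complete Poisson/NB2 pair skipped: ",
            paste(skipped, collapse = ", "))
  if (!length(ts)) stop("no bin has both family fits")
  po <- po[match(ts, po$t), ]
  nb <- nb[match(ts, nb$t), ]
  per_bin <- data.frame(
    t = ts, n = po$n,
    aic_poisson = po$aic, aic_nb2 = nb$aic,
    bic_poisson = po$bic, bic_nb2 = nb$bic,
    kld_poisson = po$kld, kld_nb2 = nb$kld,
    pearson_ratio_poisson = po$pearson / po$df,
    pearson_ratio_nb2 = nb$pearson / nb$df,
    dispersion_nb2 = nb$dispersion)
  share <- function(x) mean(x)
  res <- list(
    per_bin = per_bin,
    share_nb2_aic = share(per_bin$aic_nb2 < per_bin$aic_poisson),
    share_nb2_bic = share(per_bin$bic_nb2 < per_bin$bic_poisson),
    share_nb2_kld = share(per_bin$kld_nb2 < per_bin$kld_poisson),
    share_nb2_pearson = share(abs(per_bin$pearson_ratio_nb2 - 1) <
                                abs(per_bin$pearson_ratio_poisson - 1)))
  res$recommendation <-
    if (res$share_nb2_aic > 0.5 && res$share_nb2_pearson > 0.5) "nb2"
    else "poisson"
  class(res) <- "family_selection"
  res
}

#' @export
print.family_selection <- function(x, digits = 3, ...) {
  cat("Measurement-model selection across", nrow(x$per_bin), "bins\n")
  cat(sprintf("  NB2 wins AIC in %.0f%%, BIC in %.0f%%, KLD in %.0f%% of bins\n",
              100 * x$share_nb2_aic, 100 * x$share_nb2_bic,
              100 * x$share_nb2_kld))
  cat(sprintf("  NB2 Pearson/df closer to 1 in %.0f%% of bins\n",
              100 * x$share_nb2_pearson))
  cat("  recommendation:", x$recommendation, "\n")
  invisible(x)
}
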