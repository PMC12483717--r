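#' Default generating truth for simulations
#'
#' A qualitatively realistic parameter set for an early-childhood
#' language-sample design: about 3 events per 1,000 sampled units at the
#' 18-month origin, rapid growth (0.25/month on the log scale) up to a
#' changepoint 10 months after the origin (28 months of age), a flat second
#' phase, dispersion decaying from 2.5 toward an asymptote of 0.2, and
#' modest independent random variation in all four growth parameters.
#'
#' @return An [slcm_params()] object.
#' @export
default_truth <- function() {
  slcm_params(growth_params(-5.8, 0.25, 0, 10),
              T = diag(c(0.2, 0.005, 0.002, 4)),
              dispersion = dispersion_trajectory("expdecay", c(2.5, 0.9, 0.2)))
}

#' Design of a synthetic accelerated longitudinal count study
#'
#' Describes the sampling frame the generator emulates: N individuals each
#' contribute a small number of assessments at 3-month bins over ages
#' 18--72 months (bins drawn uniformly without replacement, i.e. missing
#' completely at random), with exposures at least 25 sampled units drawn
#' from a shifted negative binomial unrelated to age.
#'
#' @param N number of individuals.
#' @param n_assessments integer vector: possible assessments per individual,
#'   drawn uniformly (default 2--5).
#' @param bin_times available bin times, months since origin (default
#'   `seq(0, 51, 3)`).
#' @param exposure_mean,exposure_size mean and size of the shifted negative
#'   binomial exposure distribution.
#' @param exposure_min exposure floor (default 25).
#' @param truth an [slcm_params()] generating truth; [default_truth()] by
#'   default.
#' @param origin age (months) mapped to time 0.
#' @param jitter_ages emit continuous ages jittered uniformly within each
#'   3-month bin (exercises the binning pathway) instead of bin lower
#'   bounds?
#' @return List of class `"sim_design"`.
#' @export
sim_design <- function(N = 300L, n_assessments = 2:5,
                       bin_times = seq(0, 51, by = 3),
                       exposure_mean = 120, exposure_size = 2,
                       exposure_min = 25, truth = default_truth(),
                       origin = 18, jitter_ages = FALSE) {
  stopifnot(inherits(truth, "slcm_params"), N >= 1,
            all(n_assessments >= 1), all(n_assessments <= length(bin_times)),
            exposure_min >= 1, exposure_mean > exposure_min)
  structure(list(N = as.integer(N), n_assessments = as.integer(n_assessments),
                 bin_times = bin_times, exposure_mean = exposure_mean,
                 exposure_size = exposure_size,
                 exposure_min = as.integer(exposure_min), truth = truth,
                 origin = origin, jitter_ages = isTRUE(jitter_ages)),
            class = "sim_design")
}

#' Simulate a longitudinal count dataset from the SLCM
#'
#' Generates data exactly under the fitted model's assumptions: per
#' individual, attended bins are drawn uniformly without replacement,
#' exposures from the design's shifted negative binomial, random effects
#' from `N(0, T)`, and counts from NB2 with
#' `mu = exposure * exp(f(t; fixed) + Lambda(t) b_i)` and `phi` from the
#' truth's dispersion trajectory.  Fully reproducible given `seed`.
#'
#' @param design a [sim_design()].
#' @param seed optional integer passed to [set.seed()].
#' @return Long-format data frame (`id`, `age_months`, `count`, `exposure`)
#'   with the generating `truth` and `design` attached as attributes.
#' @export
simulate_slcm_data <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(seed)) set.seed(seed)
  truth <- design$truth
  fx <- truth$fixed
  d <- length(truth$random)
  n_i <- sample(design$n_assessments, design$N, replace = TRUE)
  total <- sum(n_i)
  id <- rep(seq_len(design$N), n_i)
  t <- unlist(lapply(n_i, function(m)
    sort(sample(design$bin_times, m, replace = FALSE))))
  u <- design$exposure_min +
    stats::rnbinom(total, size = design$exposure_size,
                   mu = design$exposure_mean - design$exposure_min)
  b <- .rmvnorm0(design$N, truth$T)
  B <- growth_basis(t, fx, random = truth$random)
  eta <- log(u) + growth_value(t, fx) + rowSums(B * b[id, , drop = FALSE])
  phi <- .phi_at(truth, t)
  y <- rnb2(total, exp(eta), phi)
  age <- design$origin + t +
    if (design$jitter_ages) stats::runif(total, 0, 3) else 0
  out <- data.frame(id = id, age_months = age, count = y, exposure = u)
  attr(out, "truth") <- truth
  attr(out, "design") <- design
  class(out) <- c("slcm_sim", "data.frame")
  out
}

#' Parameter-recovery study
#'
#' Repeatedly simulates from a generating truth, fits the SLCM to each
#' replicate, and tabulates bias, RMSE, and confidence-interval coverage of
#' the fixed growth effects.  Replicates whose optimizer fails to converge
#' are recorded and excluded from the summaries.
#'
#' @param design a [sim_design()] (its `truth` is the estimand).
#' @param n_reps number of replicates (>= 2).
#' @param seed base seed; replicate `r` uses `seed + r`.
#' @param level confidence level for coverage (default 0.95).
#' @param quad,control passed to [slcm()].
#' @param ... further arguments to [slcm()] (e.g. `dispersion`,
#'   `re_structure`).
#' @return List of class `"recovery_study"`: `per_rep` (replicate, parameter,
#'   estimate, SE, CI cover flag), `summary` (per parameter: truth, mean
#'   estimate, bias, RMSE, coverage), `n_failed`.
#' @export
recovery_study <- function(design, n_reps, seed = 1L, level = 0.95,
                           quad = slcm_quad(), control = slcm_control(),
                           ...) {
  stopifnot(inherits(design, "sim_design"))
  n_reps <- as.integer(n_reps)
  if (n_reps < 2L) stop("n_reps must be >= 2")
  truth <- design$truth
  tr <- c(intercept = truth$fixed[["intercept"]],
          slope1 = truth$fixed[["slope1"]],
          slope2 = truth$fixed[["slope2"]],
          changepoint = truth$fixed[["changepoint"]])
  zc <- stats::qnorm(1 - (1 - level) / 2)
  rows <- list()
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    dat <- simulate_slcm_data(design, seed = seed + r)
    fit <- tryCatch(
      suppressWarnings(slcm(dat, quad = quad, control = control, ...)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1L
      next
    }
    est <- coef(fit)
    se <- tryCatch(robust_se(fit)[names(tr)], error = function(e)
      rep(NA_real_, 4))
    rows[[length(rows) + 1L]] <- data.frame(
      rep = r, param = names(tr), truth = unname(tr),
      estimate = unname(est[names(tr)]), se = unname(se),
      cover = abs(unname(est[names(tr)]) - unname(tr)) <= zc * unname(se))
  }
  if (!length(rows)) stop("no replicate converged")
  per_rep <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(split(per_rep, per_rep$param), function(g) {
    data.frame(param = g$param[1], truth = g$truth[1],
               mean_estimate = mean(g$estimate),
               bias = mean(g$estimate) - g$truth[1],
               empirical_sd = stats::sd(g$estimate),
               rmse = sqrt(mean((g$estimate - g$truth[1])^2)),
               coverage = mean(g$cover, na.rm = TRUE),
               n = nrow(g))
  }))
  rownames(smry) <- NULL
  structure(list(per_rep = per_rep, summary = smry, n_failed = n_failed,
                 level = level),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, digits = 4, ...) {
  cat("Parameter recovery over", max(x$per_rep$rep), "replicates (",
      x$n_failed, "failed )\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}
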