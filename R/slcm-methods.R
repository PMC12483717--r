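#' Identification counting for the count SLCM
#'
#' The model is a confirmatory factor model with a mean structure: the mean
#' structure offers `W` observations (one per unique occasion) against the
#' freely estimated population growth parameters, and the covariance
#' structure offers `W(W+1)/2` observations against the unique free elements
#' of the random-effect covariance `T` plus the free dispersion parameters.
#' Each structure must be overidentified for the model as a whole to be
#' overidentified.
#'
#' @param n_growth_means number of freely estimated population growth
#'   parameters (4 for the continuity-constrained linear--linear model).
#' @param random growth parameters carrying random effects.
#' @param re_structure `"diagonal"` or `"full"`.
#' @param dispersion `"expdecay"` (3 parameters), `"loglinear"` (2), or
#'   `"free"` (`W`).
#' @param W number of unique measurement occasions.
#' @return List of class `"slcm_identification"` with the parameter counts,
#'   the available observations, and `"overidentified"` /
#'   `"just-identified"` / `"underidentified"` status per structure and
#'   overall.
#' @examples
#' slcm_identification(W = 18)  # mean: 4 of 18; covariance: 13 of 171
#' @export
slcm_identification <- function(n_growth_means = 4L,
                                random = c("intercept", "slope1", "slope2",
                                           "changepoint"),
                                re_structure = c("full", "diagonal"),
                                dispersion = c("expdecay", "loglinear",
                                               "free"),
                                W) {
  re_structure <- match.arg(re_structure)
  dispersion <- match.arg(dispersion)
  random <- match.arg(random, several.ok = TRUE)
  W <- as.integer(W)
  if (W < 1L) stop("W must be >= 1")
  d <- length(random)
  n_T <- if (re_structure == "full") (d * (d + 1L)) %/% 2L else d
  n_disp <- .disp_dim(dispersion, W)
  p_mean <- as.integer(n_growth_means)
  p_cov <- n_T + n_disp
  obs_mean <- W
  obs_cov <- (W * (W + 1L)) %/% 2L
  status <- function(obs, p)
    if (obs > p) "overidentified" else if (obs == p) "just-identified"
    else "underidentified"
  mean_status <- status(obs_mean, p_mean)
  cov_status <- status(obs_cov, p_cov)
  overall <- if (mean_status == "underidentified" ||
                 cov_status == "underidentified") "underidentified"
             else if (mean_status == "overidentified" &&
                      cov_status == "overidentified") "overidentified"
             else "just-identified"
  structure(list(p_mean = p_mean, p_cov = p_cov, n_T = n_T, n_disp = n_disp,
                 obs_mean = obs_mean, obs_cov = obs_cov, W = W,
                 mean_structure = mean_status, covariance_structure = cov_status,
                 overall = overall),
            class = "slcm_identification")
}

#' @export
print.slcm_identification <- function(x, ...) {
  cat("Identification (W =", x$W, "occasions)\n")
  cat(sprintf("  mean structure:       %d free parameters vs %d observations (%s)\n",
              x$p_mean, x$obs_mean, x$mean_structure))
  cat(sprintf("  covariance structure: %d free parameters (%d in T + %d dispersion) vs %d observations (%s)\n",
              x$p_cov, x$n_T, x$n_disp, x$obs_cov, x$covariance_structure))
  cat("  overall:", x$overall, "\n")
  invisible(x)
}

#' @rdname slcm_identification
#' @param object a fitted [slcm()] model.
#' @export
identification <- function(object) UseMethod("identification")

#' @export
identification.slcm <- function(object) object$identification

# ---------------------------------------------------------------------------
# variance estimation
# ---------------------------------------------------------------------------

# natural-scale parameter vector used for reporting
.natural_names <- function(pm) {
  d <- pm$d
  nmT <- if (d == 0L) character(0)
         else if (pm$re_structure == "diagonal") paste0("var_", pm$random)
         else {
    lt <- which(lower.tri(diag(d), diag = TRUE), arr.ind = TRUE)
    ifelse(lt[, 1] == lt[, 2], paste0("var_", pm$random[lt[, 1]]),
           paste0("cov_", pm$random[lt[, 1]], ".", pm$random[lt[, 2]]))
  }
  nmD <- switch(pm$disp_form,
                expdecay = c("disp_level", "disp_decay", "disp_asymptote"),
                loglinear = c("disp_log_level", "disp_log_slope"),
                free = paste0("phi_", seq_len(pm$W)))
  c("intercept", "slope1", "slope2", "changepoint", nmT, nmD)
}

.natural_from_internal <- function(th, pm, tvals) {
  up <- .unpack(th, pm, tvals)
  d <- pm$d
  natT <- if (d == 0L) numeric(0)
          else if (pm$re_structure == "diagonal") diag(up$Tmat)
          else up$Tmat[lower.tri(up$Tmat, diag = TRUE)]
  natD <- switch(pm$disp_form,
                 expdecay = unname(up$traj$coeffs),
                 loglinear = unname(up$traj$coeffs),
                 free = unname(up$phi_w))
  stats::setNames(c(up$fixed[["intercept"]], up$fixed[["slope1"]],
                    up$fixed[["slope2"]], up$gamma, natT, natD),
                  .natural_names(pm))
}

# numerical jacobian of the internal -> natural map (central differences)
.jac_nat <- function(th, pm, tvals) {
  f0 <- .natural_from_internal(th, pm, tvals)
  p <- length(th)
  J <- matrix(0, length(f0), p)
  for (j in seq_len(p)) {
    h <- 1e-6 * max(1, abs(th[j]))
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    J[, j] <- (.natural_from_internal(tp, pm, tvals) -
                 .natural_from_internal(tm, pm, tvals)) / (2 * h)
  }
  dimnames(J) <- list(names(f0), pm$names)
  J
}

# observed information and cluster-robust sandwich on the natural scale
.slcm_vcov_build <- function(fit, nodes_tab = NULL) {
  pm <- fit$parmap
  layout <- fit$layout
  th <- fit$theta_internal
  if (is.null(nodes_tab)) nodes_tab <- .node_tables(fit$quad, max(pm$d, 1L))

  grad_int <- function(tht) {
    up <- .unpack(tht, pm, layout$tvals)
    par <- .params_from_unpack(up, pm)
    res <- .slcm_kernel(layout, par, fit$quad, want_grad = TRUE,
                        nodes_tab = nodes_tab)
    raw <- c(res$grad_beta, as.numeric(res$grad_L), res$grad_phi)
    drop(.chain_matrix(tht, pm, up) %*% raw)
  }
  p <- length(th)
  # observed information = -Hessian of the log-likelihood, by central
  # differences of the analytic gradient
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    h <- 1e-5 * max(1, abs(th[j]))
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    H[, j] <- -(grad_int(tp) - grad_int(tm)) / (2 * h)
  }
  H <- (H + t(H)) / 2

  # per-individual scores at the optimum (analytic), chained to internal scale
  up <- .unpack(th, pm, layout$tvals)
  par <- .params_from_unpack(up, pm)
  res <- .slcm_kernel(layout, par, fit$quad, want_grad = TRUE,
                      want_scores = TRUE, nodes_tab = nodes_tab)
  Cmat <- .chain_matrix(th, pm, up)
  S <- res$scores %*% t(Cmat)              # N x p
  meat <- crossprod(S)

  inv_or_pinv <- function(M) {
    out <- tryCatch(solve(M), error = function(e) NULL)
    if (is.null(out)) {
      warning("information matrix is singular; using a pseudo-inverse")
      e <- eigen(M, symmetric = TRUE)
      pos <- e$values > max(e$values, 0) * 1e-10
      out <- e$vectors[, pos, drop = FALSE] %*%
        (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
    }
    out
  }
  bread <- inv_or_pinv(H)
  V_model_int <- bread
  V_robust_int <- bread %*% meat %*% bread

  J <- .jac_nat(th, pm, layout$tvals)
  V_model <- J %*% V_model_int %*% t(J)
  V_robust <- J %*% V_robust_int %*% t(J)
  nm <- rownames(J)
  dimnames(V_model) <- dimnames(V_robust) <- list(nm, nm)
  list(model = V_model, robust = V_robust, score_norm = sqrt(sum(colSums(S)^2)),
       scores = S, information = H)
}

#' @export
coef.slcm <- function(object, ...) object$coefficients

#' Variance--covariance matrix of a fitted count SLCM
#'
#' @param object a fitted [slcm()] model.
#' @param type `"robust"` for the cluster-robust sandwich (observed
#'   information bread, per-individual score outer-product meat) or
#'   `"model"` for the inverse observed information.
#' @param ... unused.
#' @return Covariance matrix on the natural parameter scale (growth fixed
#'   effects, `T` elements, dispersion coefficients).
#' @export
vcov.slcm <- function(object, type = c("robust", "model"), ...) {
  type <- match.arg(type)
  if (is.null(object$vcov))
    stop("fit was run with se = FALSE; refit with slcm_control(se = TRUE)")
  object$vcov[[type]]
}

#' Cluster-robust standard errors of a fitted count SLCM
#'
#' @inheritParams vcov.slcm
#' @return Named vector of standard errors on the natural scale.
#' @export
robust_se <- function(object, type = c("robust", "model")) {
  type <- match.arg(type)
  v <- diag(vcov.slcm(object, type = type))
  sqrt(pmax(v, 0))
}

#' @export
logLik.slcm <- function(object, ...) {
  structure(object$loglik, df = object$n_par,
            nobs = object$n_individuals, class = "logLik")
}

#' @export
print.slcm <- function(x, digits = 4, ...) {
  cat("Structured latent curve model for counts (NB2, linear-linear)\n")
  cat("  ", x$n_individuals, " individuals, ", x$n_obs, " observations, ",
      x$W, " occasions\n", sep = "")
  cat("  log-likelihood ", format(x$loglik, digits = 8),
      "  AIC ", format(x$aic, digits = 8),
      "  BIC ", format(x$bic, digits = 8), "\n", sep = "")
  cat("Fixed effects:\n")
  print(round(x$coefficients, digits))
  cat("Changepoint age:", round(x$coefficients[["changepoint"]] + x$origin,
                                2), "months\n")
  if (!x$converged) cat("NOTE: optimizer did not converge\n")
  invisible(x)
}

#' Summary of a fitted count SLCM
#'
#' @param object a fitted [slcm()] model.
#' @param se_type `"robust"` (default) or `"model"` standard errors.
#' @param ... unused.
#' @return Object of class `"summary.slcm"`.
#' @export
summary.slcm <- function(object, se_type = c("robust", "model"), ...) {
  se_type <- match.arg(se_type)
  est <- .natural_from_internal(object$theta_internal, object$parmap,
                                object$layout$tvals)
  tab <- data.frame(estimate = est)
  if (!is.null(object$vcov)) {
    se <- robust_se(object, se_type)
    tab$se <- se[rownames(tab)]
    tab$z <- tab$estimate / tab$se
    tab$p <- 2 * stats::pnorm(-abs(tab$z))
  }
  structure(list(fit = object, table = tab, se_type = se_type),
            class = "summary.slcm")
}

#' @export
print.summary.slcm <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nParameter estimates (", x$se_type, " SEs):\n", sep = "")
  print(round(x$table, digits))
  cat("\nRandom-effect covariance T:\n")
  print(round(x$fit$T, digits))
  cat("\n")
  print(x$fit$identification)
  invisible(x)
}

#' Empirical-Bayes random effects
#'
#' Posterior modes of each individual's random-effect vector given the data
#' and the fitted population parameters, with Laplace posterior standard
#' deviations.  These are the quantities that center the adaptive quadrature
#' and generate individual fitted trajectories.
#'
#' @param object a fitted [slcm()] model.
#' @param ... unused.
#' @return Data frame: `id`, one column per random effect (posterior mode),
#'   and `sd_*` columns (posterior standard deviations).
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @export
ranef.slcm <- function(object, ...) object$eb

#' Population and individual fitted curves
#'
#' For `level = "population"`, expected counts per `per_exposure` sampled
#' units along the population average trajectory,
#' `per_exposure * exp(f(t))`.  For `level = "individual"`, each requested
#' individual's empirical-Bayes fitted curve
#' `per_exposure * exp(f(t) + Lambda(t) b_i)`.
#'
#' @param object a fitted [slcm()] model.
#' @param times times (months since origin); default the observed occasions.
#' @param per_exposure exposure at which to state expected counts
#'   (default 1000 sampled units).
#' @param level `"population"` or `"individual"`.
#' @param ids individuals to predict for (default all).
#' @param ... unused.
#' @return Data frame with `t`, `age_months`, and `expected` (population) or
#'   one row per (id, t) (individual).
#' @export
predict.slcm <- function(object, times = NULL, per_exposure = 1000,
                         level = c("population", "individual"), ids = NULL,
                         ...) {
  level <- match.arg(level)
  if (is.null(times)) times <- object$times
  gp <- growth_params(object$coefficients[["intercept"]],
                      object$coefficients[["slope1"]],
                      object$coefficients[["slope2"]],
                      object$coefficients[["changepoint"]])
  f <- growth_value(times, gp)
  if (level == "population")
    return(data.frame(t = times, age_months = times + object$origin,
                      expected = per_exposure * exp(f)))
  eb <- object$eb
  if (!is.null(ids)) eb <- eb[eb$id %in% ids, , drop = FALSE]
  B <- growth_basis(times, gp, random = object$random)
  out <- do.call(rbind, lapply(seq_len(nrow(eb)), function(i) {
    b <- as.numeric(eb[i, object$random])
    data.frame(id = eb$id[i], t = times, age_months = times + object$origin,
               expected = per_exposure * exp(f + drop(B %*% b)))
  }))
  rownames(out) <- NULL
  out
}

#' Population average curve with changepoint age
#'
#' Convenience wrapper around [predict.slcm()] that also reports the shifted
#' changepoint in chronological months.
#'
#' @inheritParams predict.slcm
#' @return List with `curve` (data frame) and `changepoint_age` (months).
#' @export
population_curve <- function(object, times = NULL, per_exposure = 1000) {
  stopifnot(inherits(object, "slcm"))
  list(curve = predict(object, times = times, per_exposure = per_exposure),
       changepoint_age = object$coefficients[["changepoint"]] + object$origin)
}

#' @export
fitted.slcm <- function(object, ...) {
  df <- object$layout$df
  gp <- growth_params(object$coefficients[["intercept"]],
                      object$coefficients[["slope1"]],
                      object$coefficients[["slope2"]],
                      object$coefficients[["changepoint"]])
  f <- growth_value(df$t, gp)
  B <- growth_basis(df$t, gp, random = object$random)
  eb <- object$eb
  bmat <- as.matrix(eb[match(df$id, eb$id), object$random, drop = FALSE])
  exp(log(df$exposure) + f + rowSums(B * bmat))
}

#' @export
residuals.slcm <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  df <- object$layout$df
  mu <- fitted(object)
  if (type == "response") return(df$count - mu)
  phi <- .phi_at(list(dispersion = object$dispersion), df$t)
  (df$count - mu) / sqrt(mu + phi * mu^2)
}

#' Simulate count responses from a fitted model
#'
#' Draws new response vectors from the fitted SLCM at the observed design
#' (same individuals, occasions and exposures): new random effects from
#' `N(0, T)`, then NB2 counts along the implied individual trajectories.
#'
#' @param object a fitted [slcm()] model.
#' @param nsim number of simulated response vectors.
#' @param seed optional seed passed to [set.seed()].
#' @param ... unused.
#' @return Data frame with one column per simulation, rows aligned with
#'   `object$layout$df`.
#' @export
simulate.slcm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  df <- object$layout$df
  gp <- growth_params(object$coefficients[["intercept"]],
                      object$coefficients[["slope1"]],
                      object$coefficients[["slope2"]],
                      object$coefficients[["changepoint"]])
  f <- growth_value(df$t, gp)
  B <- growth_basis(df$t, gp, random = object$random)
  phi <- .phi_at(list(dispersion = object$dispersion), df$t)
  ids <- object$layout$ids
  out <- as.data.frame(matrix(0L, nrow(df), nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  for (s in seq_len(nsim)) {
    b <- .rmvnorm0(length(ids), object$T)
    bmat <- b[match(df$id, ids), , drop = FALSE]
    mu <- exp(log(df$exposure) + f + rowSums(B * bmat))
    out[[s]] <- rnb2(nrow(df), mu, phi)
  }
  out
}

#' Plot a fitted count SLCM
#'
#' Observed bin-level rates (total count over total exposure, scaled to
#' `per_exposure`) with the fitted population average curve and the
#' changepoint marked.
#'
#' @param x a fitted [slcm()] model.
#' @param per_exposure exposure scale for the y axis.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the plotted curve data frame.
#' @export
plot.slcm <- function(x, per_exposure = 1000, ...) {
  df <- x$layout$df
  tv <- x$times
  obs <- vapply(tv, function(tw) {
    sel <- df$t == tw
    per_exposure * sum(df$count[sel]) / sum(df$exposure[sel])
  }, numeric(1))
  tt <- seq(min(tv), max(tv), length.out = 200)
  crv <- predict(x, times = tt, per_exposure = per_exposure)
  graphics::plot(tv + x$origin, obs, xlab = "age (months)",
                 ylab = paste("expected count per", per_exposure),
                 pch = 16, ...)
  graphics::lines(crv$age_months, crv$expected, lwd = 2)
  graphics::abline(v = x$coefficients[["changepoint"]] + x$origin, lty = 2)
  invisible(crv)
}

#' Classify individuals against the population average
#'
#' Uses the empirical-Bayes effects to flag each individual's entry level
#' (intercept effect) and initial-phase growth (first-slope effect) as above
#' or below the population average, with exact zeros reported separately as
#' ties, and cross-tabulates the joint classes.
#'
#' @param object a fitted [slcm()] model with random effects on `intercept`
#'   and `slope1`.
#' @return List of class `"slcm_classification"`: `per_individual` (id,
#'   entry, growth), `table` (counts), `percent` (percentages summing to
#'   100), `n`.
#' @export
compare_to_average <- function(object) {
  stopifnot(inherits(object, "slcm"))
  need <- c("intercept", "slope1")
  if (!all(need %in% object$random))
    stop("classification needs random effects on intercept and slope1")
  eb <- object$eb
  cls <- function(v) factor(ifelse(v > 0, "above", ifelse(v < 0, "below",
                                                          "at average")),
                            levels = c("above", "below", "at average"))
  per <- data.frame(id = eb$id, entry = cls(eb$intercept),
                    growth = cls(eb$slope1))
  tab <- table(entry = per$entry, growth = per$growth)
  structure(list(per_individual = per, table = tab,
                 percent = 100 * prop.table(tab), n = nrow(per)),
            class = "slcm_classification")
}

#' @export
print.slcm_classification <- function(x, ...) {
  cat("Entry level x phase-1 growth relative to the population average\n")
  cat("(", x$n, "individuals; counts, with percentages)\n\n")
  print(x$table)
  cat("\n")
  print(round(x$percent, 2))
  invisible(x)
}
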