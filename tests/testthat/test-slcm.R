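test_that("linear predictor honors the exposure-offset contract", {
  p <- growth_params(-5.8, 0.25, 0, 10)
  expect_equal(linear_predictor(0, 1, p), -5.8)
  expect_equal(linear_predictor(6, 200, p) - linear_predictor(6, 100, p),
               log(2), tolerance = 1e-12)
  # rate-per-1000 arithmetic
  expect_equal(exp(linear_predictor(0, 1000, p)), 1000 * exp(-5.8))
  expect_error(linear_predictor(0, 0, p), "positive")
})

test_that("marginal likelihood degenerates correctly and is invariant to
           record order", {
  b <- small_binned(N = 25, seed = 41)
  # T = 0: the integral collapses to the fixed-effects likelihood
  tr0 <- truth_no_re()
  ml <- slcm_marginal_loglik(b, tr0)
  f <- growth_value(b$t, tr0$fixed)
  phi <- dispersion_at(tr0$dispersion, b$t)
  direct <- sum(dnb2(b$count, b$exposure * exp(f), phi, log = TRUE))
  expect_equal(ml$loglik, direct, tolerance = 1e-9)

  # reordering rows changes nothing
  tr <- test_truth()
  ml1 <- slcm_marginal_loglik(b, tr)
  set.seed(1)
  ml2 <- slcm_marginal_loglik(b[sample(nrow(b)), ], tr)
  expect_equal(ml1$loglik, ml2$loglik, tolerance = 1e-10)
})

test_that("one-dimensional adaptive quadrature matches a dense-grid
           integral", {
  b <- data.frame(id = 1, t = 9, count = 4, exposure = 120)
  tau2 <- 0.4
  par <- slcm_params(growth_params(-5.8, 0.25, 0, 10),
                     T = matrix(tau2, 1, 1),
                     dispersion = dispersion_trajectory("expdecay",
                                                        c(2.5, 0.9, 0.2)),
                     random = "intercept")
  agh <- slcm_marginal_loglik(b, par, slcm_quad(nodes = 15))$loglik
  # brute-force trapezoid over b in [-10 sd, 10 sd]
  f <- growth_value(b$t, par$fixed)
  phi <- dispersion_at(par$dispersion, b$t)
  bb <- seq(-10, 10, length.out = 1e5) * sqrt(tau2)
  lw <- dnb2(b$count, b$exposure * exp(f + bb), phi, log = TRUE) +
    dnorm(bb, 0, sqrt(tau2), log = TRUE)
  M <- max(lw)
  dense <- M + log(sum(exp(lw - M)) * (bb[2] - bb[1]))
  expect_equal(agh, dense, tolerance = 1e-6)
})

test_that("quadrature refinement converges on a multi-dimensional fit", {
  b <- small_binned(N = 40, seed = 42)
  tr <- test_truth()
  ll <- vapply(c(5, 9, 15), function(nq)
    slcm_marginal_loglik(b, tr, slcm_quad(nodes = nq))$loglik, numeric(1))
  expect_lt(abs(ll[2] - ll[3]), abs(ll[1] - ll[3]) + 1e-10)
  expect_lt(abs(ll[2] - ll[3]), 1e-3)
})

test_that("empirical-Bayes effects: degenerate prior, grid oracle, centering", {
  b <- small_binned(N = 20, seed = 43)
  # nearly degenerate prior pins the modes at zero
  par0 <- slcm_params(growth_params(-5.8, 0.25, 0, 10),
                      T = diag(rep(1e-10, 4)),
                      dispersion = dispersion_trajectory("expdecay",
                                                         c(2.5, 0.9, 0.2)))
  eb0 <- slcm_eb(b, par0)
  expect_lt(max(abs(as.matrix(eb0[, 2:5]))), 1e-4)

  # one individual, random intercept: mode matches a dense-grid argmax
  b1 <- data.frame(id = 1, t = c(0, 9, 21), count = c(2, 9, 30),
                   exposure = c(120, 100, 150))
  par1 <- slcm_params(growth_params(-5.8, 0.25, 0, 10),
                      T = matrix(0.3, 1, 1),
                      dispersion = dispersion_trajectory("expdecay",
                                                         c(2.5, 0.9, 0.2)),
                      random = "intercept")
  eb1 <- slcm_eb(b1, par1)
  f <- growth_value(b1$t, par1$fixed)
  phi <- dispersion_at(par1$dispersion, b1$t)
  grid <- seq(-3, 3, by = 1e-5)
  post <- vapply(grid, function(bb)
    sum(dnb2(b1$count, b1$exposure * exp(f + bb), phi, log = TRUE)) +
      dnorm(bb, 0, sqrt(0.3), log = TRUE), numeric(1))
  expect_lt(abs(eb1$intercept[1] - grid[which.max(post)]), 1e-4)

  # an individual lying exactly on the population curve has mode near zero
  mu_pop <- 150 * exp(growth_value(c(0, 9, 21), par1$fixed))
  b2 <- data.frame(id = 1, t = c(0, 9, 21), count = round(mu_pop),
                   exposure = 150)
  # rounding keeps counts integral; with counts at the curve the intercept
  # effect should be small relative to the prior sd
  eb2 <- slcm_eb(b2, par1)
  expect_lt(abs(eb2$intercept[1]), 0.25 * sqrt(0.3))
})

test_that("identification counting reproduces the model's structure", {
  id <- slcm_identification(W = 18)
  expect_equal(id$p_mean, 4L)
  expect_equal(id$n_T, 10L)       # unique elements of an unstructured 4x4 T
  expect_equal(id$p_cov, 13L)     # + 3 exponential-decay coefficients
  expect_equal(id$mean_structure, "overidentified")
  expect_equal(id$covariance_structure, "overidentified")
  expect_equal(id$overall, "overidentified")

  short <- slcm_identification(W = 3)
  expect_equal(short$mean_structure, "underidentified")
  expect_equal(short$overall, "underidentified")

  diag18 <- slcm_identification(re_structure = "diagonal", W = 18)
  expect_equal(diag18$n_T, 4L)
  free_w <- slcm_identification(dispersion = "free", W = 18)
  expect_equal(free_w$n_disp, 18L)
})

test_that("a small fit is self-consistent, nested by dispersion constraint,
           and exposes sane methods", {
  sim <- simulate_slcm_data(sim_design(N = 80), seed = 44)
  fit <- suppressWarnings(slcm(sim, quad = slcm_quad(nodes = 5)))
  expect_s3_class(fit, "slcm")
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_par)
  expect_equal(fit$bic, -2 * fit$loglik + fit$n_par * log(fit$n_individuals))

  # warm restart from the solution stays at the solution
  fit2 <- suppressWarnings(slcm(sim, quad = slcm_quad(nodes = 5), init = fit,
                                control = slcm_control(se = FALSE)))
  expect_lt(abs(fit2$loglik - fit$loglik), 1e-5)

  # the constrained dispersion trajectory cannot beat free dispersions
  fit_free <- suppressWarnings(slcm(sim, dispersion = "free",
                                    quad = slcm_quad(nodes = 5),
                                    control = slcm_control(se = FALSE)))
  expect_lte(fit$loglik, fit_free$loglik + 1e-4)

  # methods
  expect_length(coef(fit), 4L)
  expect_equal(unname(AIC(fit)), fit$aic)
  expect_equal(unname(BIC(fit)), fit$bic)
  se <- robust_se(fit)
  expect_true(all(se[c("intercept", "slope1", "slope2", "changepoint")] > 0))
  # per-individual scores sum to ~0 at the optimum
  gr <- colSums(fit$vcov$scores)
  expect_lt(max(abs(gr)) / max(abs(fit$vcov$scores)), 0.02)
  # model-based and robust SEs agree broadly under correct specification
  sm <- robust_se(fit, "model")[1:4]
  expect_lt(mean(abs(log(se[1:4] / sm))), log(1.6))

  pr <- predict(fit, times = c(0, 24), per_exposure = 1000)
  expect_equal(pr$expected[1], 1000 * exp(coef(fit)[["intercept"]]))
  ind <- predict(fit, times = c(0, 12), level = "individual",
                 ids = fit$eb$id[1:3])
  expect_equal(nrow(ind), 6L)
  expect_true(all(is.finite(residuals(fit))))
  s <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(s), c(fit$n_obs, 2L))
  cls <- compare_to_average(fit)
  expect_equal(sum(cls$table), fit$n_individuals)
  expect_equal(sum(cls$percent), 100, tolerance = 1e-9)
})

test_that("population curve changes slope exactly at the changepoint and is
           monotone for nonnegative slopes", {
  sim <- simulate_slcm_data(sim_design(N = 80), seed = 45)
  fit <- suppressWarnings(slcm(sim, quad = slcm_quad(nodes = 5),
                               control = slcm_control(se = FALSE)))
  g <- coef(fit)[["changepoint"]]
  pc <- population_curve(fit, times = c(g - 2, g - 1, g, g + 1, g + 2))
  lr <- diff(log(pc$curve$expected))
  expect_equal(lr[1], lr[2], tolerance = 1e-10)   # constant slope before
  expect_equal(lr[3], lr[4], tolerance = 1e-10)   # constant slope after
  expect_equal(pc$changepoint_age, g + 18)
  if (all(coef(fit)[c("slope1", "slope2")] >= 0))
    expect_true(all(diff(predict(fit, times = 0:51)$expected) >= 0))
})

test_that("negative intercept-slope coupling shows up in the EB
           classification", {
  Tm <- diag(c(0.35, 0.006, 0.001, 1))
  Tm[1, 2] <- Tm[2, 1] <- -0.8 * sqrt(0.35 * 0.006)
  truth <- slcm_params(growth_params(-5.8, 0.25, 0, 10), T = Tm,
                       dispersion = dispersion_trajectory("expdecay",
                                                          c(1.5, 0.9, 0.2)))
  sim <- simulate_slcm_data(sim_design(N = 250, truth = truth), seed = 46)
  fit <- suppressWarnings(slcm(sim, re_structure = "full",
                               quad = slcm_quad(nodes = 5),
                               control = slcm_control(se = FALSE)))
  cls <- compare_to_average(fit)
  above <- cls$per_individual$entry == "above"
  expect_gt(mean(cls$per_individual$growth[above] == "below"), 0.5)
})
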