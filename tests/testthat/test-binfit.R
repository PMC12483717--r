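test_that("binning applies the exposure floor, window arithmetic and dedup", {
  d <- data.frame(id = 1:3, age_months = c(18, 21, 69),
                  count = c(1, 2, 3), exposure = c(100, 100, 100))
  set.seed(1)
  b <- bin_counts(d)
  expect_equal(b$t, c(0, 3, 51))

  # duplicate assessments of one child within one window collapse to one
  d2 <- data.frame(id = c(1, 1), age_months = c(19.0, 20.5),
                   count = c(2, 5), exposure = c(100, 110))
  set.seed(2)
  b2 <- bin_counts(d2)
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$t, 0)
  expect_true(b2$count %in% c(2, 5))

  # exposure floor applies before anything else
  d3 <- toy_long()
  d3$exposure[c(2, 5)] <- 24
  set.seed(3)
  b3 <- suppressWarnings(bin_counts(d3))
  expect_equal(nrow(b3), 4L)
  expect_equal(unname(attr(b3, "n_dropped")[["exposure"]]), 2L)

  # ages outside the supported range warn and are rejected, not silently lost
  d4 <- toy_long()
  d4$age_months[1] <- 10
  set.seed(4)
  expect_warning(b4 <- bin_counts(d4), "outside")
  expect_equal(unname(attr(b4, "n_dropped")[["age_range"]]), 1L)
})

test_that("empirical dispersion summary flags over- and underdispersion", {
  b <- data.frame(t = rep(c(0, 3), each = 3),
                  count = c(2, 2, 2, 0, 0, 12))
  s <- dispersion_summary(b)
  expect_equal(s$mean, c(2, 4))
  expect_equal(s$var, c(0, 48))
  expect_equal(s$dispersion, c("under", "over"))

  s1 <- dispersion_summary(data.frame(t = 0, count = 5))
  expect_true(is.na(s1$var) && is.na(s1$dispersion))

  set.seed(5)
  y <- rnb2(500, mu = 5, phi = 1)
  s2 <- dispersion_summary(data.frame(t = 0, count = y))
  expect_equal(s2$dispersion, "over")
})

test_that("per-bin GLMs agree with independent maximum-likelihood oracles", {
  # saturated single-record Poisson: intercept is log(y/u) exactly
  f1 <- fit_bin_glm(7, 100, "poisson")
  expect_equal(f1$intercept, log(7 / 100), tolerance = 1e-8)

  # 10-record toy bin versus an independent Newton-scoring oracle
  set.seed(6)
  y <- c(0, 2, 1, 4, 0, 3, 2, 1, 5, 2)
  u <- c(80, 120, 95, 200, 60, 150, 110, 70, 220, 130)
  fp <- fit_bin_glm(y, u, "poisson")
  expect_equal(fp$intercept, poisson_irls_oracle(y, u), tolerance = 1e-8)
  # ... which for the intercept-only offset model is log(sum y / sum u)
  expect_equal(fp$intercept, log(sum(y) / sum(u)), tolerance = 1e-8)
  expect_equal(fp$loglik, sum(dpois(y, u * exp(fp$intercept), log = TRUE)))

  # NB2 dispersion recovery on a large simulated bin
  set.seed(7)
  u2 <- 25 + rnbinom(2000, size = 2, mu = 95)
  y2 <- rnb2(2000, mu = u2 * 0.03, phi = 0.5)
  fnb <- fit_bin_glm(y2, u2, "nb2")
  # SE of phi from the observed information of a refit oracle: use 3 * a
  # conservative large-sample SE ~ phi * sqrt(2/n) scaled up
  expect_lt(abs(fnb$dispersion - 0.5), 0.1)
  expect_equal(fnb$k, fit_bin_glm(y2, u2, "poisson")$k + 1L)

  # all-zero bin: NB2 dispersion unidentified, degenerate Poisson returned
  expect_warning(fz <- fit_bin_glm(rep(0, 20), rep(100, 20), "nb2"),
                 "unidentified")
  expect_equal(fz$family, "poisson")
})

test_that("AIC/BIC identities hold for every bin fit", {
  b <- small_binned(N = 60, seed = 21)
  bf <- suppressWarnings(fit_bins(b))
  expect_equal(bf$aic, -2 * bf$loglik + 2 * bf$k)
  expect_equal(bf$bic, -2 * bf$loglik + bf$k * log(bf$n))
  expect_true(all(bf$df == bf$n - bf$k))
})

test_that("Pearson statistic: zero at saturation, calibrated under NB2,
           inflated when Poisson is fit to overdispersed counts", {
  f1 <- fit_bin_glm(7, 100, "poisson")
  expect_equal(pearson_statistic(f1)$statistic, 0, tolerance = 1e-10)

  set.seed(8)
  ratios_nb <- ratios_po <- numeric(20)
  for (r in 1:20) {
    u <- 25 + rnbinom(400, size = 2, mu = 95)
    y <- rnb2(400, mu = u * 0.03, phi = 1)
    fn <- fit_bin_glm(y, u, "nb2"); pn <- pearson_statistic(fn)
    fo <- fit_bin_glm(y, u, "poisson"); po <- pearson_statistic(fo)
    ratios_nb[r] <- pn$statistic / pn$df
    ratios_po[r] <- po$statistic / po$df
  }
  expect_gt(mean(ratios_nb > 0.85 & ratios_nb < 1.15), 0.75)
  expect_true(all(ratios_po > 1.5))
})

test_that("marginal KLD: direct-summation oracle, nonnegativity, zero at
           equality", {
  # hand-checkable two-point case against a Poisson(1) marginal
  fake <- structure(list(family = "poisson", mu = c(1, 1), count = c(0, 2),
                         dispersion = NA_real_, n = 2L), class = "bin_glm")
  expected <- kld_oracle(c(0, 2), function(y) dpois(y, 1), 0:2)
  expect_equal(marginal_kld(fake), expected, tolerance = 1e-12)
  expect_equal(expected, 0.5 * log(0.5 / dpois(0, 1)) +
                 0.5 * log(0.5 / dpois(2, 1)), tolerance = 1e-12)

  # p-hat constructed to equal the model marginal exactly -> zero divergence
  mu <- 1.3
  qs <- dpois(0:3, mu)
  counts <- rep(0:3, times = round(1e4 * qs / sum(qs)))
  fake2 <- structure(list(family = "poisson",
                          mu = rep(mu, length(counts)), count = counts,
                          dispersion = NA_real_, n = length(counts)),
                     class = "bin_glm")
  # renormalize the oracle over the truncated support
  expected2 <- kld_oracle(counts, function(y) dpois(y, mu), 0:3)
  expect_equal(marginal_kld(fake2), expected2, tolerance = 1e-10)

  # nonnegativity on genuine fits
  set.seed(9)
  b <- small_binned(N = 60, seed = 22)
  bf <- suppressWarnings(fit_bins(b))
  expect_true(all(bf$kld >= 0))
})

test_that("measurement-model selection recommends NB2 for overdispersed
           counts and not for Poisson counts", {
  # strongly overdispersed generator (no random effects: clean NB2 bins)
  sim <- simulate_slcm_data(sim_design(
    N = 500, truth = truth_no_re(
      dispersion_trajectory("expdecay", c(2.5, 0.95, 1)))), seed = 31)
  b <- bin_counts(sim)
  sel <- select_count_family(suppressWarnings(fit_bins(b)))
  expect_equal(sel$recommendation, "nb2")
  expect_gt(sel$share_nb2_kld, 0.5)

  # equidispersed generator: NB2 should rarely win on AIC
  simp <- simulate_slcm_data(sim_design(
    N = 500, truth = truth_no_re(
      dispersion_trajectory("expdecay", c(3e-6, 0.5, 1e-6)))), seed = 32)
  bp <- bin_counts(simp)
  selp <- suppressWarnings(select_count_family(suppressWarnings(fit_bins(bp))))
  expect_lt(selp$share_nb2_aic, 0.35)

  expect_error(select_count_family(data.frame()), "empty")
})
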