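test_that("the generator is reproducible and respects its design contract", {
  d <- sim_design(N = 50)
  a <- simulate_slcm_data(d, seed = 7)
  b <- simulate_slcm_data(d, seed = 7)
  expect_identical(a, b)
  c2 <- simulate_slcm_data(d, seed = 8)
  expect_false(identical(a$count, c2$count))

  expect_true(all(a$exposure >= 25))
  expect_true(all(a$age_months >= 18 & a$age_months < 72))
  per_id <- table(a$id)
  expect_true(all(per_id >= 2 & per_id <= 5))
  # no age-exposure relationship built in
  expect_lt(abs(cor(a$age_months, a$exposure)), 0.2)

  # generated data are already deduplicated and above the exposure floor:
  # binning leaves them unchanged
  bb <- bin_counts(a)
  expect_equal(nrow(bb), nrow(a))
  expect_equal(sum(attr(bb, "n_dropped")), 0)
  expect_equal(sort(bb$count), sort(a$count))

  # jittered ages still land in the same bins
  dj <- sim_design(N = 50, jitter_ages = TRUE)
  aj <- simulate_slcm_data(dj, seed = 7)
  expect_false(all(aj$age_months == round(aj$age_months)))
  expect_equal(nrow(bin_counts(aj)), nrow(aj))
})

test_that("bin-level moments track the generating curve and its
           marginal variance", {
  # no random effects, near-Poisson: mean count / mean exposure -> exp(f)
  tr <- truth_no_re(dispersion_trajectory("expdecay", c(3e-6, 0.5, 1e-6)))
  sim <- simulate_slcm_data(sim_design(N = 2000, truth = tr), seed = 9)
  b <- bin_counts(sim)
  for (tw in c(0, 9, 24, 45)) {
    sel <- b$t == tw
    obs_rate <- sum(b$count[sel]) / sum(b$exposure[sel])
    tru_rate <- exp(growth_value(tw, tr$fixed))
    # Poisson sampling error on the aggregated rate
    se <- sqrt(sum(b$count[sel])) / sum(b$exposure[sel])
    expect_lt(abs(obs_rate - tru_rate), 4 * se + 1e-12)
  }

  # with lognormal random effects the marginal rate gains exp(var/2):
  # E[y]/E[u] ~ exp(f + Lambda T Lambda' / 2) (exact for the generator)
  tr2 <- test_truth()
  sim2 <- simulate_slcm_data(sim_design(N = 4000, truth = tr2), seed = 10)
  b2 <- bin_counts(sim2)
  for (tw in c(0, 24)) {
    sel <- b2$t == tw
    lam <- growth_basis(tw, tr2$fixed)
    v <- drop(lam %*% tr2$T %*% t(lam))
    tru <- exp(growth_value(tw, tr2$fixed) + v / 2)
    obs <- mean(b2$count[sel] / b2$exposure[sel])
    se <- sd(b2$count[sel] / b2$exposure[sel]) / sqrt(sum(sel))
    expect_lt(abs(obs - tru), 4 * se)
  }

  # overdispersion is visible empirically in nearly every bin
  sim3 <- simulate_slcm_data(sim_design(N = 1000), seed = 11)
  s3 <- dispersion_summary(bin_counts(sim3))
  expect_gte(sum(s3$dispersion == "over", na.rm = TRUE), 16)
})

test_that("recovery study validates its inputs and reports per-parameter
           rows", {
  expect_error(recovery_study(sim_design(N = 20), n_reps = 0), ">= 2")
  rs <- suppressWarnings(
    recovery_study(sim_design(N = 60), n_reps = 2, seed = 5,
                   quad = slcm_quad(nodes = 3),
                   control = slcm_control(se = FALSE)))
  expect_s3_class(rs, "recovery_study")
  expect_setequal(unique(rs$per_rep$param),
                  c("intercept", "slope1", "slope2", "changepoint"))
  expect_true(all(c("bias", "rmse", "coverage") %in% names(rs$summary)))
})
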