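# small in-code fixtures shared across test files

# a tiny deterministic long-format table
toy_long <- function() {
  data.frame(id = c(1, 1, 1, 2, 2, 3),
             age_months = c(18, 21.5, 30, 19, 20.5, 69.9),
             count = c(2, 3, 7, 0, 1, 12),
             exposure = c(100, 120, 90, 80, 150, 200))
}

# truth used for quick simulation-based tests (the package default)
test_truth <- function() default_truth()

# truth with all random-effect variation switched off (pure NB2 bins)
truth_no_re <- function(dispersion = dispersion_trajectory("expdecay",
                                                           c(2.5, 0.9, 0.2))) {
  slcm_params(growth_params(-5.8, 0.25, 0, 10), T = diag(0, 4),
              dispersion = dispersion)
}

# a small simulated dataset, binned
small_binned <- function(N = 80, seed = 11, truth = test_truth()) {
  d <- sim_design(N = N, truth = truth)
  sim <- simulate_slcm_data(d, seed = seed)
  bin_counts(sim)
}

# independent Poisson IRLS oracle for an intercept-only log-link model with
# offset (Newton scoring from 0); used to cross-check fit_bin_glm
poisson_irls_oracle <- function(y, u, tol = 1e-12) {
  b <- 0
  for (i in 1:100) {
    mu <- u * exp(b)
    step <- sum(y - mu) / sum(mu)
    b <- b + step
    if (abs(step) < tol) break
  }
  b
}

# direct-summation KLD oracle between an empirical pmf and model marginal
kld_oracle <- function(y, qfun, support) {
  phat <- tabulate(y + 1L, nbins = max(support) + 1L) / length(y)
  q <- vapply(support, qfun, numeric(1))
  obs <- phat[support + 1L] > 0
  sum(phat[support + 1L][obs] *
        (log(phat[support + 1L][obs]) - log(q[obs])))
}
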