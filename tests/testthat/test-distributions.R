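test_that("NB2 pmf normalizes and matches the gamma-function form", {
  # term-by-term gamma-form oracle: C(y+r-1, y) p^r (1-p)^y with p = r/(r+mu)
  nb2_oracle <- function(y, mu, phi) {
    r <- 1 / phi
    p <- r / (r + mu)
    exp(lchoose(y + r - 1, y)) * p^r * (1 - p)^y
  }
  expect_equal(dnb2(3, mu = 2, phi = 0.5), nb2_oracle(3, 2, 0.5),
               tolerance = 1e-12)
  expect_equal(dnb2(3, mu = 2, phi = 0.5), 0.125, tolerance = 1e-12)

  for (mu in c(0.3, 2, 9)) {
    for (phi in c(0.1, 0.5, 2)) {
      y <- 0:2000
      expect_equal(sum(dnb2(y, mu, phi)), 1, tolerance = 1e-9)
      expect_equal(dnb2(0:50, mu, phi), nb2_oracle(0:50, mu, phi),
                   tolerance = 1e-10)
      # independent library implementation agrees (size = 1/phi mapping)
      expect_equal(dnb2(0:50, mu, phi),
                   dnbinom(0:50, size = 1 / phi, mu = mu), tolerance = 1e-12)
      # first moment
      expect_equal(sum(y * dnb2(y, mu, phi)), mu, tolerance = 1e-7)
    }
  }
})

test_that("Poisson is the small-dispersion limit of NB2", {
  for (y in c(0, 1, 5))
    expect_lt(abs(dnb2(y, 3, 1e-8, log = TRUE) - dpois(y, 3, log = TRUE)),
              1e-5)
  # sup distance over y <= 50 shrinks monotonically as phi decreases
  supd <- vapply(c(1, 0.1, 0.01, 0.001), function(phi)
    max(abs(dnb2(0:50, 3, phi) - dpois(0:50, 3))), numeric(1))
  expect_true(all(diff(supd) < 0))
})

test_that("Poisson log-pmf has its closed form and correct mean", {
  expect_equal(dpois_count(0, 1, log = TRUE), -1)
  expect_equal(dpois_count(2, 2, log = TRUE), log(2) - 2)
  y <- 0:200
  expect_equal(sum(y * dpois_count(y, 3.7)), 3.7, tolerance = 1e-10)
})

test_that("variance function reflects equi- and overdispersion", {
  expect_equal(count_variance(2, count_family("nb2", 0.5)), 4)
  expect_equal(count_variance(7, count_family("poisson")), 7)
  grid <- expand.grid(mu = c(0.2, 1, 5, 40), phi = c(0.01, 0.5, 3))
  v <- count_variance(grid$mu, count_family("nb2", 1))
  expect_true(all(mapply(function(m, p)
    count_variance(m, count_family("nb2", p)) >= m, grid$mu, grid$phi)))
})

test_that("NB2 sampler matches its first two moments and is reproducible", {
  set.seed(99)
  x <- rnb2(1e5, mu = 4, phi = 0.8)
  se_mean <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 4), 3 * se_mean)
  v_true <- 4 + 0.8 * 16
  # Monte-Carlo error of the sample variance from the fourth moment
  se_var <- sqrt((mean((x - mean(x))^4) - var(x)^2) / length(x))
  expect_lt(abs(var(x) - v_true), 4 * se_var)

  set.seed(123); a <- rcount(50, 3, count_family("nb2", 0.5))
  set.seed(123); b <- rcount(50, 3, count_family("nb2", 0.5))
  expect_identical(a, b)
})

test_that("domain violations are rejected", {
  expect_error(dnb2(-1, 2, 0.5), "nonnegative")
  expect_error(dnb2(1.5, 2, 0.5), "integer")
  expect_error(dnb2(1, -2, 0.5), "positive")
  expect_error(dnb2(1, 2, 0), "positive")
  expect_error(count_family("poisson", dispersion = 1), "must not")
  expect_error(count_family("nb2"), "requires")
  expect_error(count_family("nb2", -1), "positive")
  expect_error(rcount(5, -1, count_family("poisson")), "positive")
})
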