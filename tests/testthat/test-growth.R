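test_that("free-parameter counting and linearity classification", {
  unconstrained <- growth_spec(continuity = -1)
  constrained <- growth_spec()
  line <- growth_spec(n_phases = 1)

  expect_equal(n_free_growth_params(unconstrained), 5L)
  expect_equal(n_free_growth_params(constrained), 4L)
  expect_equal(n_free_growth_params(line), 2L)

  tu <- table(classify_linearity(unconstrained))
  expect_equal(unname(tu[["linear"]]), 4L)
  expect_equal(unname(tu[["nonlinear"]]), 1L)
  tc <- table(classify_linearity(constrained))
  expect_equal(unname(tc[["linear"]]), 3L)
  expect_equal(unname(tc[["nonlinear"]]), 1L)
  expect_true(all(classify_linearity(line) == "linear"))

  # three phases, both knots continuous: 4 linear + 2 nonlinear
  three <- growth_spec(n_phases = 3, continuity = 0)
  expect_equal(n_free_growth_params(three), 6L)
  expect_equal(sum(classify_linearity(three) == "nonlinear"), 2L)
})

test_that("trajectory evaluation: intercept, degenerate line, continuity", {
  p <- growth_params(-5.8, 0.25, 0, 10)
  expect_equal(growth_value(0, p), -5.8)
  expect_equal(phase2_intercept(p), -5.8 + 2.5)

  line <- growth_params(1, 0.3, 0.3, 7)
  tt <- seq(0, 30, by = 0.5)
  expect_equal(growth_value(tt, line), 1 + 0.3 * tt)

  set.seed(4)
  for (i in 1:20) {
    pr <- growth_params(rnorm(1), rnorm(1), rnorm(1), runif(1, 1, 40))
    g <- pr[["changepoint"]]
    eps <- 1e-9
    expect_equal(growth_value(g - eps, pr), growth_value(g + eps, pr),
                 tolerance = 1e-7)
    # reparameterization identity: explicit two-segment form with derived
    # phase-2 intercept equals the min/max form everywhere
    t2 <- runif(5, 0, 50)
    seg <- ifelse(t2 <= g, pr[["intercept"]] + pr[["slope1"]] * t2,
                  phase2_intercept(pr) + pr[["slope2"]] * (t2 - g))
    expect_equal(growth_value(t2, pr), seg, tolerance = 1e-12)
  }
  expect_error(growth_value(-1, p), "nonnegative")
})

test_that("basis matrix matches finite differences and knot conventions", {
  set.seed(5)
  for (i in 1:10) {
    pr <- growth_params(rnorm(1), rnorm(1), rnorm(1), runif(1, 5, 40))
    g <- pr[["changepoint"]]
    tt <- setdiff(seq(0, 51, by = 1.7), g)   # avoid the knot itself
    B <- growth_basis(tt, pr)
    expect_equal(unname(B[, "intercept"]), rep(1, length(tt)))
    expect_true(all(B[tt <= g, "changepoint"] == 0))

    # central finite differences of the trajectory in each parameter
    h <- 1e-6
    fd <- function(k) {
      up <- dn <- as.numeric(pr)
      up[k] <- up[k] + h; dn[k] <- dn[k] - h
      (growth_value(tt, do.call(growth_params, as.list(up))) -
         growth_value(tt, do.call(growth_params, as.list(dn)))) / (2 * h)
    }
    for (k in 1:4)
      expect_equal(unname(B[, k]), fd(k), tolerance = 1e-5)
  }

  # at t exactly at the knot the changepoint loading takes its left value, 0
  pr <- growth_params(0, 0.3, 0.1, 9)
  B <- growth_basis(c(9, 9.0001), pr)
  expect_equal(unname(B[1, "changepoint"]), 0)
  expect_equal(unname(B[2, "changepoint"]), 0.2, tolerance = 1e-12)
  expect_error(growth_basis(-3, pr), "nonnegative")
})
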