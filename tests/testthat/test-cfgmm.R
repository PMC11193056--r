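test_that("generalized gamma density matches its closed form and the gamma pdf", {
  expect_equal(dGenGamma(1, 2, 1), exp(-1), tolerance = 1e-12)
  xs <- c(0.1, 0.7, 1.5, 4)
  expect_equal(dGenGamma(xs, 2.3, 0.8),
               dgamma(xs, shape = 2.3, scale = 0.8), tolerance = 1e-12)
  # g != 1 leaves the gamma family; normalization still holds numerically
  for (g in c(1, 0.7, 1.6)) {
    int <- integrate(dGenGamma, 0, Inf, shape = 1.8, scale = 0.6, gamma = g,
                     rel.tol = 1e-9)
    expect_equal(int$value, 1, tolerance = 1e-6)
  }
  expect_error(dGenGamma(1, -1, 1), class = "mifGate_domain_error")
})

test_that("closed-form estimator reproduces the worked {1,2,4} case", {
  est <- cfGammaEstimate(c(1, 2, 4))
  expect_equal(est[["shape"]], 21 / (9 * log(2)), tolerance = 1e-12)
  expect_equal(est[["scale"]], log(2), tolerance = 1e-12)
  expect_error(cfGammaEstimate(c(2, 2, 2)),
               class = "mifGate_degenerate_sample_error")
  expect_error(cfGammaEstimate(c(1, 2), weights = c(0, 0)),
               class = "mifGate_empty_component_error")
})

test_that("closed-form estimates approach the numerical MLE across shapes", {
  set.seed(101)
  for (shape in c(0.5, 2, 10)) {
    x <- rgamma(1e5, shape = shape, scale = 3)
    cf <- cfGammaEstimate(x)
    ml <- oracleGammaMLE(x)
    expect_lt(abs(cf[["shape"]] - ml[["shape"]]) / ml[["shape"]], 0.005)
    expect_lt(abs(cf[["scale"]] - ml[["scale"]]) / ml[["scale"]], 0.005)
    # and both are close to the truth
    expect_lt(abs(cf[["shape"]] - shape) / shape, 0.02)
    expect_lt(abs(cf[["scale"]] - 3) / 3, 0.02)
  }
})

test_that("weighted estimator equals unweighted on replicated values", {
  x <- c(0.5, 1.2, 3.1)
  w <- c(2, 1, 3)
  xRep <- rep(x, times = w)
  expect_equal(cfGammaEstimate(x, w), cfGammaEstimate(xRep),
               tolerance = 1e-12)
})

test_that("constrained M-step returns interior estimates untouched", {
  set.seed(7)
  x <- rgamma(5000, shape = 4, scale = 0.2)   # mode 0.6
  comp <- constrainedMStep(x, rep(1, length(x)), ModeConstraint(lower = 0.45))
  expect_identical(comp@constraintActive, "none")
  expect_equal(c(shape = comp@shape, scale = comp@scale),
               cfGammaEstimate(x), tolerance = 1e-12)
})

test_that("boundary M-step lands on the bound and matches a grid oracle", {
  set.seed(8)
  x <- rgamma(4000, shape = 4, scale = 0.1)   # mode 0.3
  w <- runif(length(x), 0.2, 1)
  for (cs in list(ModeConstraint(lower = 0.45),
                  ModeConstraint(upper = 0.18))) {
    comp <- constrainedMStep(x, w, cs)
    bound <- if (is.finite(cs@upper)) cs@upper else cs@lower
    side <- if (is.finite(cs@upper)) "upper" else "lower"
    expect_identical(comp@constraintActive, side)
    expect_equal((comp@shape - 1) * comp@scale, bound, tolerance = 1e-8)
    grid <- oracleBoundaryGrid(x, w, bound)
    qFit <- oracleGammaQ(comp@shape, comp@scale, x, w)
    expect_gte(qFit, grid$Q - 1e-4)
  }
})

test_that("EM recovers a well-separated two-component gamma mixture", {
  set.seed(5)
  n <- 50000
  z <- rbinom(n, 1, 0.4)
  x <- ifelse(z == 1, rgamma(n, 20, scale = 0.3), rgamma(n, 2, scale = 0.5))
  fit <- emFitGamma(x)
  expect_true(fit@converged)
  expect_lt(max(abs(fit@weights - c(0.6, 0.4))), 0.02)
  m <- modes(fit)
  expect_equal(m[1], 0.5, tolerance = 0.05)
  expect_equal(m[2], 5.7, tolerance = 0.05)
  expect_gt(m[2], m[1])
  # EM ascent for the unconstrained fit
  expect_true(all(diff(fit@loglikTrace) >=
                    -1e-10 * pmax(abs(fit@loglikTrace[-1]), 1)))
})

test_that("fits are deterministic and permutation invariant", {
  set.seed(6)
  x <- c(rgamma(2000, 3, scale = 0.2), rgamma(500, 15, scale = 0.1))
  f1 <- emFitGamma(x)
  f2 <- emFitGamma(sample(x))
  expect_identical(f1@weights, f2@weights)
  expect_identical(f1@components[[2]]@shape, f2@components[[2]]@shape)
  expect_identical(f1@loglikTrace, f2@loglikTrace)
})

test_that("mode constraints are honored by the full EM fit", {
  set.seed(9)
  x <- c(rgamma(3000, 4, scale = 0.05), rgamma(1500, 6, scale = 0.08))
  # true positive mode 0.4; force it at least 0.45
  fit <- emFitGamma(x, list(unconstrained(), ModeConstraint(lower = 0.45)))
  expect_gte(modes(fit)[2], 0.45 - 1e-9)
  # quantile constraints resolve against the data before fitting
  fitQ <- emFitGamma(x, list(unconstrained(),
                             ModeConstraint(lower = 0.9, kind = "quantile")))
  expect_gte(modes(fitQ)[2], quantile(x, 0.9, names = FALSE) - 1e-9)
})

test_that("too-few or degenerate inputs are classed errors", {
  expect_error(emFitGamma(rgamma(50, 2, scale = 1)),
               class = "mifGate_too_few_cells_error")
  expect_error(emFitGamma(rep(2, 500)),
               class = "mifGate_too_few_cells_error")
})
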