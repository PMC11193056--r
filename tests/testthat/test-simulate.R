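test_that("proportion rescaling follows the fixed-expression formula", {
  out <- rescaleProportions(0.2, 0.7, 0.05)
  expect_equal(unname(out),
               c(0.95 * 0.2 / 0.9, 0.95 * 0.7 / 0.9, 0.05),
               tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-15)
  # p = 0 renormalizes onto the zero/negative split
  expect_equal(unname(rescaleProportions(0.2, 0.6, 0)),
               c(0.25, 0.75, 0), tolerance = 1e-12)
  expect_error(rescaleProportions(0, 0, 0.05),
               class = "mifGate_degenerate_error")
  # conservation holds for arbitrary inputs
  set.seed(3)
  for (i in 1:20) {
    l <- runif(2); p <- runif(1, 0, 0.99)
    expect_equal(sum(rescaleProportions(l[1], l[2], p)), 1,
                 tolerance = 1e-12)
  }
})

test_that("the packaged library is valid and spans ordered modes", {
  lib <- defaultParamLibrary()
  expect_equal(nrow(lib), 16L)
  expect_equal(lib$lambda0 + lib$lambda1 + lib$lambda2, rep(1, 16),
               tolerance = 1e-12)
  m1 <- (lib$a1 - 1) * lib$b1
  m2 <- (lib$a2 - 1) * lib$b2
  expect_true(all(m2 > m1))
  # identifiability: the analytic elbow sits below every expressed mode,
  # down to the rare-population setting
  for (p in c(0.05, 0.001)) {
    for (i in seq_len(nrow(lib))) {
      lam <- rescaleProportions(lib$lambda0[i], lib$lambda1[i], p)
      cdf <- function(x)
        lam[1] + lam[2] * pgamma(x, lib$a1[i], scale = lib$b1[i]) +
          lam[3] * pgamma(x, lib$a2[i], scale = lib$b2[i])
      q <- uniroot(function(x) cdf(x) - (1 - p), c(1e-9, 20))$root
      expect_lt(q, 0.95 * m2[i])
    }
  }
})

test_that("simulation respects its seed, labels and proportions", {
  sim <- simulateSlides(pExpressed = 0.05, nSlides = 3, nCells = 5000,
                        seed = 42)
  sim2 <- simulateSlides(pExpressed = 0.05, nSlides = 3, nCells = 5000,
                         seed = 42)
  expect_identical(
    SummarizedExperiment::assay(sim, "intensity"),
    SummarizedExperiment::assay(sim2, "intensity"))
  cd <- SummarizedExperiment::colData(sim)
  v <- as.numeric(SummarizedExperiment::assay(sim, "intensity")[1, ])
  # zeros exactly where the truth label is 0
  expect_identical(v == 0, cd$truth == 0L)
  # growing the batch never reshuffles earlier slides
  sim5 <- simulateSlides(pExpressed = 0.05, nSlides = 5, nCells = 5000,
                         seed = 42)
  v5 <- as.numeric(SummarizedExperiment::assay(sim5, "intensity")[1, ])
  expect_identical(v, v5[seq_along(v)])
})

test_that("empirical expressed fraction matches the target within binomial error", {
  n <- 1e5
  lib <- defaultParamLibrary()[4, ]
  sim <- simulateSlides(lib, pExpressed = 0.05, nSlides = 1, nCells = n,
                        seed = 9)
  frac <- mean(SummarizedExperiment::colData(sim)$truth == 2L)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(frac - 0.05), 3 * se)
  # p = 0 leaves no expressed cells at all
  sim0 <- simulateSlides(lib, pExpressed = 0, nSlides = 2, nCells = 2000,
                         seed = 9)
  expect_false(any(SummarizedExperiment::colData(sim0)$truth == 2L))
})

test_that("constraint scenarios have their defining shapes", {
  none <- scenarioConstraints("none")
  expect_identical(none[[2]]@lower, 0)
  expect_identical(none[[2]]@upper, Inf)

  acc <- scenarioConstraints("accurate", pExpressed = 0.05)
  expect_identical(acc[[2]]@kind, "quantile")
  expect_equal(acc[[2]]@lower, 0.95)

  lib <- defaultParamLibrary()
  m2 <- (lib$a2 - 1) * lib$b2
  inacc <- scenarioConstraints("inaccurate", pExpressed = 0.05)
  expect_identical(inacc[[2]]@kind, "fixed")
  expect_equal(inacc[[2]]@lower, 1.5 * median(m2), tolerance = 1e-12)
  # deliberately higher than reasonable: excludes true expressed modes
  # for a substantial share of the library (here all of it)
  expect_gt(mean(inacc[[2]]@lower > m2), 0.5)

  # the accurate elbow, resolved on a concrete slide, stays below the
  # slide's expressed mode while the inaccurate bound sits above it
  set.seed(99)
  v <- c(rep(0, 2000), rgamma(7500, 4, scale = 0.08 / 3),
         rgamma(500, 10, scale = 0.6 / 9))
  rAcc <- resolveConstraint(acc[[2]], v)
  expect_lt(rAcc@lower, 0.6)
  expect_gt(inacc[[2]]@lower, 0.6)
})

test_that("quantile constraints honor cap and inflate when resolved", {
  v <- 1:100 / 10
  base <- resolveConstraint(ModeConstraint(lower = 0.9, kind = "quantile"), v)
  infl <- resolveConstraint(ModeConstraint(lower = 0.9, kind = "quantile",
                                           inflate = 2), v)
  capd <- resolveConstraint(ModeConstraint(lower = 0.9, kind = "quantile",
                                           cap = 5), v)
  expect_equal(infl@lower, 2 * base@lower, tolerance = 1e-12)
  expect_equal(capd@lower, min(base@lower, 5), tolerance = 1e-12)
})

test_that("a library can be rebuilt from fitted models", {
  sim <- simulateSlides(pExpressed = 0.2, nSlides = 3, nCells = 4000,
                        seed = 12)
  fits <- fitBatch(sim, assay = "intensity")
  lib <- libraryFromFits(fits)
  expect_true(all(c("lambda0", "a1", "b2") %in% colnames(lib)))
  expect_equal(nrow(lib), sum(qcSummary(fits)$converged))
})

test_that("thresholded posteriors recover truth well for separated libraries", {
  lib <- defaultParamLibrary()
  sep <- lib[(lib$a2 - 1) * lib$b2 >= 0.65, ]   # well-separated regime
  sim <- simulateSlides(sep, pExpressed = 0.05, nSlides = 12,
                        nCells = 10000, seed = 13)
  fits <- fitBatch(sim, constraints = scenarioConstraints(
    "accurate", paramLibrary = sep, pExpressed = 0.05),
    assay = "intensity")
  rep <- simulationReport(fits, sim)
  expect_gt(rep$meanARI, 0.8)
  expect_lt(abs(rep$meanBias), 0.01)
})
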