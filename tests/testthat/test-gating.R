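# One reusable simulated stratum: 20% zeros, negative/positive split 60/20.
simStratum <- function(n = 20000, seed = 31) {
  set.seed(seed)
  z <- sample(0:2, n, replace = TRUE, prob = c(0.2, 0.6, 0.2))
  v <- numeric(n)
  v[z == 1] <- rgamma(sum(z == 1), 4, scale = 0.03)    # mode 0.09
  v[z == 2] <- rgamma(sum(z == 2), 18, scale = 0.04)   # mode 0.68
  list(values = v, truth = z)
}

test_that("zero mass is exact and lambda decomposition is conserved", {
  s <- simStratum()
  fit <- fitMarker(s$values)
  expect_true(fit@converged)
  expect_identical(fit@lambda[["zero"]], mean(s$values == 0))
  expect_equal(sum(fit@lambda), 1, tolerance = 1e-12)
  expect_equal(unname(fit@lambda[c("negative", "positive")] /
                        (1 - fit@lambda[["zero"]])),
               unname(fit@mixture@weights), tolerance = 1e-12)
  # recovery of all three proportions
  expect_lt(max(abs(fit@lambda - c(0.2, 0.6, 0.2))), 0.02)
})

test_that("degenerate strata are flagged unfit, not raised", {
  f <- fitMarker(c(rep(0, 500), rgamma(40, 2, scale = 1)))
  expect_false(f@converged)
  expect_match(f@failure, "positive values")
  allZero <- fitMarker(rep(0, 300))
  expect_false(allZero@converged)
  expect_error(posteriorProb(allZero, 1),
               class = "mifGate_nonconvergence_error")
  expect_error(marginalProb(allZero, 1),
               class = "mifGate_nonconvergence_error")
})

test_that("posterior obeys the formula, the zero rule and the weighted flag", {
  f <- makeMarkerFit(2, 0.1, 8, 0.1, 0.1, 0.63, 0.27)
  x <- c(0, 0.3, 1.0)
  pw <- posteriorProb(f, x, adjust = FALSE)
  expect_identical(pw[1], 0)
  f1 <- dgamma(x[-1], 2, scale = 0.1); f2 <- dgamma(x[-1], 8, scale = 0.1)
  expect_equal(pw[-1], 0.27 * f2 / (0.63 * f1 + 0.27 * f2),
               tolerance = 1e-12)
  pu <- posteriorProb(f, x, weighted = FALSE, adjust = FALSE)
  expect_equal(pu[-1], f2 / (f1 + f2), tolerance = 1e-12)
  # identical components: weighted posterior is flat at lambda2/(lambda1+lambda2)
  fEq <- makeMarkerFit(2, 0.1, 2, 0.1 + 1e-9, 0, 0.7, 0.3)
  expect_equal(posteriorProb(fEq, c(0.2, 0.8, 2), adjust = FALSE),
               rep(0.3, 3), tolerance = 1e-6)
})

test_that("marginal probability is the positive component CDF", {
  f <- makeMarkerFit(2, 0.5, 2, 1, 0.2, 0.5, 0.3)
  expect_identical(marginalProb(f, 0), 0)
  # closed form for integer shape: 1 - (1 + x) e^{-x} at scale 1
  expect_equal(marginalProb(f, 2), 1 - 3 * exp(-2), tolerance = 1e-12)
  xs <- seq(0, 8, by = 0.25)
  expect_true(all(diff(marginalProb(f, xs)) >= 0))
  expect_gte(marginalProb(f, qgamma(0.99999, 2, scale = 1)), 0.9999)
})

test_that("monotonicity adjustment fixes a dipping posterior and no more", {
  # heavy negative tail (shape 1.2, scale 1) vs light positive tail:
  # raw posterior rises then collapses in the far tail
  f <- makeMarkerFit(1.2, 1.0, 12, 0.1, 0.1, 0.6, 0.3,
                     grid = seq(0.01, 6, by = 0.01))
  ma <- monotoneAdjust(f)
  expect_true(ma$adjusted)
  expect_true(any(diff(ma$posterior) < -1e-9))          # raw dips
  post <- ma$posteriorAdj
  idx <- ma$crossing:length(post)
  expect_true(all(diff(post[idx]) >= -1e-12))           # fixed beyond x*
  expect_true(all(post[idx] >= ma$posterior[idx] - 1e-12))
  before <- seq_len(ma$crossing - 1)
  expect_equal(post[before], ma$posterior[before])      # untouched before x*
  # posteriorProb(adjust = TRUE) interpolates the adjusted curve
  pAdj <- posteriorProb(f, c(3, 5.5))
  expect_true(all(diff(pAdj) >= 0))
  expect_gt(pAdj[2], 0.9)
})

test_that("curves that never cross are returned unmodified", {
  f <- makeMarkerFit(2, 0.1, 30, 0.1, 0, 0.999, 0.001,
                     grid = seq(0.01, 0.5, by = 0.01))
  ma <- monotoneAdjust(f)
  if (!ma$adjusted) {
    expect_identical(ma$g1adj, ma$g1)
    expect_identical(ma$g2adj, ma$g2)
  } else succeed("curves cross inside this grid")
})

test_that("batch fitting is independent per stratum and reports failures", {
  set.seed(77)
  good <- function() c(rep(0, 50), rgamma(400, 4, scale = 0.05),
                       rgamma(100, 18, scale = 0.04))
  ct <- CellTable(cbind(CD3 = c(good(), good(), good()),
                        CD68 = c(good(), good(),
                                 c(rep(0, 530), rgamma(20, 2, scale = 1)))),
                  slide = rep(c("s1", "s2", "s3"), each = 550))
  fits <- fitBatch(ct, assay = "intensity")
  expect_equal(length(fits), 6L)
  rep <- convergenceReport(fits)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$slide, "s3")
  expect_equal(rep$channel, "CD68")
  # the failing stratum does not perturb any other fit
  ct2 <- ct[, SummarizedExperiment::colData(ct)$slide_id != "s3"]
  fits2 <- fitBatch(ct2, assay = "intensity")
  expect_identical(getFit(fits, "s1", "CD3")@lambda,
                   getFit(fits2, "s1", "CD3")@lambda)
  # refitting the same input is bit-identical
  fits3 <- fitBatch(ct, assay = "intensity")
  expect_identical(getFit(fits, "s2", "CD68")@mixture@loglikTrace,
                   getFit(fits3, "s2", "CD68")@mixture@loglikTrace)
})

test_that("qc table carries one row per fit and the density integrates", {
  s <- simStratum()
  fit <- fitMarker(s$values)
  fits <- new("MarkerFitSet", fits = list(s1.m = fit))
  qc <- qcSummary(fits)
  expect_equal(nrow(qc), 1L)
  expect_equal(qc$lambda2, fit@lambda[["positive"]], tolerance = 1e-12)
  expect_equal(qc$mode2, modes(fit)[2], tolerance = 1e-12)
  # mixture density integrates to lambda1 + lambda2 over the positive axis
  grid <- seq(1e-4, qgamma(0.999999, 18, scale = 0.04), length.out = 512)
  dens <- mixtureDensity(fit, grid)
  integral <- sum(diff(grid) * (dens[-1] + dens[-length(dens)]) / 2)
  expect_equal(integral, sum(fit@lambda[c("negative", "positive")]),
               tolerance = 1e-3)
})

test_that("probabilities for nonconverged strata propagate as missing", {
  set.seed(78)
  v1 <- c(rep(0, 100), rgamma(300, 4, scale = 0.05),
          rgamma(100, 18, scale = 0.04))
  v2 <- c(rep(0, 480), rgamma(20, 2, scale = 1))   # unfittable
  ct <- CellTable(cbind(m = c(v1, v2)), slide = rep(c("a", "b"), each = 500))
  fits <- fitBatch(ct, assay = "intensity")
  probs <- gateProbabilities(fits, ct, assay = "intensity")
  expect_equal(nrow(probs), 1000L)
  expect_true(all(is.na(probs$posterior[probs$slide == "b"])))
  pa <- probs[probs$slide == "a", ]
  expect_true(all(!is.na(pa$posterior)))
  expect_true(all(pa$posterior[v1 == 0] == 0))
  expect_true(all(pa$marginal[v1 == 0] == 0))
})

test_that("compareFits aligns strata and enforces matching keys", {
  s <- simStratum()
  fA <- fitMarker(s$values, slide = "s1", channel = "CD4")
  fB <- fitMarker(s$values,
                  constraints = list(unconstrained(),
                                     ModeConstraint(lower = 0.8)),
                  slide = "s1", channel = "CD4")
  cmp <- compareFits(fA, fB)
  expect_setequal(unique(cmp$fit), c("A", "B"))
  expect_gte(modes(fB)[2], 0.8 - 1e-9)
  wrong <- fitMarker(s$values, slide = "s2", channel = "CD4")
  expect_error(compareFits(fA, wrong), class = "mifGate_schema_error")
})
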