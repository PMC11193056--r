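# Independent oracles used across the suite. Each is deliberately written
# from first principles (root-finding, brute-force enumeration, grid
# search) so it shares no code path with the implementation it checks.

# Numerical gamma MLE: solve the profile score
#   log(a) - digamma(a) = log(mean(x)) - mean(log(x))
# by root finding; scale = mean(x)/a.
oracleGammaMLE <- function(x) {
  rhs <- log(mean(x)) - mean(log(x))
  f <- function(loga) {
    a <- exp(loga)
    log(a) - digamma(a) - rhs
  }
  root <- uniroot(f, c(log(1e-4), log(1e6)), tol = 1e-12)$root
  a <- exp(root)
  c(shape = a, scale = mean(x) / a)
}

# Weighted expected gamma log-likelihood, direct form.
oracleGammaQ <- function(a, b, values, weights)
  sum(weights * dgamma(values, shape = a, scale = b, log = TRUE))

# Best boundary solution (a-1)b = m by brute-force grid search over a.
oracleBoundaryGrid <- function(values, weights, m, aGrid = NULL) {
  if (is.null(aGrid)) aGrid <- exp(seq(log(1 + 1e-6), log(50), length.out = 20000))
  q <- vapply(aGrid, function(a)
    oracleGammaQ(a, m / (a - 1), values, weights), numeric(1))
  i <- which.max(q)
  list(shape = aGrid[i], scale = m / (aGrid[i] - 1), Q = q[i])
}

# Adjusted Rand Index by brute-force pair counting.
oracleARI <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sameA <- a[i] == a[j]
      sameB <- b[i] == b[j]
      if (sameA && sameB) s11 <- s11 + 1
      else if (sameA && !sameB) s10 <- s10 + 1
      else if (!sameA && sameB) s01 <- s01 + 1
      else s00 <- s00 + 1
    }
  }
  tot <- choose(n, 2)
  expected <- (s11 + s10) * (s11 + s01) / tot
  maxIdx <- ((s11 + s10) + (s11 + s01)) / 2
  if (maxIdx == expected) return(if (s11 == expected) 1 else 0)
  (s11 - expected) / (maxIdx - expected)
}

# Uncorrected Ripley K by brute-force pair enumeration.
oracleKNone <- function(x, y, r, window) {
  A <- (window[2] - window[1]) * (window[4] - window[3])
  n <- length(x)
  count <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= r)
        count <- count + 1
    }
  }
  A * count / (n * (n - 1))
}

# A small synthetic MarkerFit with known parameters (bypasses fitting).
makeMarkerFit <- function(a1, b1, a2, b2, lambda0, lambda1, lambda2,
                          grid = NULL) {
  if (is.null(grid)) {
    hi <- qgamma(0.999, shape = a2, scale = b2)
    grid <- seq(hi / 400, hi, length.out = 400)
  }
  w <- c(lambda1, lambda2) / (lambda1 + lambda2)
  mix <- new("MixtureFit",
             components = list(
               new("GammaComponent", shape = a1, scale = b1,
                   constraintActive = "none"),
               new("GammaComponent", shape = a2, scale = b2,
                   constraintActive = "none")),
             weights = w, loglikTrace = 0, converged = TRUE, nIter = 1L)
  new("MarkerFit", slide = "s1", channel = "m1",
      lambda = c(zero = lambda0, negative = lambda1, positive = lambda2),
      mixture = mix, grid = grid, nCells = 1000L,
      nZero = as.integer(round(1000 * lambda0)), converged = TRUE)
}
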