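#' Fit the zero-inflated gamma mixture to one slide and channel
#'
#' The per-stratum model places probability \eqn{\lambda_0} on exact zeros
#' (arising from autofluorescence adjustment) and models the positive
#' values as a two-component gamma mixture whose lower-mode component is
#' marker-negative and higher-mode component marker-positive:
#' \deqn{P(X = x) = I(x=0)\,\lambda_0 +
#'   I(x>0)\sum_{k=1}^{2}\lambda_k f(x; a_k, b_k).}
#' \eqn{\lambda_0} is set to the exact empirical zero fraction; the
#' mixture is fitted to the positive values by [emFitGamma()] and its
#' weights are renormalized onto the full cell count so that
#' \eqn{\lambda_0 + \lambda_1 + \lambda_2 = 1}.
#'
#' Quantile-specified mode constraints are resolved here against the full
#' value vector, zeros included — a bound at probability \eqn{1-p} then
#' means "a fraction \eqn{p} of all cells lie above it", matching how
#' expressed-cell fractions are quoted. (When [emFitGamma()] is called
#' directly, quantiles resolve against its positive input instead.)
#'
#' Strata with too few positive cells, or whose EM run fails, return a
#' MarkerFit with \code{converged = FALSE} and a \code{failure} reason
#' instead of raising, so batch runs can report and continue.
#'
#' @param values nonnegative per-cell intensities (normalized scale).
#' @param constraints list of two \linkS4class{ModeConstraint}s (negative,
#'   positive component).
#' @param slide,channel identifiers recorded on the fit.
#' @param ... passed to [emFitGamma()].
#' @return a \linkS4class{MarkerFit}.
#' @export
fitMarker <- function(values,
                      constraints = list(unconstrained(), unconstrained()),
                      slide = "slide", channel = "marker", ...) {
  if (any(!is.finite(values)) || any(values < 0))
    stopc("mifGate_validation_error", "intensities must be finite and >= 0")
  n <- length(values)
  if (n == 0L) stopc("mifGate_empty_input_error", "no cells supplied")
  nZero <- sum(values == 0)
  lambda0 <- nZero / n
  pos <- values[values > 0]
  grid <- sort(unique(pos))
  bad <- function(reason)
    new("MarkerFit", slide = slide, channel = channel,
        lambda = c(zero = lambda0, negative = 1 - lambda0, positive = 0),
        mixture = NULL, grid = grid, nCells = n, nZero = as.integer(nZero),
        converged = FALSE, failure = reason)
  constraints <- lapply(constraints, resolveConstraint, values = values)
  mix <- tryCatch(emFitGamma(pos, constraints = constraints, ...),
                  mifGate_too_few_cells_error = function(e) e,
                  mifGate_degenerate_sample_error = function(e) e)
  if (inherits(mix, "condition")) return(bad(conditionMessage(mix)))
  lam <- (1 - lambda0) * mix@weights
  fit <- new("MarkerFit", slide = slide, channel = channel,
             lambda = c(zero = lambda0, negative = lam[1L],
                        positive = lam[2L]),
             mixture = mix, grid = grid, nCells = n,
             nZero = as.integer(nZero), converged = mix@converged,
             failure = mix@failure)
  fit
}

#' @describeIn modes component modes of the positive-part mixture
#'   (numeric(0) when no mixture was fitted).
setMethod("modes", "MarkerFit", function(object)
  if (is.null(object@mixture)) numeric(0) else modes(object@mixture))

#' @describeIn mixWeights zero/negative/positive proportions over all
#'   cells.
setMethod("mixWeights", "MarkerFit", function(object) object@lambda)

.positiveComp <- function(fit) {
  k <- length(fit@mixture@components)
  fit@mixture@components[[k]]
}
.negativeComp <- function(fit) fit@mixture@components[[1L]]

.assertConverged <- function(fit) {
  if (is.null(fit@mixture) || !fit@converged)
    stopc("mifGate_nonconvergence_error",
          "fit for (%s, %s) did not converge (%s); probabilities unavailable",
          fit@slide, fit@channel,
          if (is.na(fit@failure)) "unknown" else fit@failure)
}

# Weighted (default) or unweighted component curves on a grid.
.componentCurves <- function(fit, grid, weighted = TRUE) {
  f1 <- .compDensity(grid, .negativeComp(fit))
  f2 <- .compDensity(grid, .positiveComp(fit))
  if (weighted) {
    lam <- fit@lambda
    list(g1 = lam[["negative"]] * f1, g2 = lam[["positive"]] * f2)
  } else list(g1 = f1, g2 = f2)
}

#' Monotonicity adjustment of the component density curves
#'
#' In the extreme tails the marker-positive component's density need not
#' dominate, so the raw posterior can decrease with intensity. The
#' correction finds the first crossing \eqn{x^*} — the smallest evaluation
#' point where the positive-component curve is at least the negative one
#' (ties count) — and, from \eqn{x^*} onward, replaces the negative curve
#' by its running minimum and the positive curve by its running maximum.
#' The adjusted posterior \eqn{g_2/(g_1+g_2)} is then nondecreasing beyond
#' \eqn{x^*} and unchanged before it. If the curves never cross, both are
#' returned unmodified with \code{adjusted = FALSE}.
#'
#' @param fit a converged \linkS4class{MarkerFit}.
#' @param evalPoints sorted ascending positive evaluation points (defaults
#'   to the sorted unique observed positive values stored on the fit).
#' @param weighted use \eqn{\lambda}-weighted component curves (default)
#'   or the bare densities.
#' @return list with \code{grid}, raw curves \code{g1}, \code{g2},
#'   adjusted curves \code{g1adj}, \code{g2adj}, \code{posterior} (raw),
#'   \code{posteriorAdj}, the crossing index \code{crossing} (NA if none)
#'   and flag \code{adjusted}.
#' @export
monotoneAdjust <- function(fit, evalPoints = fit@grid, weighted = TRUE) {
  .assertConverged(fit)
  if (is.unsorted(evalPoints))
    stopc("mifGate_domain_error", "evalPoints must be sorted ascending")
  cur <- .componentCurves(fit, evalPoints, weighted = weighted)
  g1 <- cur$g1; g2 <- cur$g2
  raw <- g2 / (g1 + g2)
  cross <- which(g2 >= g1)[1L]
  g1a <- g1; g2a <- g2
  if (!is.na(cross)) {
    idx <- cross:length(evalPoints)
    g1a[idx] <- cummin(g1[idx])
    g2a[idx] <- cummax(g2[idx])
  }
  list(grid = evalPoints, g1 = g1, g2 = g2, g1adj = g1a, g2adj = g2a,
       posterior = raw, posteriorAdj = g2a / (g1a + g2a),
       crossing = cross, adjusted = !is.na(cross))
}

#' Posterior marker-positive probability
#'
#' Probability that a cell belongs to the marker-positive component given
#' its intensity. For \eqn{x > 0} the default (\code{weighted = TRUE})
#' form is the Bayes posterior
#' \eqn{\lambda_2 f_2(x) / (\lambda_1 f_1(x) + \lambda_2 f_2(x))}; the
#' \code{weighted = FALSE} variant drops the mixing proportions and
#' returns \eqn{f_2/(f_1+f_2)}. Cells at exactly zero always receive
#' probability 0. With \code{adjust = TRUE} (default) probabilities are
#' read off the monotonicity-adjusted curves defined on the fit's observed
#' grid ([monotoneAdjust()]); off-grid queries are interpolated
#' monotonically (piecewise linear, clamped to the grid ends).
#'
#' @param fit a converged \linkS4class{MarkerFit}.
#' @param x nonnegative intensities.
#' @param weighted include mixing proportions (default TRUE).
#' @param adjust apply the monotonicity correction (default TRUE).
#' @param ... unused.
#' @return probabilities in [0, 1], same length as \code{x}.
#' @export
#' @rdname posteriorProb
setMethod("posteriorProb", "MarkerFit",
  function(fit, x, weighted = TRUE, adjust = TRUE, ...) {
    .assertConverged(fit)
    if (any(x < 0)) stopc("mifGate_domain_error", "intensities must be >= 0")
    out <- numeric(length(x))
    posIdx <- which(x > 0)
    if (length(posIdx)) {
      if (adjust) {
        ma <- monotoneAdjust(fit, weighted = weighted)
        if (length(ma$grid) == 1L) {
          out[posIdx] <- ma$posteriorAdj
        } else {
          out[posIdx] <- stats::approx(ma$grid, ma$posteriorAdj, x[posIdx],
                                       rule = 2, ties = "ordered")$y
        }
      } else {
        cur <- .componentCurves(fit, x[posIdx], weighted = weighted)
        out[posIdx] <- cur$g2 / (cur$g1 + cur$g2)
      }
    }
    pmin(pmax(out, 0), 1)
  })

#' Marginal marker-positive probability
#'
#' The marker-positive component's cumulative distribution evaluated at
#' the cell's intensity, \eqn{P(X \le x \mid Z = 2) = F(x; a_2, b_2)}: the
#' probability that a marker-positive cell has expression below \code{x}.
#' Monotone increasing in the intensity by construction; 0 at \eqn{x = 0}.
#'
#' @param fit a converged \linkS4class{MarkerFit}.
#' @param x nonnegative intensities.
#' @param ... unused.
#' @return probabilities in [0, 1].
#' @export
#' @rdname marginalProb
setMethod("marginalProb", "MarkerFit", function(fit, x, ...) {
  .assertConverged(fit)
  if (any(x < 0)) stopc("mifGate_domain_error", "intensities must be >= 0")
  cp <- .positiveComp(fit)
  ifelse(x > 0, stats::pgamma(x, shape = cp@shape, scale = cp@scale), 0)
})

#' Mixture density of the positive part
#'
#' \eqn{\lambda_1 f_1(x) + \lambda_2 f_2(x)}; integrates to
#' \eqn{\lambda_1 + \lambda_2} over the positive axis.
#'
#' @param fit a \linkS4class{MarkerFit} with a fitted mixture.
#' @param grid evaluation points.
#' @return density values.
#' @export
mixtureDensity <- function(fit, grid) {
  if (is.null(fit@mixture))
    stopc("mifGate_nonconvergence_error", "no mixture was fitted")
  cur <- .componentCurves(fit, grid, weighted = TRUE)
  cur$g1 + cur$g2
}

# ---- batch fitting --------------------------------------------------------

.fitKey <- function(slide, channel) paste(slide, channel, sep = ".")

#' Fit all (slide, channel) strata of a CellTable
#'
#' Fits [fitMarker()] independently to every slide and requested channel.
#' Strata are independent by construction: results are identical whatever
#' the execution order, and removing one slide never changes another
#' slide's fit. Failures (too few positive cells, EM nonconvergence) are
#' recorded per stratum, never fatal.
#'
#' @param ct a \linkS4class{CellTable}; the \code{"normexpr"} assay is
#'   used when present (see [normalizeMeanLog10()]), else raw intensities.
#' @param channels channels to fit (default all).
#' @param constraints either one list of two \linkS4class{ModeConstraint}s
#'   applied to every channel, or a named list of such lists per channel
#'   (see [readConstraints()]).
#' @param assay assay name override.
#' @param ... passed to [fitMarker()]/[emFitGamma()].
#' @return a \linkS4class{MarkerFitSet}.
#' @export
fitBatch <- function(ct, channels = markerNames(ct),
                     constraints = list(unconstrained(), unconstrained()),
                     assay = NULL, ...) {
  stopifnot(is(ct, "CellTable"))
  miss <- setdiff(channels, markerNames(ct))
  if (length(miss))
    stopc("mifGate_schema_error", "channel(s) not in table: %s",
          paste(miss, collapse = ", "))
  perChannel <- !is.null(names(constraints)) &&
    all(channels %in% names(constraints))
  fits <- list()
  for (ch in channels) {
    cstr <- if (perChannel) constraints[[ch]] else constraints
    for (s in slideIds(ct)) {
      v <- channelValues(ct, ch, slide = s, assay = assay)
      fits[[.fitKey(s, ch)]] <-
        fitMarker(v, constraints = cstr, slide = s, channel = ch, ...)
    }
  }
  new("MarkerFitSet", fits = fits)
}

#' Number of fits in a MarkerFitSet
#' @param x a MarkerFitSet.
#' @export
setMethod("length", "MarkerFitSet", function(x) length(x@fits))

#' Extract one fit by slide and channel
#' @param fits a MarkerFitSet.
#' @param slide,channel stratum identifiers.
#' @export
getFit <- function(fits, slide, channel) {
  f <- fits@fits[[.fitKey(slide, channel)]]
  if (is.null(f))
    stopc("mifGate_schema_error", "no fit for (%s, %s)", slide, channel)
  f
}

#' Per-fit quality-control table
#'
#' One row per (slide, channel) stratum with the component modes, mixing
#' proportions, convergence flag and active constraints — the data behind
#' the mode-versus-lambda diagnostic scatter used to spot outlier slides
#' in the fit-diagnose-refit loop. Nonconverged strata keep their row with
#' missing parameter fields.
#'
#' @param fits a \linkS4class{MarkerFitSet}.
#' @param ... unused.
#' @return a data.frame.
#' @export
#' @rdname qcSummary
setMethod("qcSummary", "MarkerFitSet", function(fits, ...) {
  if (length(fits@fits) == 0L)
    stopc("mifGate_empty_input_error", "no fits to summarize")
  rows <- lapply(fits@fits, function(f) {
    ok <- f@converged && !is.null(f@mixture)
    m <- if (ok) modes(f) else c(NA_real_, NA_real_)
    act <- if (ok)
      vapply(f@mixture@components, function(cp) cp@constraintActive,
             character(1))
    else c(NA_character_, NA_character_)
    data.frame(slide = f@slide, channel = f@channel,
               mode1 = m[1L], mode2 = m[2L],
               lambda0 = f@lambda[["zero"]],
               lambda1 = if (ok) f@lambda[["negative"]] else NA_real_,
               lambda2 = if (ok) f@lambda[["positive"]] else NA_real_,
               nCells = f@nCells, nZero = f@nZero,
               converged = f@converged,
               constraint1 = act[1L], constraint2 = act[2L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
})

#' Convergence report for a batch of fits
#'
#' @param fits a \linkS4class{MarkerFitSet}.
#' @return data.frame of the nonconverged strata (slide, channel, reason);
#'   zero rows when everything converged.
#' @export
convergenceReport <- function(fits) {
  qc <- qcSummary(fits)
  bad <- qc[!qc$converged, c("slide", "channel"), drop = FALSE]
  bad$reason <- vapply(seq_len(nrow(bad)), function(i)
    getFit(fits, bad$slide[i], bad$channel[i])@failure, character(1))
  rownames(bad) <- NULL
  bad
}

#' Extract per-cell gate probabilities for a whole batch
#'
#' Posterior and marginal marker-positive probabilities for every cell and
#' fitted channel. Cells in strata whose fit did not converge receive
#' missing values, so downstream analyses can drop them explicitly.
#'
#' @param fits a \linkS4class{MarkerFitSet} from [fitBatch()].
#' @param ct the \linkS4class{CellTable} the fits came from.
#' @param channels channels to extract (default: all fitted).
#' @param assay assay override (must match the one fitted).
#' @param weighted,adjust see [posteriorProb()].
#' @return long data.frame (slide, cell, channel, posterior, marginal).
#' @export
gateProbabilities <- function(fits, ct, channels = NULL, assay = NULL,
                              weighted = TRUE, adjust = TRUE) {
  cd <- SummarizedExperiment::colData(ct)
  if (is.null(channels))
    channels <- unique(vapply(fits@fits, function(f) f@channel, character(1)))
  res <- list()
  for (ch in channels) {
    for (s in slideIds(ct)) {
      sel <- cd$slide_id == s
      v <- channelValues(ct, ch, slide = s, assay = assay)
      f <- fits@fits[[.fitKey(s, ch)]]
      if (!is.null(f) && f@converged) {
        post <- posteriorProb(f, v, weighted = weighted, adjust = adjust)
        marg <- marginalProb(f, v)
      } else {
        post <- rep(NA_real_, length(v))
        marg <- rep(NA_real_, length(v))
      }
      res[[length(res) + 1L]] <- data.frame(
        slide = s, cell = as.character(cd$cell_id[sel]), channel = ch,
        posterior = post, marginal = marg, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Compare two fits of the same stratum under different constraints
#'
#' Produces aligned component density curves for plotting a refit against
#' its predecessor (the refit step of the fit-diagnose-refit loop).
#'
#' @param fitA,fitB two \linkS4class{MarkerFit}s for the same slide and
#'   channel.
#' @param grid evaluation grid (default: 512 points spanning both fits'
#'   observed values).
#' @return long data.frame (fit, component, x, density).
#' @export
compareFits <- function(fitA, fitB, grid = NULL) {
  if (fitA@slide != fitB@slide || fitA@channel != fitB@channel)
    stopc("mifGate_schema_error",
          "fits are for different strata: (%s, %s) vs (%s, %s)",
          fitA@slide, fitA@channel, fitB@slide, fitB@channel)
  if (is.null(grid)) {
    hi <- max(fitA@grid, fitB@grid)
    grid <- seq(min(fitA@grid, fitB@grid), hi, length.out = 512L)
  }
  one <- function(fit, tag) {
    if (is.null(fit@mixture)) return(NULL)
    cur <- .componentCurves(fit, grid, weighted = TRUE)
    rbind(data.frame(fit = tag, component = "negative", x = grid,
                     density = cur$g1),
          data.frame(fit = tag, component = "positive", x = grid,
                     density = cur$g2))
  }
  out <- rbind(one(fitA, "A"), one(fitB, "B"))
  rownames(out) <- NULL
  out
}

setMethod("show", "MarkerFit", function(object) {
  cat(sprintf("MarkerFit (%s, %s): n = %d cells (%d zero), %s\n",
              object@slide, object@channel, object@nCells, object@nZero,
              if (object@converged) "converged"
              else paste0("NOT converged [", object@failure, "]")))
  cat(sprintf("  lambda: zero %.3f, negative %.3f, positive %.3f\n",
              object@lambda[["zero"]], object@lambda[["negative"]],
              object@lambda[["positive"]]))
  if (!is.null(object@mixture) && object@converged) {
    m <- modes(object)
    cat(sprintf("  modes: negative %.4g, positive %.4g\n", m[1L], m[2L]))
  }
})

setMethod("show", "MarkerFitSet", function(object) {
  nBad <- sum(!vapply(object@fits, function(f) f@converged, logical(1)))
  cat(sprintf("MarkerFitSet: %d fits (%d nonconverged)\n",
              length(object@fits), nBad))
})
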