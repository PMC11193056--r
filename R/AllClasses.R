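#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' CellTable: segmented cell-level marker intensities
#'
#' A \linkS4class{SummarizedExperiment} holding one row per marker channel
#' and one column per segmented cell. The \code{"intensity"} assay stores
#' nonnegative raw (or pre-normalized) intensities; \code{colData} carries
#' the slide identifier, the within-slide cell identifier and, optionally,
#' planar centroid coordinates (\code{x}, \code{y}, any consistent length
#' unit) and a categorical \code{region} label (e.g. epithelium/stroma or a
#' tumor mask).
#'
#' Validity requires: all intensities finite and \eqn{\ge 0}; the
#' (slide, cell) key unique; \code{x} present iff \code{y} is, both finite.
#'
#' @seealso [CellTable()], [readCellTable()], [normalizeMeanLog10()]
#' @export
setClass("CellTable", contains = "SummarizedExperiment")

setValidity("CellTable", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("slide_id", "cell_id") %in% colnames(cd)))
    return("colData must contain 'slide_id' and 'cell_id'")
  key <- paste(cd$slide_id, cd$cell_id, sep = "\r")
  if (anyDuplicated(key))
    return("(slide_id, cell_id) pairs must be unique")
  if (xor("x" %in% colnames(cd), "y" %in% colnames(cd)))
    return("coordinates must provide both 'x' and 'y' or neither")
  if ("x" %in% colnames(cd) &&
      (!all(is.finite(cd$x)) || !all(is.finite(cd$y))))
    return("cell coordinates must be finite")
  for (a in SummarizedExperiment::assayNames(object)) {
    m <- SummarizedExperiment::assay(object, a)
    if (!all(is.finite(m)))
      return(sprintf("assay '%s' contains non-finite values", a))
    if (a == "intensity" && any(m < 0))
      return("marker intensities must be nonnegative")
  }
  TRUE
})

#' ModeConstraint: admissible interval for a gamma-component mode
#'
#' Constrains the mode \eqn{m = (a-1)b} of one mixture component to lie in
#' \code{(lower, upper)}. A constraint may be specified directly
#' (\code{kind = "fixed"}) or as quantiles of the positive intensity
#' distribution (\code{kind = "quantile"}), in which case it must be
#' resolved against a sample with [resolveConstraint()] before fitting.
#'
#' @slot lower,upper numeric bounds, \code{lower < upper}; use \code{0} /
#'   \code{Inf} for open sides. For quantile constraints these hold the
#'   probabilities (\code{NA} for an open side).
#' @slot kind \code{"fixed"} or \code{"quantile"}.
#' @slot cap absolute ceiling applied to the resolved lower bound of a
#'   quantile constraint (default \code{Inf}); lets a data-driven elbow be
#'   bounded by prior knowledge of where expressed modes can start.
#' @slot inflate multiplier applied to the resolved lower bound of a
#'   quantile constraint (default 1); values above 1 deliberately shift a
#'   data-driven elbow upward, as in the inaccurate constraint scenario.
#' @export
setClass("ModeConstraint",
  representation(lower = "numeric", upper = "numeric", kind = "character",
                 cap = "numeric", inflate = "numeric"),
  prototype(lower = 0, upper = Inf, kind = "fixed", cap = Inf, inflate = 1))

setValidity("ModeConstraint", function(object) {
  if (length(object@lower) != 1L || length(object@upper) != 1L)
    return("bounds must be scalars")
  if (!object@kind %in% c("fixed", "quantile"))
    return("kind must be 'fixed' or 'quantile'")
  if (object@kind == "fixed") {
    if (is.na(object@lower) || is.na(object@upper))
      return("fixed bounds may not be NA (use 0/Inf for open sides)")
    if (object@lower < 0) return("lower bound must be nonnegative")
    if (object@lower >= object@upper) return("need lower < upper")
  } else {
    for (p in c(object@lower, object@upper))
      if (!is.na(p) && (p < 0 || p > 1))
        return("quantile probabilities must lie in [0, 1]")
    if (!is.na(object@lower) && !is.na(object@upper) &&
        object@lower >= object@upper)
      return("need lower quantile < upper quantile")
  }
  TRUE
})

#' GammaComponent: one gamma mixture component
#'
#' @slot shape,scale positive gamma parameters (scale parametrization).
#' @slot constraintActive \code{"none"}, \code{"lower"} or \code{"upper"}:
#'   whether the component sits on a mode-constraint boundary.
#' @export
setClass("GammaComponent",
  representation(shape = "numeric", scale = "numeric",
                 constraintActive = "character"),
  prototype(constraintActive = "none"))

setValidity("GammaComponent", function(object) {
  if (!is.finite(object@shape) || object@shape <= 0) return("shape must be > 0")
  if (!is.finite(object@scale) || object@scale <= 0) return("scale must be > 0")
  if (!object@constraintActive %in% c("none", "lower", "upper"))
    return("constraintActive must be none/lower/upper")
  TRUE
})

#' MixtureFit: a fitted K-component gamma mixture on positive values
#'
#' @slot components list of \linkS4class{GammaComponent}, ordered so that
#'   component modes are increasing (the last component is marker-positive).
#' @slot weights mixing proportions over the positive part (sum to 1).
#' @slot loglikTrace observed-data log-likelihood per EM iteration.
#' @slot converged,nIter convergence flag and iteration count.
#' @slot failure reason for nonconvergence (NA when converged).
#' @export
setClass("MixtureFit",
  representation(components = "list", weights = "numeric",
                 loglikTrace = "numeric", converged = "logical",
                 nIter = "integer", failure = "character"),
  prototype(failure = NA_character_))

setValidity("MixtureFit", function(object) {
  if (length(object@components) != length(object@weights))
    return("one weight per component required")
  if (any(object@weights < -1e-12))
    return("weights must be nonnegative")
  if (abs(sum(object@weights) - 1) > 1e-8)
    return("weights must sum to 1")
  TRUE
})

setClassUnion("MixtureFitOrNULL", c("MixtureFit", "NULL"))

#' MarkerFit: zero-inflated gamma mixture fit for one (slide, channel)
#'
#' The zero-inflated model places probability \code{lambda[“zero”]} on
#' exact zeros (set to the empirical zero fraction) and splits the
#' remaining mass between the marker-negative (\code{"negative"}) and
#' marker-positive (\code{"positive"}) gamma components of \code{mixture}.
#'
#' @slot slide,channel identifiers of the fitted stratum.
#' @slot lambda named numeric: \code{zero}, \code{negative},
#'   \code{positive}; sums to 1.
#' @slot mixture the \linkS4class{MixtureFit} on positive values, or
#'   \code{NULL} when the fit was not attempted.
#' @slot grid sorted unique positive values observed in the stratum; the
#'   lattice on which the monotonicity adjustment is defined.
#' @slot nCells,nZero cell counts.
#' @slot converged logical; \code{failure} holds a reason when FALSE.
#' @export
setClass("MarkerFit",
  representation(slide = "character", channel = "character",
                 lambda = "numeric", mixture = "MixtureFitOrNULL",
                 grid = "numeric", nCells = "integer", nZero = "integer",
                 converged = "logical", failure = "character"),
  prototype(failure = NA_character_))

setValidity("MarkerFit", function(object) {
  if (!identical(names(object@lambda), c("zero", "negative", "positive")))
    return("lambda must be named (zero, negative, positive)")
  if (any(object@lambda < -1e-12) || abs(sum(object@lambda) - 1) > 1e-8)
    return("lambda must be nonnegative and sum to 1")
  if (object@nZero > object@nCells)
    return("nZero cannot exceed nCells")
  TRUE
})

#' MarkerFitSet: fits for many (slide, channel) strata
#'
#' A simple container for the per-stratum \linkS4class{MarkerFit} objects
#' produced by [fitBatch()]. Fits are independent: removing one stratum
#' never changes another stratum's fit.
#'
#' @slot fits named list of \linkS4class{MarkerFit} (names
#'   \code{"slide.channel"}).
#' @export
setClass("MarkerFitSet", representation(fits = "list"))

setValidity("MarkerFitSet", function(object) {
  if (!all(vapply(object@fits, is, logical(1), class2 = "MarkerFit")))
    return("all elements must be MarkerFit objects")
  TRUE
})
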