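#' @rdname posteriorProb
#' @export
setGeneric("posteriorProb", function(fit, x, ...) standardGeneric("posteriorProb"))

#' @rdname marginalProb
#' @export
setGeneric("marginalProb", function(fit, x, ...) standardGeneric("marginalProb"))

#' @rdname qcSummary
#' @export
setGeneric("qcSummary", function(fits, ...) standardGeneric("qcSummary"))

#' Component modes of a fit
#'
#' Mode of a gamma component, \eqn{m = (a-1)b} for shape \eqn{a > 1} and 0
#' otherwise; for mixtures and marker fits, the vector of component modes
#' in component order.
#'
#' @param object a GammaComponent, MixtureFit or MarkerFit.
#' @return numeric vector of modes.
#' @export
setGeneric("modes", function(object) standardGeneric("modes"))

#' Mixing proportions
#'
#' @param object a MixtureFit (proportions over the positive part) or
#'   MarkerFit (named zero/negative/positive proportions over all cells).
#' @return numeric vector.
#' @export
setGeneric("mixWeights", function(object) standardGeneric("mixWeights"))

#' @rdname normalizeMeanLog10
#' @export
setGeneric("normalizeMeanLog10", function(x, ...) standardGeneric("normalizeMeanLog10"))
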