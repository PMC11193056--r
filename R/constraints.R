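#' Create a mode constraint
#'
#' @param lower,upper bounds for the component mode \eqn{(a-1)b}. For
#'   \code{kind = "fixed"} these are intensities (0 / \code{Inf} leave a
#'   side open); for \code{kind = "quantile"} they are probabilities in
#'   [0, 1] resolved against the positive intensity distribution of the
#'   stratum being fitted (NA leaves a side open).
#' @param kind \code{"fixed"} (default) or \code{"quantile"}.
#' @param cap for quantile constraints, an absolute ceiling on the
#'   resolved lower bound (default none): however high the empirical
#'   elbow lands, the bound never exceeds \code{cap}, so prior knowledge
#'   of where expressed modes can start is respected.
#' @param inflate for quantile constraints, a multiplier on the resolved
#'   lower bound (default 1); above 1 it shifts the data-driven elbow
#'   deliberately upward.
#' @return a \linkS4class{ModeConstraint}.
#' @examples
#' ModeConstraint(lower = 0.45)                   # m >= 0.45
#' ModeConstraint(lower = 0.95, kind = "quantile")
#' @export
ModeConstraint <- function(lower = 0, upper = Inf, kind = "fixed",
                           cap = Inf, inflate = 1) {
  if (kind == "quantile") {
    if (missing(lower)) lower <- NA_real_
    if (missing(upper)) upper <- NA_real_
  }
  new("ModeConstraint", lower = as.numeric(lower), upper = as.numeric(upper),
      kind = kind, cap = as.numeric(cap), inflate = as.numeric(inflate))
}

#' An unconstrained mode interval
#' @export
unconstrained <- function() ModeConstraint(0, Inf)

#' Resolve a quantile constraint against observed values
#'
#' Quantile-specified bounds are converted to fixed intensities using the
#' empirical quantiles of the supplied (positive) values; fixed constraints
#' are returned unchanged. Resolution happens once, before the first
#' E-step, so the interval does not move during EM.
#'
#' @param constraint a \linkS4class{ModeConstraint}.
#' @param values positive intensities of the stratum being fitted.
#' @return a fixed \linkS4class{ModeConstraint}.
#' @export
resolveConstraint <- function(constraint, values) {
  if (constraint@kind == "fixed") return(constraint)
  lo <- if (is.na(constraint@lower)) 0
        else as.numeric(stats::quantile(values, constraint@lower, names = FALSE))
  up <- if (is.na(constraint@upper)) Inf
        else as.numeric(stats::quantile(values, constraint@upper, names = FALSE))
  ModeConstraint(min(lo * constraint@inflate, constraint@cap), up)
}

#' Read per-channel mode constraints from YAML
#'
#' The file maps channel names to two component entries, each either
#' \code{fixed: [l, u]} or \code{quantile: [ql, qu]} with \code{null} for
#' an open side, e.g.
#' \preformatted{
#' CD4:
#'   - fixed: [null, 0.3]
#'   - fixed: [0.45, null]
#' }
#'
#' @param path YAML file path.
#' @return named list; each element a list of two
#'   \linkS4class{ModeConstraint}s (negative, positive component).
#' @export
readConstraints <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(chan) {
    if (length(chan) != 2L)
      stopc("mifGate_schema_error",
            "each channel needs exactly two component constraints")
    lapply(chan, function(comp) {
      kind <- names(comp)[1L]
      if (!kind %in% c("fixed", "quantile"))
        stopc("mifGate_schema_error", "constraint kind must be fixed/quantile")
      b <- comp[[1L]]
      lo <- if (is.null(b[[1L]])) { if (kind == "fixed") 0 else NA_real_ } else b[[1L]]
      up <- if (is.null(b[[2L]])) { if (kind == "fixed") Inf else NA_real_ } else b[[2L]]
      ModeConstraint(lo, up, kind = kind)
    })
  })
}

setMethod("show", "ModeConstraint", function(object) {
  cat(sprintf("ModeConstraint<%s>: (%s, %s)\n", object@kind,
              format(object@lower), format(object@upper)))
})
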