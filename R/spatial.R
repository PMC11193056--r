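#' Soft cell-population proportion from posterior probabilities
#'
#' Instead of dichotomizing cells, the proportion of a marker-positive
#' population within a region is estimated as the arithmetic mean of the
#' per-cell posterior marker-positive probabilities over the cells in the
#' region, \eqn{\sum_i P(Z = 2 \mid X = x_i)/n}. With the
#' \eqn{\lambda}-weighted posterior this mean is a consistent estimator of
#' the marker-positive mixing proportion.
#'
#' @param posteriors per-cell probabilities in [0, 1] (NA allowed when
#'   \code{na.rm = TRUE}).
#' @param mask logical region membership per cell (default: all).
#' @param na.rm drop missing probabilities (from nonconverged fits)?
#' @return proportion in [0, 1].
#' @export
meanPosteriorProportion <- function(posteriors, mask = NULL, na.rm = FALSE) {
  if (is.null(mask)) mask <- rep(TRUE, length(posteriors))
  if (length(mask) != length(posteriors))
    stopc("mifGate_domain_error", "mask and posteriors lengths differ")
  sel <- posteriors[mask]
  if (length(sel) == 0L)
    stopc("mifGate_empty_input_error", "mask selects no cells")
  ok <- !is.na(sel)
  if (any(sel[ok] < 0 | sel[ok] > 1))
    stopc("mifGate_domain_error", "posteriors must lie in [0, 1]")
  mean(sel, na.rm = na.rm)
}

.checkWindow <- function(x, y, window) {
  if (is.null(window)) window <- c(min(x), max(x), min(y), max(y))
  if (length(window) != 4L || window[2L] <= window[1L] ||
      window[4L] <= window[3L])
    stopc("mifGate_domain_error",
          "window must be c(xmin, xmax, ymin, ymax) with positive area")
  if (any(x < window[1L] | x > window[2L] | y < window[3L] | y > window[4L]))
    stopc("mifGate_domain_error", "points fall outside the window")
  window
}

# Pairwise |dx|, |dy| and distances between two point sets.
.pairGeom <- function(x1, y1, x2, y2) {
  dx <- abs(outer(x1, x2, `-`))
  dy <- abs(outer(y1, y2, `-`))
  list(dx = dx, dy = dy, d = sqrt(dx^2 + dy^2))
}

#' Ripley's K function on a rectangular window
#'
#' Estimates Ripley's K for a univariate point pattern, or the cross-type
#' K between two patterns, at the given radii. Available edge corrections:
#' \code{"translation"} (default; exactly symmetric between types),
#' \code{"border"} (minus sampling) and \code{"none"} (the naive
#' \eqn{(A/(n(n-1)))\sum_{i \ne j} 1\{d_{ij} \le r\}}).
#' Radii exceeding half the window's shorter side are dropped with a
#' warning.
#'
#' @param x,y point coordinates.
#' @param r increasing positive radii.
#' @param window \code{c(xmin, xmax, ymin, ymax)}; default the bounding
#'   box of all points (pass the true region geometry when known).
#' @param correction \code{"translation"}, \code{"border"} or
#'   \code{"none"}.
#' @param x2,y2 optional second point set for cross-type K.
#' @return data.frame with columns \code{r} and \code{K}.
#' @export
ripleyK <- function(x, y, r, window = NULL,
                    correction = c("translation", "border", "none"),
                    x2 = NULL, y2 = NULL) {
  correction <- match.arg(correction)
  cross <- !is.null(x2)
  if (length(x) < 2L || (cross && length(x2) < 1L))
    stopc("mifGate_empty_input_error", "need >= 2 points (>= 1 per type)")
  if (is.unsorted(r) || any(r <= 0))
    stopc("mifGate_domain_error", "radii must be positive and increasing")
  allx <- c(x, x2); ally <- c(y, y2)
  window <- .checkWindow(allx, ally, window)
  ax <- window[2L] - window[1L]; ay <- window[4L] - window[3L]
  A <- ax * ay
  rmax <- min(ax, ay) / 2
  if (any(r > rmax)) {
    warning(sprintf("dropping %d radii exceeding half the shorter side (%g)",
                    sum(r > rmax), rmax))
    r <- r[r <= rmax]
    if (!length(r))
      stopc("mifGate_domain_error", "no usable radii left")
  }
  if (!cross) { x2 <- x; y2 <- y }
  g <- .pairGeom(x, y, x2, y2)
  self <- if (!cross) diag(length(x)) == 1 else
    matrix(FALSE, length(x), length(x2))
  npairs <- if (!cross) length(x) * (length(x) - 1) else
    length(x) * length(x2)
  K <- vapply(r, function(ri) {
    hit <- g$d <= ri & !self
    switch(correction,
      none = A * sum(hit) / npairs,
      translation = {
        w <- A / ((ax - g$dx) * (ay - g$dy))
        A * sum(w[hit]) / npairs
      },
      border = {
        b <- pmin(x - window[1L], window[2L] - x,
                  y - window[3L], window[4L] - y)
        keep <- b >= ri
        if (!any(keep)) return(NA_real_)
        lambda2 <- length(x2) / A
        sum(hit[keep, , drop = FALSE]) / (lambda2 * sum(keep))
      })
  }, numeric(1))
  data.frame(r = r, K = K)
}

#' Ripley's H (centred L) function
#'
#' \eqn{H(r) = L(r) - r} with \eqn{L(r) = \sqrt{K(r)/\pi}}. Under complete
#' spatial randomness \eqn{H \approx 0}; positive values indicate spatial
#' attraction (clustering, or cross-type attraction for two types),
#' negative values repulsion. The usual per-slide scalar summary over a
#' radius range is the mean of \eqn{H} across the evaluated radii
#' ([meanH()]).
#'
#' @inheritParams ripleyK
#' @return data.frame with columns \code{r}, \code{K}, \code{L}, \code{H}.
#' @export
ripleyH <- function(x, y, r, window = NULL,
                    correction = c("translation", "border", "none"),
                    x2 = NULL, y2 = NULL) {
  out <- ripleyK(x, y, r, window = window, correction = correction,
                 x2 = x2, y2 = y2)
  out$L <- sqrt(out$K / pi)
  out$H <- out$L - out$r
  out
}

#' Average an H curve across radii
#'
#' @param curve numeric vector of H values, or a data.frame from
#'   [ripleyH()].
#' @return scalar mean H.
#' @export
meanH <- function(curve) {
  h <- if (is.data.frame(curve)) curve$H else curve
  if (length(h) == 0L)
    stopc("mifGate_empty_input_error", "empty H curve")
  mean(h)
}

#' Radius grid for H-curve summaries
#'
#' Evenly spaced radii on (0, rmax], the default discretization used when
#' averaging H over a radius range.
#'
#' @param rmax largest radius (same length unit as the coordinates).
#' @param n number of radii (default 50).
#' @export
radiusGrid <- function(rmax, n = 50L) seq(rmax / n, rmax, length.out = n)
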