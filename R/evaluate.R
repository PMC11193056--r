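#' Threshold probabilities into marker-positive calls
#'
#' A cell is called marker-positive when its probability is at least
#' \code{t} (ties positive). Missing probabilities — cells from
#' nonconverged fits — yield missing calls so they can be excluded
#' downstream.
#'
#' @param probabilities per-cell probabilities in [0, 1] or NA.
#' @param t threshold in [0, 1] (default 0.5).
#' @return logical vector (NA where the probability was missing).
#' @export
thresholdPositive <- function(probabilities, t = 0.5) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1)
    stopc("mifGate_domain_error", "threshold must lie in [0, 1]")
  ok <- !is.na(probabilities)
  if (any(probabilities[ok] < 0 | probabilities[ok] > 1))
    stopc("mifGate_domain_error", "probabilities must lie in [0, 1]")
  probabilities >= t
}

#' Assemble phenotypes from marker-positive calls
#'
#' Each cell is labeled with the first phenotype definition it matches: a
#' definition requires all of its \code{positive} channels called positive
#' and all of its \code{negative} channels called negative. Cells matching
#' no definition are labeled \code{"other"}; a missing call in a
#' definition's channel makes that cell's label missing.
#'
#' @param calls logical cell-by-channel matrix (column names = channels).
#' @param definitions list of definitions, each a list with \code{name},
#'   \code{positive} (character, nonempty) and optional \code{negative};
#'   earlier definitions take priority on overlap.
#' @return character vector of per-cell phenotype labels.
#' @export
assemblePhenotypes <- function(calls, definitions) {
  if (is.null(colnames(calls)))
    stopc("mifGate_schema_error", "call matrix needs channel column names")
  n <- nrow(calls)
  labels <- rep("other", n)
  done <- rep(FALSE, n)       # a definition already claimed the cell
  naSeen <- rep(FALSE, n)     # an unevaluable definition blocks priority
  for (def in definitions) {
    pos <- def$positive
    neg <- def$negative %||% character(0)
    if (is.null(def$name) || length(pos) == 0L)
      stopc("mifGate_schema_error",
            "each definition needs a name and >= 1 positive channel")
    if (length(intersect(pos, neg)))
      stopc("mifGate_schema_error",
            "definition '%s': positive and negative sets overlap", def$name)
    miss <- setdiff(c(pos, neg), colnames(calls))
    if (length(miss))
      stopc("mifGate_schema_error",
            "definition '%s' references absent channel(s): %s",
            def$name, paste(miss, collapse = ", "))
    m <- rep(TRUE, n)
    for (ch in pos) m <- m & calls[, ch]
    for (ch in neg) m <- m & !calls[, ch]
    hit <- !done & !naSeen & !is.na(m) & m
    labels[hit] <- def$name
    done <- done | hit
    naSeen <- naSeen | (!done & is.na(m))
  }
  labels[naSeen & !done] <- NA_character_
  labels
}

#' Adjusted Rand Index
#'
#' Chance-corrected agreement between two categorical labelings
#' (Hubert-Arabie form), computed from the pair-count contingency table:
#' 1 for identical partitions, expectation about 0 for independent ones.
#' Pairs with a missing label in either vector are dropped listwise.
#'
#' @param labelsA,labelsB equal-length label vectors.
#' @return scalar ARI.
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c(1, 2, 1, 2))   # -0.5
#' @export
adjustedRandIndex <- function(labelsA, labelsB) {
  if (length(labelsA) != length(labelsB))
    stopc("mifGate_domain_error", "label vectors must have equal length")
  keep <- !is.na(labelsA) & !is.na(labelsB)
  a <- labelsA[keep]; b <- labelsB[keep]
  if (length(a) < 2L)
    stopc("mifGate_empty_input_error", "need >= 2 non-missing label pairs")
  tab <- table(a, b)
  n <- length(a)
  sumIJ <- sum(choose(tab, 2))
  sumA <- sum(choose(rowSums(tab), 2))
  sumB <- sum(choose(colSums(tab), 2))
  expected <- sumA * sumB / choose(n, 2)
  maxIdx <- (sumA + sumB) / 2
  if (maxIdx == expected) return(if (sumIJ == expected) 1 else 0)
  (sumIJ - expected) / (maxIdx - expected)
}

#' Evaluate fits against simulation ground truth
#'
#' Per-slide comparison of a fitted batch with the generating truth of a
#' [simulateSlides()] dataset: estimated marker-positive proportion
#' \eqn{\hat\lambda_2}, its bias against the generating expressed
#' fraction, and the Adjusted Rand Index between thresholded adjusted
#' posterior calls and the true labels. Nonconverged fits keep their row
#' with missing metrics and are excluded from the summary means, with the
#' failure count reported.
#'
#' @param fits \linkS4class{MarkerFitSet} fitted on the simulated table.
#' @param sim the simulated \linkS4class{CellTable} (with \code{truth}).
#' @param threshold probability threshold for positive calls.
#' @param ariLabels \code{"binary"} (expressed vs not, default) or
#'   \code{"three"} (zero / unexpressed / expressed truth).
#' @param weighted,adjust posterior variant, see [posteriorProb()].
#' @return list with \code{perSlide} (data.frame: slide, lambda2, trueP,
#'   bias, ari, converged), \code{meanBias}, \code{meanARI},
#'   \code{nFailed}.
#' @export
simulationReport <- function(fits, sim, threshold = 0.5,
                             ariLabels = c("binary", "three"),
                             weighted = TRUE, adjust = TRUE) {
  ariLabels <- match.arg(ariLabels)
  cd <- SummarizedExperiment::colData(sim)
  if (is.null(cd$truth))
    stopc("mifGate_schema_error", "simulation table lacks a 'truth' column")
  pExp <- S4Vectors::metadata(sim)$params$pExpressed
  rows <- lapply(slideIds(sim), function(s) {
    sel <- cd$slide_id == s
    f <- fits@fits[[.fitKey(s, "marker")]]
    if (is.null(f))
      stopc("mifGate_schema_error", "no fit for simulated slide %s", s)
    trueP <- pExp[match(s, S4Vectors::metadata(sim)$params$slide)]
    if (!f@converged)
      return(data.frame(slide = s, lambda2 = NA_real_, trueP = trueP,
                        bias = NA_real_, ari = NA_real_, converged = FALSE))
    v <- channelValues(sim, "marker", slide = s, assay = "intensity")
    post <- posteriorProb(f, v, weighted = weighted, adjust = adjust)
    call <- thresholdPositive(post, threshold)
    tr <- cd$truth[sel]
    truthLab <- if (ariLabels == "binary") as.integer(tr == 2L) else tr
    lam2 <- f@lambda[["positive"]]
    data.frame(slide = s, lambda2 = lam2, trueP = trueP,
               bias = lam2 - trueP,
               ari = adjustedRandIndex(as.integer(call), truthLab),
               converged = TRUE)
  })
  perSlide <- do.call(rbind, rows)
  rownames(perSlide) <- NULL
  list(perSlide = perSlide,
       meanBias = mean(perSlide$bias[perSlide$converged]),
       meanARI = mean(perSlide$ari[perSlide$converged]),
       nFailed = sum(!perSlide$converged))
}
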