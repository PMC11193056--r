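#' Construct a CellTable from per-cell marker intensities
#'
#' @param intensities numeric matrix or data.frame of nonnegative marker
#'   intensities, one row per cell, one column per marker channel.
#' @param slide,cell slide identifiers and within-slide cell identifiers
#'   (recycled \code{cell} defaults to the row index).
#' @param x,y optional planar centroid coordinates (both or neither).
#' @param region optional categorical compartment label per cell.
#' @return a validated \linkS4class{CellTable}.
#' @examples
#' ct <- CellTable(cbind(CD3 = c(0, 1.2, 0.4), CD68 = c(0.1, 0, 2)),
#'                 slide = "s1")
#' markerNames(ct)
#' @export
CellTable <- function(intensities, slide, cell = NULL, x = NULL, y = NULL,
                      region = NULL) {
  m <- as.matrix(intensities)
  storage.mode(m) <- "double"
  if (is.null(colnames(m)))
    colnames(m) <- paste0("marker", seq_len(ncol(m)))
  n <- nrow(m)
  slide <- as.character(rep_len(slide, n))
  cell <- if (is.null(cell)) as.character(seq_len(n)) else as.character(cell)
  cd <- S4Vectors::DataFrame(slide_id = slide, cell_id = cell)
  if (!is.null(x) || !is.null(y)) {
    if (is.null(x) || is.null(y))
      stopc("mifGate_schema_error", "provide both 'x' and 'y' or neither")
    cd$x <- as.numeric(x); cd$y <- as.numeric(y)
  }
  if (!is.null(region)) cd$region <- as.character(region)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = t(m)), colData = cd)
  new("CellTable", se)
}

.checkIntensityBlock <- function(m, channels, rowOffset = 0L) {
  bad <- !is.finite(m) | m < 0
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    stopc("mifGate_validation_error",
          paste0("%d cell(s) carry negative or non-finite intensities; ",
                 "first offence: row %d, column '%s'"),
          length(unique(idx[, 1L])), idx[1L, 1L] + rowOffset,
          channels[idx[1L, 2L]])
  }
  invisible(TRUE)
}

#' Read a segmented cell quantification table
#'
#' Reads a CSV/TSV with one row per cell and maps its columns onto the
#' \linkS4class{CellTable} model via a schema: a list (or YAML file) with
#' entries \code{slide}, \code{cell}, optional \code{x}, \code{y},
#' \code{region}, and \code{markers} (character vector of intensity column
#' names). Rows carrying negative or non-finite intensities are an error;
#' the message reports the offending row, column and count.
#'
#' @param path path to a delimited text file.
#' @param schema named list or path to a YAML file as above.
#' @param sep field separator; guessed from the extension when NULL
#'   (\code{.tsv}/\code{.txt} tab, otherwise comma).
#' @return a validated \linkS4class{CellTable}.
#' @export
readCellTable <- function(path, schema, sep = NULL) {
  if (!file.exists(path))
    stopc("mifGate_io_error", "file not found: %s", path)
  if (is.character(schema) && length(schema) == 1L) {
    schema <- yaml::read_yaml(schema)
    # a bare y: key is a YAML 1.1 boolean; map it back
    names(schema)[names(schema) == "TRUE"] <- "y"
  }
  if (is.null(schema$slide) || is.null(schema$markers))
    stopc("mifGate_schema_error", "schema must name 'slide' and 'markers'")
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c(schema$slide, schema$cell, schema$x, schema$y, schema$region,
              schema$markers)
  missing <- setdiff(needed, colnames(df))
  if (length(missing))
    stopc("mifGate_schema_error", "mapped column(s) absent from file: %s",
          paste(missing, collapse = ", "))
  if (nrow(df) == 0L)
    stopc("mifGate_empty_input_error", "no cell rows in %s", path)
  m <- as.matrix(df[, schema$markers, drop = FALSE])
  storage.mode(m) <- "double"
  .checkIntensityBlock(m, schema$markers)
  slide <- df[[schema$slide]]
  cell <- if (!is.null(schema$cell)) df[[schema$cell]] else seq_len(nrow(df))
  key <- paste(slide, cell, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stopc("mifGate_key_error", "duplicate (slide, cell) key: (%s)",
          gsub("\r", ", ", d, fixed = TRUE))
  }
  CellTable(m, slide = slide, cell = cell,
            x = if (!is.null(schema$x)) df[[schema$x]],
            y = if (!is.null(schema$y)) df[[schema$y]],
            region = if (!is.null(schema$region)) df[[schema$region]])
}

#' Write a CellTable back to delimited text
#'
#' Inverse of [readCellTable()] with the canonical column names
#' (\code{slide_id}, \code{cell_id}, optional \code{x}/\code{y}/
#' \code{region}, one column per marker). Values round-trip bit-exactly at
#' full double precision.
#'
#' @param ct a \linkS4class{CellTable}.
#' @param path output file path.
#' @param assay assay to write (default \code{"intensity"}).
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
writeCellTable <- function(ct, path, assay = "intensity", sep = ",") {
  cd <- as.data.frame(SummarizedExperiment::colData(ct))
  m <- t(SummarizedExperiment::assay(ct, assay))
  df <- cbind(cd, as.data.frame(m, check.names = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Canonical schema for files written by writeCellTable
#' @param markers marker channel names.
#' @param coords,region include coordinate / region mappings?
#' @return schema list for [readCellTable()].
#' @export
defaultSchema <- function(markers, coords = FALSE, region = FALSE) {
  s <- list(slide = "slide_id", cell = "cell_id", markers = markers)
  if (coords) { s$x <- "x"; s$y <- "y" }
  if (region) s$region <- "region"
  s
}

# ---- accessors ------------------------------------------------------------

#' Marker channel names of a CellTable
#' @param ct a CellTable.
#' @export
markerNames <- function(ct) rownames(ct)

#' Slide identifiers (unique, in order of first appearance)
#' @param ct a CellTable.
#' @export
slideIds <- function(ct) unique(SummarizedExperiment::colData(ct)$slide_id)

#' Extract one channel's per-cell values
#' @param ct a CellTable.
#' @param channel marker channel name.
#' @param slide optional slide to restrict to.
#' @param assay assay name (default the normalized assay when present).
#' @export
channelValues <- function(ct, channel, slide = NULL, assay = NULL) {
  assay <- assay %||%
    (if ("normexpr" %in% SummarizedExperiment::assayNames(ct)) "normexpr"
     else "intensity")
  v <- SummarizedExperiment::assay(ct, assay)[channel, ]
  if (!is.null(slide))
    v <- v[SummarizedExperiment::colData(ct)$slide_id == slide]
  as.numeric(v)
}

# ---- normalization --------------------------------------------------------

#' Slide-level mean-division log10 normalization
#'
#' Normalizes intensities by dividing by the slide-channel mean and then
#' log10-transforming, the standard variance-stabilizing step that reduces
#' slide-to-slide intensity variation before mixture modeling. Because the
#' zero-inflated model carries an exact point mass at zero, the default
#' transform is \code{log10(1 + x/mean(x))}, which maps 0 to exactly 0 and
#' is monotone increasing; \code{offset = FALSE} instead applies
#' \code{log10(x/mean(x))} to positive values and passes zeros through
#' unchanged.
#'
#' @param x numeric vector of nonnegative intensities for one slide and
#'   channel, or a \linkS4class{CellTable}.
#' @param offset logical; use the +1 offset convention (default TRUE).
#' @param ... passed between methods.
#' @return For vectors, the normalized vector (same order). For a
#'   CellTable, the object with a new \code{"normexpr"} assay computed per
#'   slide and per channel.
#' @examples
#' normalizeMeanLog10(c(0, 2, 2, 2))   # zeros stay zero
#' @export
#' @rdname normalizeMeanLog10
setMethod("normalizeMeanLog10", "numeric", function(x, offset = TRUE, ...) {
  if (length(x) == 0L)
    stopc("mifGate_empty_input_error", "empty intensity vector")
  if (any(!is.finite(x)) || any(x < 0))
    stopc("mifGate_validation_error", "intensities must be finite and >= 0")
  mu <- mean(x)
  if (mu <= 0)
    stopc("mifGate_degenerate_slide_error",
          "all-zero slide: mean intensity is 0")
  if (offset) log10(1 + x / mu)
  else ifelse(x > 0, log10(x / mu), 0)
})

#' @rdname normalizeMeanLog10
#' @export
setMethod("normalizeMeanLog10", "CellTable", function(x, offset = TRUE, ...) {
  m <- SummarizedExperiment::assay(x, "intensity")
  slide <- SummarizedExperiment::colData(x)$slide_id
  out <- m
  for (s in unique(slide)) {
    j <- slide == s
    for (i in seq_len(nrow(m)))
      out[i, j] <- normalizeMeanLog10(as.numeric(m[i, j]), offset = offset)
  }
  SummarizedExperiment::assay(x, "normexpr", withDimnames = FALSE) <- out
  validObject(x)
  x
})
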