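#' SpreadExperiment: biotyped expression matrix for spread-type analyses
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one
#' feature-by-sample expression assay together with a per-feature biotype
#' (\code{rowData(x)$biotype}), the original per-sample library sizes
#' (\code{colData(x)$lib_size}, total raw read counts, fixed at construction
#' and preserved through filtering), and a scale flag recording whether the
#' assay holds raw counts, log-CPM values, or cyclic-loess-normalized log-CPM
#' values.
#'
#' Sample annotations relevant downstream live in \code{colData}: typically
#' \code{patient}, \code{tissue} (one of P, M, A, S: primary ovarian tumor,
#' peritoneal metastasis, ascitic single cells, ascitic spheroids) and
#' \code{spread} (miliary / non-miliary).
#'
#' @slot scale Character flag, one of \code{"raw"}, \code{"log_cpm"},
#'   \code{"loess_normalized"}.
#'
#' @param counts Numeric feature-by-sample matrix (non-negative integers when
#'   \code{scale = "raw"}).
#' @param biotype Character vector, one biotype per feature (see
#'   \code{\link{biotypeLevels}}).
#' @param colData Optional \code{DataFrame} or data.frame of sample
#'   annotations (e.g. patient, tissue, spread).
#' @param libSizes Optional per-sample total read counts; defaults to
#'   \code{colSums(counts)} for raw input. Required when \code{scale} is not
#'   \code{"raw"}.
#' @param scale Scale flag of \code{counts}.
#' @param x A \code{SpreadExperiment}.
#'
#' @return \code{SpreadExperiment()} returns a \code{SpreadExperiment} object.
#'   \code{biotype()} returns the per-feature biotype vector, \code{libSizes()}
#'   the per-sample library sizes, \code{exprScale()} the scale flag.
#'
#' @aliases SpreadExperiment biotype exprScale libSizes
#'   biotype,SpreadExperiment-method exprScale,SpreadExperiment-method
#'   libSizes,SpreadExperiment-method
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
#' @export SpreadExperiment
#' @exportClass SpreadExperiment
#' @examples
#' cnt <- matrix(rpois(40, 50), nrow = 10,
#'               dimnames = list(paste0("f", 1:10), paste0("s", 1:4)))
#' se <- SpreadExperiment(cnt, biotype = rep(c("coding", "miRNA"), each = 5))
#' biotype(se)
#' libSizes(se)
setClass("SpreadExperiment",
  contains = "SummarizedExperiment",
  slots = c(scale = "character"),
  prototype = prototype(scale = "raw")
)

setValidity("SpreadExperiment", function(object) {
  msg <- character()
  if (length(object@scale) != 1L ||
      !object@scale %in% c("raw", "log_cpm", "loess_normalized"))
    msg <- c(msg, "scale must be one of 'raw', 'log_cpm', 'loess_normalized'")
  if (!"biotype" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain a 'biotype' column")
  else if (!all(rowData(object)$biotype %in% biotypeLevels()))
    msg <- c(msg, sprintf("biotype values must be in {%s}",
                          paste(biotypeLevels(), collapse = ", ")))
  if (!"lib_size" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'lib_size' column")
  else if (any(colData(object)$lib_size <= 0))
    msg <- c(msg, "library sizes must be positive")
  if (length(assays(object)) >= 1L) {
    a <- assay(object)
    if (identical(object@scale, "raw") && any(a < 0))
      msg <- c(msg, "raw counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

SpreadExperiment <- function(counts, biotype, colData = NULL, libSizes = NULL,
                             scale = "raw") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("feature%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("sample%03d", seq_len(ncol(counts)))
  if (length(biotype) != nrow(counts))
    stop("'biotype' must have one entry per feature")
  if (is.null(libSizes)) {
    if (!identical(scale, "raw"))
      stop("libSizes must be supplied when counts are not on the raw scale")
    libSizes <- colSums(counts)
  }
  if (any(libSizes <= 0)) stop("library sizes must be positive")
  cd <- if (is.null(colData)) S4Vectors::DataFrame(row.names = colnames(counts))
        else S4Vectors::DataFrame(colData, row.names = colnames(counts))
  cd$lib_size <- as.numeric(libSizes)
  se <- SummarizedExperiment(
    assays = list(expr = counts),
    rowData = S4Vectors::DataFrame(biotype = as.character(biotype)),
    colData = cd
  )
  new("SpreadExperiment", se, scale = scale)
}

#' @rdname SpreadExperiment-class
#' @export
setMethod("biotype", "SpreadExperiment", function(x) {
  setNames(as.character(rowData(x)$biotype), rownames(x))
})

#' @rdname SpreadExperiment-class
#' @export
setMethod("exprScale", "SpreadExperiment", function(x) x@scale)

#' @rdname SpreadExperiment-class
#' @export
setMethod("libSizes", "SpreadExperiment", function(x) {
  setNames(colData(x)$lib_size, colnames(x))
})

setMethod("show", "SpreadExperiment", function(object) {
  callNextMethod()
  cat("scale:", object@scale, "\n")
  bt <- table(factor(rowData(object)$biotype, levels = biotypeLevels()))
  cat("biotypes:", paste(sprintf("%s=%d", names(bt), bt), collapse = " "), "\n")
})

## internal: replace the assay keeping annotations, with a new scale flag
.replaceExpr <- function(x, values, scale) {
  assay(x, "expr") <- values
  x@scale <- scale
  validObject(x)
  x
}
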