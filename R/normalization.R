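#' Log counts-per-million transformation
#'
#' Transforms raw counts to the analysis scale
#' \code{log2((count + 0.5) / (lib_size / 1e6))}, i.e. log2 counts per
#' million with a 0.5 read offset. Library sizes are the totals stored at
#' construction (total library reads, not post-filter sums), so filtering
#' does not change the scale.
#'
#' @param x A raw-scale \code{\linkS4class{SpreadExperiment}}.
#' @return A \code{SpreadExperiment} with scale \code{"log_cpm"}.
#' @seealso \code{\link{cyclicLoessNormalize}}, \code{\link{filterMinReads}}
#' @export
#' @examples
#' se <- SpreadExperiment(matrix(c(0, 7), 1, 2,
#'                               dimnames = list("f1", c("a", "b"))),
#'                        biotype = "miRNA", libSizes = c(1e6, 2e6))
#' SummarizedExperiment::assay(logCPM(se))   # -1 and log2(7.5/2)
logCPM <- function(x) {
  stopifnot(is(x, "SpreadExperiment"))
  if (exprScale(x) != "raw")
    stop("logCPM expects raw counts (scale is '", exprScale(x), "')")
  libs <- libSizes(x)
  if (any(libs <= 0)) stop("library sizes must be positive")
  v <- log2(sweep(assay(x) + 0.5, 2, libs / 1e6, "/"))
  .replaceExpr(x, v, "log_cpm")
}

#' Cyclic loess normalization of log-CPM values
#'
#' Removes smooth intensity-dependent (M-vs-A) biases between samples by
#' cyclic loess: for each sample pair a loess trend of the log-ratio M
#' against the average log-intensity A is estimated and half of it
#' subtracted from each member, cycling over all pairs for a fixed number of
#' iterations. The computation is delegated to
#' \code{\link[limma]{normalizeCyclicLoess}}.
#'
#' @param x A log-CPM-scale \code{\linkS4class{SpreadExperiment}}.
#' @param span Loess span.
#' @param iterations Number of cycles over all pairs.
#' @param method \code{"pairs"} (all sample pairs, default) or \code{"fast"}
#'   (each sample against the mean; linear in sample number, used for large
#'   simulation sweeps).
#' @return A \code{SpreadExperiment} with scale \code{"loess_normalized"},
#'   same features and samples in the same order.
#' @importFrom limma normalizeCyclicLoess
#' @export
cyclicLoessNormalize <- function(x, span = 0.7, iterations = 3,
                                 method = c("pairs", "fast")) {
  stopifnot(is(x, "SpreadExperiment"))
  method <- match.arg(method)
  if (exprScale(x) != "log_cpm")
    stop("cyclicLoessNormalize expects log_cpm values")
  if (ncol(x) < 2) stop("at least 2 samples are required")
  v <- limma::normalizeCyclicLoess(assay(x), span = span,
                                   iterations = iterations, method = method)
  dimnames(v) <- dimnames(assay(x))
  .replaceExpr(x, v, "loess_normalized")
}

#' Minimum supporting-read filter
#'
#' Keeps features with strictly more than \code{threshold} supporting reads
#' summed over all samples (default > 100 reads), the inclusion rule applied
#' before any statistical analysis. A feature with exactly \code{threshold}
#' total reads is removed. Library sizes are left untouched.
#'
#' @param x A raw-scale \code{\linkS4class{SpreadExperiment}}.
#' @param threshold Minimum total read count (exclusive).
#' @return The filtered \code{SpreadExperiment}.
#' @export
#' @examples
#' cnt <- matrix(c(50, 50, 51, 50), 2, 2, byrow = TRUE,
#'               dimnames = list(c("at100", "at101"), c("a", "b")))
#' se <- SpreadExperiment(cnt, biotype = c("miRNA", "miRNA"))
#' rownames(filterMinReads(se))   # only "at101" survives
filterMinReads <- function(x, threshold = 100L) {
  stopifnot(is(x, "SpreadExperiment"))
  if (exprScale(x) != "raw")
    stop("filterMinReads operates on raw counts")
  x[rowSums(assay(x)) > threshold, ]
}

#' Collapse features into groups
#'
#' Sums raw counts of features mapped to the same group (e.g. isomiRs of one
#' mature miRNA collapsed to a single feature); the group identifier becomes
#' the feature identifier. Every feature must be mapped; total counts are
#' conserved. Groups mixing biotypes are resolved to the first member's
#' biotype with a warning.
#'
#' @param x A raw-scale \code{\linkS4class{SpreadExperiment}}.
#' @param collapseMap Named character vector mapping feature id to group id.
#' @return A collapsed \code{SpreadExperiment}, rows ordered by first
#'   occurrence of each group.
#' @export
collapseFeatures <- function(x, collapseMap) {
  stopifnot(is(x, "SpreadExperiment"))
  if (exprScale(x) != "raw")
    stop("collapseFeatures operates on raw counts")
  missing_f <- setdiff(rownames(x), names(collapseMap))
  if (length(missing_f))
    stop("collapseMap lacks ", length(missing_f), " feature(s), e.g. ",
         missing_f[1])
  grp <- collapseMap[rownames(x)]
  glev <- unique(grp)
  cnt <- rowsum(assay(x), group = grp, reorder = FALSE)
  cnt <- cnt[glev, , drop = FALSE]
  bt <- vapply(glev, function(g) {
    b <- unique(biotype(x)[grp == g])
    if (length(b) > 1)
      warning("group '", g, "' mixes biotypes; using '", b[1], "'")
    b[1]
  }, character(1))
  SpreadExperiment(cnt, biotype = bt, colData = colData(x)[
                     setdiff(colnames(colData(x)), "lib_size")],
                   libSizes = libSizes(x))
}
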