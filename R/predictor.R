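#' Spread-predictor score of a sample
#'
#' The 13 sRNA spread predictor of a sample is the median expression of the
#' miliary-up signature members minus the median expression of the
#' non-miliary-up members: higher scores indicate a more miliary-like
#' expression pattern. The score is location-invariant (adding a constant to
#' every member leaves it unchanged), so any consistently normalized log
#' expression — or negated Cq values from RT-qPCR — can be scored.
#'
#' @param x Expression over signature members: a
#'   \code{\linkS4class{SpreadExperiment}} on a log scale, a numeric matrix
#'   (features x samples), or a named vector for a single sample.
#' @param signature A \code{\linkS4class{SpreadSignature}} (default the
#'   shipped 13-member predictor).
#' @param minCoverage Required fraction of measured members per list; the
#'   default 1 is strict (every member must be measured). Lowering it (e.g.
#'   0.75) scores on the measured subset with a warning.
#' @return Named numeric vector of scores, one per sample.
#' @seealso \code{\link{dichotomize}}, \code{\link{defaultSpreadSignature}}
#' @export
#' @examples
#' expr <- c(a = 2, b = 4, c = 6, d = 1, e = 1)
#' spreadScore(expr, SpreadSignature(up = c("a", "b", "c"),
#'                                   down = c("d", "e")))   # 4 - 1 = 3
spreadScore <- function(x, signature = defaultSpreadSignature(),
                        minCoverage = 1) {
  stopifnot(is(signature, "SpreadSignature"))
  if (is(x, "SpreadExperiment")) {
    if (exprScale(x) == "raw")
      stop("spreadScore expects log-scale expression")
    v <- assay(x)
  } else if (is.null(dim(x))) {
    v <- matrix(x, ncol = 1, dimnames = list(names(x), "sample"))
  } else {
    v <- as.matrix(x)
  }
  pick <- function(ids, lab) {
    found <- intersect(ids, rownames(v))
    if (length(found) < minCoverage * length(ids))
      stop("missing ", lab, " signature member(s): ",
           paste(setdiff(ids, rownames(v)), collapse = ", "))
    if (length(found) < length(ids))
      warning(length(ids) - length(found), " ", lab,
              " member(s) unmeasured; scoring on the measured subset")
    found
  }
  up <- pick(upIds(signature), "miliary-up")
  down <- pick(downIds(signature), "non-miliary-up")
  apply(v[up, , drop = FALSE], 2, median) -
    apply(v[down, , drop = FALSE], 2, median)
}

#' Median dichotomization of predictor scores
#'
#' Splits a cohort of predictor scores at the cohort median: samples
#' strictly above the median are called miliary, samples at or below it
#' non-miliary (ties at the median fall to non-miliary by convention).
#'
#' @param scores Named numeric vector of per-sample scores (>= 2 samples,
#'   not all identical).
#' @return Named factor with levels \code{non-miliary}, \code{miliary}.
#' @export
#' @examples
#' dichotomize(c(s1 = 1, s2 = 2, s3 = 3, s4 = 4))
dichotomize <- function(scores) {
  if (length(scores) < 2) stop("at least 2 samples are required")
  if (diff(range(scores)) == 0)
    stop("all scores are identical; a median split is undefined")
  med <- median(scores)
  setNames(factor(ifelse(scores > med, "miliary", "non-miliary"),
                  levels = c("non-miliary", "miliary")),
           names(scores))
}

#' Select a spread signature from tissue-restricted DE results
#'
#' Threshold-and-direction signature selection, deliberately not
#' model-driven: candidate sRNAs are those significantly deregulated
#' (FDR < \code{alpha}) between miliary and non-miliary in the primary
#' ovarian (P) comparison and \emph{not} significant in any other supplied
#' comparison (other tissue origins), keeping only markers specific to the
#' ovarian tumor contrast. Candidates are partitioned by direction:
#' \code{"up"} (higher in miliary) members form the up list, \code{"down"}
#' members the down list.
#'
#' @param primary DE results (\code{\link{fitFeatureStats}}) of the
#'   P-sample miliary vs non-miliary comparison, with group coded so that
#'   direction \code{"up"} means higher in miliary.
#' @param others Optional named list of DE result data frames for the other
#'   comparisons; features significant in any of them are excluded.
#'   Features absent from a comparison count as not significant there.
#' @param alpha FDR significance threshold.
#' @param minPerDirection Minimum members required per direction; selection
#'   refuses (errors) below it.
#' @return A \code{\linkS4class{SpreadSignature}}.
#' @export
selectSignature <- function(primary, others = list(), alpha = 0.05,
                            minPerDirection = 2) {
  need <- c("feature_id", "fdr", "direction")
  if (!all(need %in% colnames(primary)))
    stop("primary must be a DE result data frame")
  sig <- primary[primary$fdr < alpha, , drop = FALSE]
  if (nrow(sig) == 0) stop("no significant candidates in the primary comparison")
  for (o in others) {
    elsewhere <- o$feature_id[o$fdr < alpha]
    sig <- sig[!sig$feature_id %in% elsewhere, , drop = FALSE]
  }
  up <- sig$feature_id[sig$direction == "up"]
  down <- sig$feature_id[sig$direction == "down"]
  if (length(up) < minPerDirection || length(down) < minPerDirection)
    stop("fewer than ", minPerDirection, " tissue-specific candidates per ",
         "direction (", length(up), " up, ", length(down), " down); ",
         "refusing to build a signature")
  SpreadSignature(up = up, down = down)
}
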