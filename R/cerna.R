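#' circRNA back-splice index
#'
#' Per-sample ratio of back-splicing events to all splicing events,
#' \code{back / (back + linear)}: a proxy for circular relative to linear
#' RNA abundance that is invariant to sequencing depth.
#'
#' @param junctions Data frame with columns \code{sample},
#'   \code{back_splice_events}, \code{linear_splice_events} (non-negative
#'   counts; their sum must be positive in every sample).
#' @return Named numeric vector of indices in [0, 1].
#' @export
#' @examples
#' circIndex(data.frame(sample = "s1", back_splice_events = 5,
#'                      linear_splice_events = 95))   # 0.05
circIndex <- function(junctions) {
  b <- junctions$back_splice_events
  l <- junctions$linear_splice_events
  if (any(b < 0 | l < 0)) stop("junction counts must be non-negative")
  tot <- b + l
  if (any(tot == 0))
    stop("back + linear splice events must be positive for every sample")
  setNames(b / tot, junctions$sample)
}

#' Ratio of median lncRNA to median coding expression
#'
#' Per sample, the median expression of lncRNA features divided by the
#' median of coding features, with medians taken on the linear scale
#' (\code{2^logexpr}; switch to \code{medianScale = "log"} for medians of
#' log values, returned as the back-transformed ratio). A global +1 log2
#' shift of all lncRNAs doubles the ratio.
#'
#' @param x A normalized (\code{log_cpm} or \code{loess_normalized})
#'   \code{\linkS4class{SpreadExperiment}} containing both biotypes.
#' @param medianScale \code{"linear"} (default) or \code{"log"}.
#' @return Named numeric vector, one ratio per sample.
#' @export
ncCodingRatio <- function(x, medianScale = c("linear", "log")) {
  stopifnot(is(x, "SpreadExperiment"))
  medianScale <- match.arg(medianScale)
  if (exprScale(x) == "raw")
    stop("ncCodingRatio expects normalized log expression")
  bt <- biotype(x)
  if (!any(bt == "lncRNA") || !any(bt == "coding"))
    stop("both lncRNA and coding features are required")
  v <- assay(x)
  lnc <- v[bt == "lncRNA", , drop = FALSE]
  cod <- v[bt == "coding", , drop = FALSE]
  r <- if (medianScale == "linear")
    apply(2^lnc, 2, median) / apply(2^cod, 2, median)
  else
    2^(apply(lnc, 2, median) - apply(cod, 2, median))
  setNames(r, colnames(x))
}

#' Global miRNA abundance ratios
#'
#' Per-sample totals of raw miRNA reads normalized to small nuclear
#' (snRNA) or small nucleolar (snoRNA) reads, and the ratio of miRNAs to
#' long linear RNAs (coding plus lncRNA; circRNAs are not part of the count
#' matrix) with both normalized to the same small-RNA class. All ratios are
#' invariant to global per-sample scaling.
#'
#' @param x A raw-scale \code{\linkS4class{SpreadExperiment}}.
#' @return Data frame with one row per sample: \code{mir_sn_ratio},
#'   \code{mir_sno_ratio}, \code{mir_long_ratio_sn},
#'   \code{mir_long_ratio_sno}.
#' @export
mirAbundanceRatios <- function(x) {
  stopifnot(is(x, "SpreadExperiment"))
  if (exprScale(x) != "raw")
    stop("mirAbundanceRatios uses total raw read counts")
  bt <- biotype(x)
  need <- c("miRNA", "snRNA", "snoRNA")
  if (!all(need %in% bt))
    stop("miRNA, snRNA and snoRNA features are all required")
  cnt <- assay(x)
  tot <- function(b) colSums(cnt[bt %in% b, , drop = FALSE])
  mi <- tot("miRNA"); sn <- tot("snRNA"); sno <- tot("snoRNA")
  long <- tot(c("coding", "lncRNA"))
  if (any(sn == 0) || any(sno == 0))
    stop("zero snRNA/snoRNA totals: normalizers must be positive")
  data.frame(sample = colnames(x),
             mir_sn_ratio = mi / sn,
             mir_sno_ratio = mi / sno,
             mir_long_ratio_sn = (mi / sn) / (long / sn),
             mir_long_ratio_sno = (mi / sno) / (long / sno),
             row.names = colnames(x))
}

#' Two-group comparison of a per-sample statistic
#'
#' Two-sample Student's t-test with pooled variance comparing a per-sample
#' summary statistic (circRNA index, abundance ratio, ...) between the two
#' spread types. The statistic is the mean of the first group minus the
#' mean of the second, on the pooled standard error.
#'
#' @param values Named numeric vector of per-sample values.
#' @param groups Per-sample factor/character with exactly two groups, in the
#'   same order as \code{values}; the first level (or first encountered
#'   value) is group 1.
#' @return List with \code{statistic} (t), \code{p} (two-sided),
#'   \code{df}, and group \code{means}.
#' @export
#' @examples
#' compareGroups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
compareGroups <- function(values, groups) {
  g <- if (is.factor(groups)) groups else factor(groups,
                                                 levels = unique(groups))
  if (nlevels(g) != 2) stop("exactly two groups are required")
  if (min(table(g)) < 2) stop("at least 2 samples per group are required")
  x <- values[g == levels(g)[1]]
  y <- values[g == levels(g)[2]]
  if (var(x) == 0 && var(y) == 0 && mean(x) == mean(y))
    return(list(statistic = 0, p = 1, df = length(values) - 2,
                means = c(mean(x), mean(y))))
  tt <- t.test(x, y, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       means = setNames(as.numeric(tt$estimate), levels(g)))
}

#' Mean expression per gene by spread type and tissue class
#'
#' Averages each gene's expression over the samples of a tissue class
#' (solid PM or ascitic AS) within each spread type, then compares the
#' spread types per biotype with a paired two-sided t-test across genes
#' (pairing genes; difference non-miliary minus miliary) — the gene-wise
#' global comparison of coding and lncRNA abundance.
#'
#' @param x A normalized \code{\linkS4class{SpreadExperiment}} whose
#'   \code{colData} has \code{tissue} (P/M/A/S) and \code{spread}
#'   (miliary / non-miliary); both spread types and both tissue classes
#'   must be present.
#' @param biotypes Biotypes to test (default coding and lncRNA).
#' @return List with \code{means} — one row per gene, tissue class and
#'   spread type — and \code{tests} — per biotype and tissue class the mean
#'   paired difference (non-miliary - miliary), t statistic and p-value.
#' @export
meanExpressionBySpread <- function(x, biotypes = c("coding", "lncRNA")) {
  stopifnot(is(x, "SpreadExperiment"))
  if (exprScale(x) == "raw")
    stop("meanExpressionBySpread expects normalized log expression")
  cd <- colData(x)
  if (!all(c("tissue", "spread") %in% colnames(cd)))
    stop("colData needs 'tissue' and 'spread'")
  tclass <- ifelse(cd$tissue %in% c("P", "M"), "PM", "AS")
  spread <- as.character(cd$spread)
  if (length(unique(spread)) < 2 || length(unique(tclass)) < 2)
    stop("both spread types and both tissue classes must be present")
  v <- assay(x)
  strata <- expand.grid(tissue_class = c("PM", "AS"),
                        spread = c("miliary", "non-miliary"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  means <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    sel <- tclass == strata$tissue_class[i] & spread == strata$spread[i]
    if (!any(sel)) return(NULL)
    data.frame(gene = rownames(v), biotype = unname(biotype(x)),
               tissue_class = strata$tissue_class[i],
               spread = strata$spread[i],
               mean_expr = rowMeans(v[, sel, drop = FALSE]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  tests <- do.call(rbind, lapply(unique(means$tissue_class), function(tc) {
    do.call(rbind, lapply(biotypes, function(bt) {
      mM <- means[means$tissue_class == tc & means$spread == "miliary" &
                    means$biotype == bt, ]
      mN <- means[means$tissue_class == tc & means$spread == "non-miliary" &
                    means$biotype == bt, ]
      if (!nrow(mM) || !nrow(mN)) return(NULL)
      d <- mN$mean_expr[match(mM$gene, mN$gene)] - mM$mean_expr
      if (all(d == 0)) {
        tt <- list(statistic = 0, p.value = 1)
      } else {
        tt <- t.test(d)
      }
      data.frame(biotype = bt, tissue_class = tc, mean_diff = mean(d),
                 statistic = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    }))
  }))
  list(means = means, tests = tests)
}
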