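#' Assign miRNA regulators to a gene set by Fisher's exact test
#'
#' For every miRNA in the target-interaction table, the fraction of gene-set
#' members it targets is compared with the fraction of targeted genes in the
#' whole gene universe through a one-sided (enrichment) Fisher's exact test
#' on the 2x2 table in-set targeted / in-set non-targeted / out-of-set
#' targeted / out-of-set non-targeted. miRNAs enriched at one-sided p < 0.05
#' form the miR set of the gene set.
#'
#' @param geneSet Character vector of gene ids (must lie in
#'   \code{universe}).
#' @param targets Data frame of miRNA-target interactions with columns
#'   \code{mirna} and \code{gene} (one row per verified pair).
#' @param universe Character vector: all analyzed genes ("all genes" of the
#'   background fraction). Interactions outside the universe are ignored.
#' @param alpha Assignment threshold on the one-sided p-value.
#' @param onlyAssigned If \code{TRUE} (default) return only miRNAs with
#'   p < \code{alpha}; otherwise all tested miRNAs.
#' @param backgroundIncludesSet If \code{TRUE}, the background fraction is
#'   computed over all genes including the set (the literal "targeted genes
#'   among all genes" reading) via \code{\link[stats]{fisher.test}};
#'   the default compares the disjoint in-set vs out-of-set fractions, the
#'   standard hypergeometric enrichment test.
#' @return Data frame with columns \code{mirna}, \code{n_targets_universe},
#'   \code{n_targets_set}, \code{p}, ordered by p.
#' @seealso \code{\link{buildGeneMiRSets}}
#' @export
#' @examples
#' targets <- data.frame(mirna = "miR-1", gene = paste0("g", 1:5))
#' assignMiRsToGeneSet(paste0("g", 1:5), targets, paste0("g", 1:100))
assignMiRsToGeneSet <- function(geneSet, targets, universe, alpha = 0.05,
                                onlyAssigned = TRUE,
                                backgroundIncludesSet = FALSE) {
  if (length(geneSet) == 0) stop("gene set is empty")
  if (length(universe) == 0) stop("universe is empty")
  universe <- unique(universe)
  geneSet <- unique(geneSet)
  if (!all(geneSet %in% universe))
    stop("gene set contains genes outside the universe")
  tt <- targets[targets$gene %in% universe, c("mirna", "gene"), drop = FALSE]
  tt <- unique(tt)
  if (nrow(tt) == 0)
    return(data.frame(mirna = character(), n_targets_universe = integer(),
                      n_targets_set = integer(), p = numeric()))
  N <- length(universe)
  n <- length(geneSet)
  K <- table(tt$mirna)                         # targets per miRNA in universe
  inSet <- tt$gene %in% geneSet
  a <- table(factor(tt$mirna[inSet], levels = names(K)))
  K <- as.integer(K); a <- as.integer(a)
  mir <- names(table(tt$mirna))
  if (backgroundIncludesSet) {
    p <- vapply(seq_along(mir), function(i) {
      stats::fisher.test(matrix(c(a[i], n - a[i], K[i], N - K[i]), 2,
                                byrow = TRUE),
                         alternative = "greater")$p.value
    }, numeric(1))
  } else {
    ## P(X >= a), X ~ Hypergeom(N, K, n)
    p <- phyper(a - 1L, K, N - K, n, lower.tail = FALSE)
  }
  out <- data.frame(mirna = mir, n_targets_universe = K,
                    n_targets_set = a, p = p, stringsAsFactors = FALSE)
  out <- out[order(out$p, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  if (onlyAssigned) out[out$p < alpha, , drop = FALSE] else out
}

#' Competitive permutation test of set-level deregulation
#'
#' Scores a feature set by the mean of its members' per-feature t statistics
#' and compares it with a competitive null built by repeatedly drawing
#' random feature sets of the same size from all scored features. The
#' two-sided p-value uses the add-one permutation estimator; the reported
#' direction is the sign of the observed score (ties broken as "up").
#'
#' @param stats Named numeric vector of per-feature statistics, or a data
#'   frame from \code{\link{fitFeatureStats}} (its \code{statistic} column
#'   is used).
#' @param members Feature ids of the set (all must be present in
#'   \code{stats}).
#' @param nPerm Number of random sets (>= 100).
#' @param seed Optional integer seed.
#' @return List with \code{p}, \code{direction}, \code{observed} (mean
#'   member statistic) and \code{nPerm}.
#' @export
setDeregulationTest <- function(stats, members, nPerm = 1000, seed = NULL) {
  s <- .statVector(stats)
  if (length(members) == 0) stop("members must be non-empty")
  if (!all(members %in% names(s)))
    stop("members absent from stats: ",
         paste(head(setdiff(members, names(s)), 3), collapse = ", "))
  if (nPerm < 100) stop("nPerm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  m <- length(members)
  obs <- mean(s[members])
  null <- .permNullMeans(s, m, nPerm)
  list(p = .twoSidedPermP(obs, null),
       direction = if (obs < 0) "down" else "up",
       observed = obs, nPerm = nPerm)
}

.statVector <- function(stats) {
  if (is.data.frame(stats)) {
    s <- stats$statistic
    names(s) <- if (!is.null(stats$feature_id)) stats$feature_id
                else rownames(stats)
    s
  } else stats
}

.permNullMeans <- function(s, m, nPerm) {
  F <- length(s)
  vapply(seq_len(nPerm),
         function(i) mean(s[sample.int(F, m)]), numeric(1))
}

.twoSidedPermP <- function(obs, null) {
  nPerm <- length(null)
  pUp <- (1 + sum(null >= obs)) / (nPerm + 1)
  pDown <- (1 + sum(null <= obs)) / (nPerm + 1)
  min(1, 2 * min(pUp, pDown))
}

#' Combine gene-set and miR-set p-values
#'
#' Fisher's method: the statistic \code{-2 (ln p_gene + ln p_mir)} is
#' referred to a chi-squared distribution with 4 degrees of freedom. Zero
#' p-values are clipped at 1e-300 with a warning.
#'
#' @param pGene,pMir Vectors of p-values in (0, 1].
#' @return Vector of combined p-values (NA where either input is NA).
#' @export
#' @examples
#' combineGeneMiRPvalues(0.05, 0.05)   # ~0.0175
combineGeneMiRPvalues <- function(pGene, pMir) {
  if (any(c(pGene, pMir) == 0, na.rm = TRUE)) {
    warning("zero p-values clipped at 1e-300")
    pGene <- pmax(pGene, 1e-300)
    pMir <- pmax(pMir, 1e-300)
  }
  stat <- -2 * (log(pGene) + log(pMir))
  pchisq(stat, df = 4, lower.tail = FALSE)
}

#' Build and test gene-miR sets
#'
#' Pipeline of the combined gene-miR set analysis: each gene set is annotated
#' with its miR set (miRNAs with Fisher enrichment p < 0.05 among verified
#' targets, \code{\link{assignMiRsToGeneSet}}), the gene set and the miR set
#' are separately tested for deregulation with the competitive permutation
#' test on the per-feature DE statistics, the two p-values are combined by
#' Fisher's method, and the combined p-values are Benjamini-Hochberg
#' adjusted across sets. The gene universe is the intersection of genes in
#' the target table with genes in the DE results.
#'
#' @param geneSets Named list of gene-id vectors (e.g. from
#'   \code{\link{readGMT}}).
#' @param targets miRNA-target interaction data frame (\code{mirna},
#'   \code{gene}).
#' @param statsGenes,statsMirs Per-feature DE results
#'   (\code{\link{fitFeatureStats}}) for genes and miRNAs.
#' @param nPerm Permutations per set-level test.
#' @param seed Integer seed for the permutation draws.
#' @param alpha Fisher assignment threshold.
#' @param backgroundIncludesSet Passed to \code{\link{assignMiRsToGeneSet}}.
#' @return Data frame with one row per gene set: \code{set_id},
#'   \code{n_genes}, \code{n_mirs}, \code{p_gene}, \code{p_mir},
#'   \code{dir_gene}, \code{dir_mir}, \code{p_combined}, \code{q_combined},
#'   and a list-column \code{mirs} of assigned miRNA ids. Sets whose miR set
#'   is empty (or whose genes are absent from the universe) carry NA in the
#'   combined columns.
#' @seealso \code{\link{concordanceSummary}}
#' @export
buildGeneMiRSets <- function(geneSets, targets, statsGenes, statsMirs,
                             nPerm = 1000, seed = 1L, alpha = 0.05,
                             backgroundIncludesSet = FALSE) {
  sg <- .statVector(statsGenes)
  sm <- .statVector(statsMirs)
  hasTargets <- !is.null(targets) && nrow(targets) > 0
  universe <- if (hasTargets)
    intersect(unique(targets$gene), names(sg)) else character()
  if (hasTargets && length(universe) == 0)
    stop("no overlap between target-table genes and DE results")
  set.seed(seed)
  rows <- lapply(names(geneSets), function(id) {
    genes <- intersect(unique(geneSets[[id]]), names(sg))
    genesU <- intersect(genes, universe)
    mirs <- character()
    pMir <- NA_real_; dirMir <- NA_character_
    if (hasTargets && length(genesU)) {
      asg <- assignMiRsToGeneSet(genesU, targets, universe, alpha = alpha,
                                 backgroundIncludesSet = backgroundIncludesSet)
      mirs <- intersect(asg$mirna, names(sm))
    }
    if (length(genes) == 0)
      return(data.frame(set_id = id, n_genes = 0L, n_mirs = 0L,
                        p_gene = NA_real_, p_mir = NA_real_,
                        dir_gene = NA_character_, dir_mir = NA_character_,
                        mirs = I(list(character())),
                        stringsAsFactors = FALSE))
    tg <- setDeregulationTest(sg, genes, nPerm = nPerm)
    if (length(mirs)) {
      tm <- setDeregulationTest(sm, mirs, nPerm = nPerm)
      pMir <- tm$p; dirMir <- tm$direction
    }
    data.frame(set_id = id, n_genes = length(genes), n_mirs = length(mirs),
               p_gene = tg$p, p_mir = pMir,
               dir_gene = tg$direction, dir_mir = dirMir,
               mirs = I(list(mirs)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_combined <- ifelse(
    is.na(out$p_gene) | is.na(out$p_mir), NA_real_,
    combineGeneMiRPvalues(out$p_gene, out$p_mir))
  out$q_combined <- NA_real_
  ok <- !is.na(out$p_combined)
  out$q_combined[ok] <- bhFDR(out$p_combined[ok])
  rownames(out) <- out$set_id
  out
}

#' Direction-concordance summary of gene-miR sets
#'
#' For each significance cutoff, among gene-miR sets whose adjusted combined
#' p-value falls below the cutoff, reports the percentage deregulated in
#' opposite directions (gene set and miR set disagreeing) and, within those,
#' the percentage with the gene set down- and the miR set upregulated — the
#' pattern expected if miRNAs suppress their targets. Cutoffs with no
#' qualifying sets yield NA (not zero).
#'
#' @param sets Data frame from \code{\link{buildGeneMiRSets}} (needs
#'   \code{q_combined}, \code{dir_gene}, \code{dir_mir}).
#' @param cutoffGrid Numeric vector of cutoffs on \code{q_combined}.
#' @return List with \code{curve} (data frame: \code{cutoff}, \code{n},
#'   \code{pct_opposite}, \code{n_opposite}, \code{pct_gene_down_mir_up})
#'   and \code{nSignificant}, the number of sets with q < 0.05.
#' @export
concordanceSummary <- function(sets, cutoffGrid = c(0.001, 0.005, 0.01,
                                                    0.05, 0.1, 0.25, 0.5, 1)) {
  if (length(cutoffGrid) == 0) stop("cutoff grid is empty")
  ok <- !is.na(sets$q_combined)
  curve <- do.call(rbind, lapply(sort(cutoffGrid), function(ct) {
    sel <- ok & sets$q_combined < ct
    n <- sum(sel)
    opp <- sel & sets$dir_gene != sets$dir_mir
    nOpp <- sum(opp)
    data.frame(
      cutoff = ct, n = n,
      pct_opposite = if (n > 0) 100 * nOpp / n else NA_real_,
      n_opposite = nOpp,
      pct_gene_down_mir_up = if (nOpp > 0)
        100 * sum(opp & sets$dir_gene == "down" & sets$dir_mir == "up") / nOpp
      else NA_real_)
  }))
  list(curve = curve,
       nSignificant = sum(ok & sets$q_combined < 0.05))
}

#' Read a gene-set collection in GMT format
#'
#' Parses a Broad-style GMT file (set name, description, tab-separated gene
#' ids) into a named list, via \code{\link[fgsea]{gmtPathways}}.
#'
#' @param file Path to a .gmt file.
#' @return Named list of character vectors.
#' @importFrom fgsea gmtPathways
#' @export
readGMT <- function(file) {
  fgsea::gmtPathways(file)
}

#' @rdname readGMT
#' @param geneSets Named list of gene-id vectors.
#' @param description Optional per-set description column (recycled).
#' @export
writeGMT <- function(geneSets, file, description = "na") {
  lines <- vapply(names(geneSets), function(nm) {
    paste(c(nm, description, geneSets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}
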