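#' Read and write biotyped count matrices
#'
#' Tab-separated exchange format: one row per feature with columns
#' \code{feature_id}, \code{biotype}, then one count column per sample.
#'
#' @param file Path to a TSV file.
#' @param x A raw-scale \code{\linkS4class{SpreadExperiment}}.
#' @return \code{readCounts} returns a \code{SpreadExperiment};
#'   \code{writeCounts} invisibly returns \code{file}.
#' @export
readCounts <- function(file) {
  tab <- utils::read.delim(file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!all(c("feature_id", "biotype") %in% colnames(tab)))
    stop("count file needs 'feature_id' and 'biotype' columns")
  cnt <- as.matrix(tab[, setdiff(colnames(tab),
                                 c("feature_id", "biotype")), drop = FALSE])
  rownames(cnt) <- tab$feature_id
  SpreadExperiment(cnt, biotype = tab$biotype)
}

#' @rdname readCounts
#' @export
writeCounts <- function(x, file) {
  stopifnot(is(x, "SpreadExperiment"))
  tab <- data.frame(feature_id = rownames(x), biotype = unname(biotype(x)),
                    assay(x), check.names = FALSE)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a synthetic cohort to a directory
#'
#' Serializes every component of a \code{\link{generateCohort}} result as
#' plain text: the raw counts (TSV with biotype column), splice-junction
#' counts, sample annotations, miRNA-target interactions and survival
#' records as TSV, gene sets as GMT, and a JSON manifest echoing the
#' planted truth (up-miRNAs, suppressed targets, planted sets, signature
#' members, effect sizes).
#'
#' @param cohort A \code{SyntheticCohort}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of written file paths.
#' @importFrom jsonlite write_json
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    junctions = file.path(dir, "junctions.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    targets = file.path(dir, "targets.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    survival = file.path(dir, "survival.tsv"),
    manifest = file.path(dir, "manifest.json"))
  writeCounts(cohort$counts, paths["counts"])
  wtsv <- function(d, p) utils::write.table(d, p, sep = "\t", quote = FALSE,
                                            row.names = FALSE)
  wtsv(cohort$junctions, paths["junctions"])
  wtsv(cohort$annotations, paths["annotations"])
  if (!is.null(cohort$targets)) wtsv(cohort$targets, paths["targets"])
  if (length(cohort$geneSets)) writeGMT(cohort$geneSets, paths["gene_sets"])
  wtsv(cohort$survival, paths["survival"])
  tr <- cohort$truth
  manifest <- list(
    effects = tr$effects[c("mirnaTargetLogFC", "lncrnaMiliaryLogFC",
                           "circIndexShift", "signatureLogFC")],
    cox_coefficients = as.list(tr$effects$coxCoefficients),
    up_mirnas = tr$upMiRNAs, suppressed_genes = tr$suppressedGenes,
    planted_sets = tr$plantedSets,
    signature = if (!is.null(tr$signature))
      list(up = upIds(tr$signature), down = downIds(tr$signature)),
    spread_by_patient = as.list(tr$spreadByPatient))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Read tabular pipeline inputs
#'
#' \code{readTargets} reads a miRNA-target interaction TSV (\code{mirna},
#' \code{gene}, optional \code{evidence}); \code{readJunctions} a
#' splice-junction TSV (\code{sample}, \code{back_splice_events},
#' \code{linear_splice_events}); \code{readSurvival} survival records
#' (\code{time_months}, \code{event}, covariates).
#'
#' @param file Path to a TSV file.
#' @return A data frame.
#' @export
readTargets <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("mirna", "gene") %in% colnames(tab)))
    stop("target file needs 'mirna' and 'gene' columns")
  tab
}

#' @rdname readTargets
#' @export
readJunctions <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("sample", "back_splice_events", "linear_splice_events")
  if (!all(need %in% colnames(tab)))
    stop("junction file needs columns: ", paste(need, collapse = ", "))
  tab
}

#' @rdname readTargets
#' @export
readSurvival <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("time_months", "event") %in% colnames(tab)))
    stop("survival file needs 'time_months' and 'event' columns")
  tab
}
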