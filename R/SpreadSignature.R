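#' SpreadSignature: small RNA spread-type signature
#'
#' Holds the two member lists of a spread-type signature: small RNAs higher
#' expressed in miliary tumors (\code{up}) and small RNAs higher expressed in
#' non-miliary tumors (\code{down}). The per-sample predictor value is
#' \code{median(expr[up]) - median(expr[down])}; see \code{\link{spreadScore}}.
#'
#' @slot up Character vector of miliary-up sRNA identifiers.
#' @slot down Character vector of non-miliary-up sRNA identifiers.
#'
#' @param up,down Character vectors of sRNA identifiers; must be non-empty,
#'   duplicate-free and disjoint.
#' @param x A \code{SpreadSignature}.
#'
#' @return \code{SpreadSignature()} returns a validated object; \code{upIds()}
#'   and \code{downIds()} return the member lists; \code{length()} the total
#'   number of members.
#'
#' @aliases SpreadSignature upIds downIds upIds,SpreadSignature-method
#'   downIds,SpreadSignature-method length,SpreadSignature-method
#' @export SpreadSignature
#' @exportClass SpreadSignature
#' @examples
#' sig <- SpreadSignature(up = c("a", "b", "c"), down = c("d", "e"))
#' upIds(sig)
#' length(sig)
setClass("SpreadSignature",
  slots = c(up = "character", down = "character"))

setValidity("SpreadSignature", function(object) {
  msg <- character()
  if (length(object@up) == 0L) msg <- c(msg, "'up' must be non-empty")
  if (length(object@down) == 0L) msg <- c(msg, "'down' must be non-empty")
  if (anyDuplicated(c(object@up, object@down)))
    msg <- c(msg, "'up' and 'down' must be disjoint and duplicate-free")
  if (length(msg)) msg else TRUE
})

SpreadSignature <- function(up, down) {
  new("SpreadSignature", up = as.character(up), down = as.character(down))
}

#' @rdname SpreadSignature-class
#' @export
setMethod("upIds", "SpreadSignature", function(x) x@up)

#' @rdname SpreadSignature-class
#' @export
setMethod("downIds", "SpreadSignature", function(x) x@down)

#' @rdname SpreadSignature-class
#' @export
setMethod("length", "SpreadSignature", function(x) {
  length(x@up) + length(x@down)
})

setMethod("show", "SpreadSignature", function(object) {
  cat(sprintf("SpreadSignature: %d miliary-up, %d non-miliary-up sRNAs\n",
              length(object@up), length(object@down)))
  cat("  up:  ", paste(object@up, collapse = ", "), "\n")
  cat("  down:", paste(object@down, collapse = ", "), "\n")
})

#' The published 13 sRNA spread-type signature
#'
#' The default signature shipped with the package: three miRNAs higher
#' expressed in miliary tumors and ten sRNAs (eight miRNAs, two piRNAs)
#' higher expressed in non-miliary tumors, as reported for the training
#' cohort. Member identities are fixed; the predictor value is the median
#' expression of the up list minus the median expression of the down list.
#'
#' @return A \code{\linkS4class{SpreadSignature}} with 3 up and 10 down
#'   members (13 sRNAs in total).
#' @seealso \code{\link{spreadScore}}, \code{\link{readSignature}}
#' @export
#' @examples
#' defaultSpreadSignature()
defaultSpreadSignature <- function() {
  SpreadSignature(
    up = c("miR-760", "novel-miR-1003", "novel-miR-2508"),
    down = c("miR-1254", "novel-miR-804", "novel-miR-1628", "novel-miR-1927",
             "novel-miR-2353", "novel-miR-2916", "novel-miR-3475",
             "novel-miR-3784", "piRno_hsa_009295",
             "novel-piR-n9_chr19_12817301")
  )
}

#' Read / write a spread signature as two-column TSV
#'
#' The file format is two tab-separated columns, \code{id} and
#' \code{direction}, with direction \code{up_miliary} or \code{up_non_miliary}.
#' The shipped default signature is at
#' \code{system.file("extdata", "sig13_published.tsv", package = "ceRNAspread")}.
#'
#' @param file Path to a signature TSV.
#' @param signature A \code{SpreadSignature}.
#' @return \code{readSignature} returns a \code{SpreadSignature};
#'   \code{writeSignature} invisibly returns \code{file}.
#' @export
readSignature <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("id", "direction") %in% colnames(tab)))
    stop("signature file needs 'id' and 'direction' columns")
  bad <- setdiff(unique(tab$direction), c("up_miliary", "up_non_miliary"))
  if (length(bad))
    stop("unknown direction label(s): ", paste(bad, collapse = ", "))
  SpreadSignature(up = tab$id[tab$direction == "up_miliary"],
                  down = tab$id[tab$direction == "up_non_miliary"])
}

#' @rdname readSignature
#' @export
writeSignature <- function(signature, file) {
  stopifnot(is(signature, "SpreadSignature"))
  tab <- data.frame(
    id = c(upIds(signature), downIds(signature)),
    direction = c(rep("up_miliary", length(upIds(signature))),
                  rep("up_non_miliary", length(downIds(signature)))))
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
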