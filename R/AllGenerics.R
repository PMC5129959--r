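#' @import methods
#' @importFrom stats median p.adjust pchisq phyper pt qnorm rbinom rexp rlnorm
#'   rnbinom rnorm rpois runif t.test uniroot complete.cases setNames sd var
#' @importFrom utils read.delim write.table head
NULL

#' Feature biotypes
#'
#' Biotype labels recognised by the package: protein-coding genes, long
#' non-coding RNAs, and the small RNA classes miRNA, piRNA, snRNA and snoRNA.
#'
#' @return Character vector of valid biotype labels.
#' @export
#' @examples
#' biotypeLevels()
biotypeLevels <- function() {
  c("coding", "lncRNA", "miRNA", "piRNA", "snRNA", "snoRNA")
}

#' @rdname biotype
#' @export
setGeneric("biotype", function(x) standardGeneric("biotype"))

#' @rdname exprScale
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' @rdname libSizes
#' @export
setGeneric("libSizes", function(x) standardGeneric("libSizes"))

#' @rdname SpreadSignature-class
#' @export
setGeneric("upIds", function(x) standardGeneric("upIds"))

#' @rdname SpreadSignature-class
#' @export
setGeneric("downIds", function(x) standardGeneric("downIds"))

#' @rdname CoxModelFit-class
#' @export
setGeneric("hazardRatios", function(object) standardGeneric("hazardRatios"))

#' @rdname CoxModelFit-class
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))
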