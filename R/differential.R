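#' Per-feature differential expression between spread types
#'
#' Fits, for every feature, the ordinary least-squares linear model
#' \code{expression ~ confounder + group} on normalized log expression and
#' reports the group coefficient (the log2 fold change group 1 minus group
#' 0), its t statistic, the two-sided p-value, and Benjamini-Hochberg
#' adjusted values. Tissue origin is the typical confounder when ascitic and
#' solid samples are analyzed together. Without a confounder the statistic
#' reduces to the pooled-variance two-sample t-test.
#'
#' @param x A \code{\linkS4class{SpreadExperiment}} on the \code{log_cpm} or
#'   \code{loess_normalized} scale, or a numeric matrix of log expression.
#' @param group Per-sample group membership: a 0/1 vector or a factor with
#'   two levels (second level is "group 1", e.g. miliary).
#' @param confounder Optional per-sample categorical confounder (e.g. tissue
#'   origin); must not be collinear with \code{group}.
#' @return Data frame with one row per feature: \code{feature_id},
#'   \code{log_fc}, \code{statistic}, \code{p}, \code{fdr}, and
#'   \code{direction} (\code{"up"} for log_fc >= 0, \code{"down"}
#'   otherwise).
#' @seealso \code{\link{bhFDR}}, \code{\link{setDeregulationTest}}
#' @export
#' @examples
#' m <- matrix(rnorm(300), 30, 10,
#'             dimnames = list(paste0("f", 1:30), paste0("s", 1:10)))
#' head(fitFeatureStats(m, group = rep(0:1, each = 5)))
fitFeatureStats <- function(x, group, confounder = NULL) {
  if (is(x, "SpreadExperiment")) {
    if (!exprScale(x) %in% c("log_cpm", "loess_normalized"))
      stop("expression must be on the log_cpm or loess_normalized scale")
    Y <- assay(x)
  } else {
    Y <- as.matrix(x)
  }
  if (is.null(rownames(Y)))
    rownames(Y) <- sprintf("feature%05d", seq_len(nrow(Y)))
  S <- ncol(Y)
  g <- if (is.factor(group)) as.integer(group) - 1L else as.numeric(group)
  if (length(g) != S) stop("group must have one entry per sample")
  if (!all(g %in% c(0, 1))) stop("group must be binary")
  if (length(unique(g)) < 2 || min(table(g)) < 2)
    stop("at least 2 samples per group are required")
  X <- cbind(`(Intercept)` = rep(1, S))
  if (!is.null(confounder)) {
    cf <- factor(confounder)
    if (nlevels(cf) > 1)
      X <- cbind(X, stats::model.matrix(~cf)[, -1, drop = FALSE])
  }
  X <- cbind(X, group = g)
  if (qr(X)$rank < ncol(X))
    stop("confounder is collinear with group")
  p <- ncol(X)
  df <- S - p
  if (df < 1) stop("no residual degrees of freedom")
  fit <- stats::lm.fit(X, t(Y))
  cf_all <- as.matrix(fit$coefficients)
  res <- as.matrix(fit$residuals)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[p, p])
  logfc <- cf_all["group", ]
  tstat <- ifelse(se > 0, logfc / se, 0)
  pval <- 2 * pt(-abs(tstat), df)
  pval[se == 0 & logfc == 0] <- 1
  out <- data.frame(
    feature_id = rownames(Y),
    log_fc = unname(logfc),
    statistic = unname(tstat),
    p = unname(pval),
    fdr = bhFDR(unname(pval)),
    direction = ifelse(logfc < 0, "down", "up"),
    stringsAsFactors = FALSE)
  rownames(out) <- rownames(Y)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; values below 5\% are the
#' package-wide significance convention. Wraps
#' \code{\link[stats]{p.adjust}(method = "BH")}.
#'
#' @param p Vector of p-values in [0, 1] (NAs are propagated).
#' @return Vector of BH-adjusted values, monotone in the ranks of \code{p}.
#' @export
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.04))   # all 0.04
bhFDR <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
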