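## Independent brute-force oracles used across the suite.
suppressMessages(library(SummarizedExperiment))

## Hypergeometric upper tail P(X >= a) by direct summation of binomial
## coefficient ratios (no phyper).
hyperTailOracle <- function(a, K, N, n) {
  j <- seq(max(a, 0), min(K, n))
  if (length(j) == 0) return(0)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

## Benjamini-Hochberg step-up by its definition.
bhStepUpOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- m / seq_len(m) * p[o]
  ## enforce monotonicity from the largest rank down
  run <- rev(cummin(rev(sorted)))
  q[o] <- pmin(run, 1)
  q
}

## Breslow partial log-likelihood and its score for a single covariate.
breslowLogLik <- function(beta, time, event, x) {
  eta <- beta * x
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    risk <- time >= t
    d <- event == 1 & time == t
    ll <- ll + sum(eta[d]) - sum(d) * log(sum(exp(eta[risk])))
  }
  ll
}

breslowScore <- function(beta, time, event, X) {
  ## gradient of the Breslow partial log-likelihood, multi-covariate
  eta <- drop(X %*% beta)
  g <- numeric(length(beta))
  for (t in sort(unique(time[event == 1]))) {
    risk <- time >= t
    d <- event == 1 & time == t
    w <- exp(eta[risk])
    xbar <- colSums(X[risk, , drop = FALSE] * w) / sum(w)
    g <- g + colSums(X[d, , drop = FALSE]) - sum(d) * xbar
  }
  g
}

## small default cohort configuration used where a full-size cohort is not
## needed (vignette documents the problem sizes used by the suite)
smallConfig <- function(...) {
  args <- list(nPatients = 10, nCoding = 250, nLncRNA = 100, nMiRNA = 120,
               nPiRNA = 40, nSnRNA = 20, nSnoRNA = 20, libSizeMean = 3e5,
               nGeneSets = 20)
  do.call(cohortConfig, utils::modifyList(args, list(...)))
}

nullEffects <- function() {
  plantedEffects(mirnaTargetLogFC = 0, lncrnaMiliaryLogFC = 0,
                 circIndexShift = 0, signatureLogFC = 0,
                 coxCoefficients = c(predictor = 0))
}
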