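logSE <- function(x, biotype) {
  if (is.null(rownames(x))) rownames(x) <- paste0("f", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  SpreadExperiment(x, biotype = biotype, libSizes = rep(1e6, ncol(x)),
                   scale = "log_cpm")
}

test_that("circIndex is the exact back-splice fraction", {
  j <- data.frame(sample = c("a", "b", "c", "d"),
                  back_splice_events = c(5, 0, 7, 10),
                  linear_splice_events = c(95, 50, 0, 190))
  ci <- circIndex(j)
  expect_equal(unname(ci), c(5 / 100, 0, 1, 0.05))
  ## ratio invariance to depth
  j2 <- j; j2$back_splice_events <- 2 * j$back_splice_events
  j2$linear_splice_events <- 2 * j$linear_splice_events
  expect_equal(circIndex(j2), ci)
  expect_error(circIndex(data.frame(sample = "z", back_splice_events = 0,
                                    linear_splice_events = 0)), "positive")
  expect_error(circIndex(data.frame(sample = "z", back_splice_events = -1,
                                    linear_splice_events = 5)),
               "non-negative")
})

test_that("ncCodingRatio reflects log2 shifts of the lncRNA distribution", {
  set.seed(20)
  x <- rbind(matrix(rnorm(50 * 4, 5), 50, 4),    # coding
             matrix(rnorm(30 * 4, 5), 30, 4))    # lncRNA
  bt <- rep(c("coding", "lncRNA"), c(50, 30))
  ## identical distributions per feature: shift lncRNAs by +1 log2 unit
  x2 <- x; x2[bt == "lncRNA", ] <- x2[bt == "lncRNA", ] + 1
  r1 <- ncCodingRatio(logSE(x, bt))
  r2 <- ncCodingRatio(logSE(x2, bt))
  expect_equal(unname(r2 / r1), rep(2, 4), tolerance = 1e-12)
  ## identical medians give ratio 1
  same <- rbind(matrix(1:4, 2, 4, byrow = TRUE),
                matrix(1:4, 2, 4, byrow = TRUE))
  expect_equal(unname(ncCodingRatio(logSE(same, rep(c("coding", "lncRNA"),
                                                    each = 2)))),
               rep(1, 4))
  ## invariant to permuting features within a biotype
  perm <- x[c(sample(1:50), 50 + sample(1:30)), ]
  expect_equal(unname(ncCodingRatio(logSE(perm, bt))), unname(r1))
  expect_error(ncCodingRatio(logSE(x, rep("coding", 80))), "lncRNA")
})

test_that("miRNA abundance ratios are scale-invariant totals", {
  cnt <- rbind(gene1 = c(4000, 100), lnc1 = c(1000, 100),
               mi1 = c(600, 50), mi2 = c(400, 50),
               sn1 = c(100, 20), sno1 = c(50, 10))
  se <- SpreadExperiment(cnt, biotype = c("coding", "lncRNA", "miRNA",
                                          "miRNA", "snRNA", "snoRNA"))
  r <- mirAbundanceRatios(se)
  expect_equal(r$mir_sn_ratio[1], 1000 / 100)
  expect_equal(r$mir_sno_ratio[1], 1000 / 50)
  expect_equal(r$mir_long_ratio_sn[1], (1000 / 100) / (5000 / 100))
  ## per-snRNA and per-snoRNA long-RNA ratios cancel identically
  expect_equal(r$mir_long_ratio_sn, r$mir_long_ratio_sno)
  ## global per-sample scaling cancels
  se2 <- SpreadExperiment(cbind(cnt[, 1] * 3, cnt[, 2] * 7),
                          biotype = biotype(se))
  expect_equal(mirAbundanceRatios(se2)$mir_sn_ratio, r$mir_sn_ratio)
  expect_error(mirAbundanceRatios(logCPM(se)), "raw")
})

test_that("compareGroups is the pooled two-sided Student t-test", {
  r <- compareGroups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(r$p, 0.02131164, tolerance = 1e-6)
  expect_equal(r$df, 4)
  ## label swap flips the sign but not the p-value
  r2 <- compareGroups(c(1, 2, 3, 4, 5, 6),
                      factor(rep(c("a", "b"), each = 3),
                             levels = c("b", "a")))
  expect_equal(r2$p, r$p)
  expect_equal(r2$statistic, -r$statistic)
  ident <- compareGroups(rep(1, 6), rep(c("a", "b"), each = 3))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p, 1)
  expect_error(compareGroups(1:6, rep("a", 6)), "two groups")
})

test_that("meanExpressionBySpread isolates a planted lncRNA shift in solid tissue", {
  set.seed(21)
  nG <- 150; nL <- 80
  bt <- rep(c("coding", "lncRNA"), c(nG, nL))
  ann <- expand.grid(tissue = c("P", "M", "A", "S"),
                     spread = c("miliary", "non-miliary"),
                     rep = 1:3, stringsAsFactors = FALSE)
  x <- matrix(rnorm((nG + nL) * nrow(ann), 5, 1), nG + nL, nrow(ann))
  sel <- ann$spread == "non-miliary" & ann$tissue %in% c("P", "M")
  x[bt == "lncRNA", sel] <- x[bt == "lncRNA", sel] + 1
  se <- SpreadExperiment(x, biotype = bt, colData = ann,
                         libSizes = rep(1e6, nrow(ann)), scale = "log_cpm")
  res <- meanExpressionBySpread(se)
  ## one row per gene, tissue class and spread type
  expect_equal(nrow(res$means), (nG + nL) * 4)
  tst <- res$tests
  pmLnc <- tst[tst$biotype == "lncRNA" & tst$tissue_class == "PM", ]
  pmCod <- tst[tst$biotype == "coding" & tst$tissue_class == "PM", ]
  expect_lt(pmLnc$p, 1e-6)
  expect_gt(pmLnc$mean_diff, 0.5)       # higher in non-miliary
  expect_gt(pmCod$p, 0.05)              # coding untouched
  asLnc <- tst[tst$biotype == "lncRNA" & tst$tissue_class == "AS", ]
  expect_gt(asLnc$p, 0.05)              # ascites untouched
})

test_that("identical spread groups give null gene-wise comparisons", {
  bt <- rep(c("coding", "lncRNA"), c(10, 10))
  ann <- expand.grid(tissue = c("P", "A"),
                     spread = c("miliary", "non-miliary"),
                     stringsAsFactors = FALSE)
  x <- matrix(rep(rnorm(20, 5), 4), 20, 4)   # same values in all samples
  se <- SpreadExperiment(x, biotype = bt, colData = ann,
                         libSizes = rep(1e6, 4), scale = "log_cpm")
  res <- meanExpressionBySpread(se)
  expect_true(all(res$tests$mean_diff == 0))
  expect_true(all(res$tests$p == 1))
})
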