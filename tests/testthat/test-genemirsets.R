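universe100 <- paste0("g", 1:100)

test_that("Fisher assignment matches enumeration on the worked examples", {
  ## a miRNA targeting the whole universe cannot be enriched
  tg <- data.frame(mirna = "m1", gene = universe100)
  all_tab <- assignMiRsToGeneSet(universe100[1:5], tg, universe100,
                                 onlyAssigned = FALSE)
  expect_equal(all_tab$p, 1)
  expect_equal(nrow(assignMiRsToGeneSet(universe100[1:5], tg, universe100)), 0)
  ## miRNA targeting exactly the 5-gene set: p = 1 / choose(100, 5)
  tg2 <- data.frame(mirna = "m2", gene = universe100[1:5])
  a2 <- assignMiRsToGeneSet(universe100[1:5], tg2, universe100,
                            onlyAssigned = FALSE)
  expect_equal(a2$p, 1 / choose(100, 5), tolerance = 1e-12)
  ## 5 of 10 set genes among 50 targeted in a universe of 1000
  uni <- paste0("u", 1:1000)
  tg3 <- data.frame(mirna = "m3", gene = uni[c(1:5, 100:144)])
  a3 <- assignMiRsToGeneSet(uni[1:10], tg3, uni, onlyAssigned = FALSE)
  expect_equal(a3$p, hyperTailOracle(5, 50, 1000, 10), tolerance = 1e-12)
})

test_that("assignment p equals the hypergeometric-tail oracle on small tables", {
  for (N in c(5, 12, 25)) {
    uni <- paste0("g", seq_len(N))
    for (K in c(1, floor(N / 3), N - 1)) {
      tg <- data.frame(mirna = "m", gene = uni[seq_len(K)])
      for (n in c(1, floor(N / 2))) {
        for (shift in 0:min(2, N - n)) {
          gs <- uni[seq_len(n) + shift]
          a <- assignMiRsToGeneSet(gs, tg, uni, onlyAssigned = FALSE)
          expect_equal(a$p,
                       hyperTailOracle(sum(gs %in% tg$gene), K, N, n),
                       tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("assignment contracts and the all-genes background variant hold", {
  tg <- data.frame(mirna = "m1", gene = universe100[1:20])
  expect_error(assignMiRsToGeneSet(character(), tg, universe100), "empty")
  expect_error(assignMiRsToGeneSet("zzz", tg, universe100), "outside")
  incl <- assignMiRsToGeneSet(universe100[1:10], tg, universe100,
                              onlyAssigned = FALSE,
                              backgroundIncludesSet = TRUE)
  expect_true(incl$p >= 0 && incl$p <= 1)
})

test_that("set deregulation test is exact in its degenerate cases", {
  s <- setNames(rep(0, 50), paste0("f", 1:50))
  r <- setDeregulationTest(s, names(s)[1:10], nPerm = 100, seed = 1)
  expect_equal(r$p, 1)
  expect_identical(r$direction, "up")
  ## competitive test of the whole feature universe is null by construction
  s2 <- setNames(rnorm(100), paste0("f", 1:100))
  r2 <- setDeregulationTest(s2, names(s2), nPerm = 100, seed = 1)
  expect_equal(r2$p, 1)
})

test_that("a strongly deregulated set is detected by the permutation test", {
  for (seed in 1:3) {
    set.seed(seed)
    s <- setNames(c(rep(3, 20), rnorm(1000)),
                  paste0("f", 1:1020))
    r <- setDeregulationTest(s, names(s)[1:20], nPerm = 2000, seed = seed)
    expect_lt(r$p, 0.01)
    expect_identical(r$direction, "up")
  }
})

test_that("permutation p-values are valid under the competitive null", {
  set.seed(10)
  s <- setNames(rnorm(500), paste0("f", 1:500))
  nPerm <- 199
  p <- vapply(1:300, function(i)
    setDeregulationTest(s, sample(names(s), 15), nPerm = nPerm)$p,
    numeric(1))
  expect_lte(mean(p <= 0.05), 0.05 + 2 / sqrt(nPerm))
})

test_that("Fisher's method combination matches its closed form", {
  expect_equal(combineGeneMiRPvalues(1, 1), 1)
  ## chi-square(4) survival function: exp(-x/2) (1 + x/2)
  x <- -2 * (log(0.05) + log(0.05))
  expect_equal(combineGeneMiRPvalues(0.05, 0.05),
               exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  expect_equal(combineGeneMiRPvalues(0.05, 0.05), 0.0174787,
               tolerance = 1e-5)
  expect_equal(combineGeneMiRPvalues(0.2, 0.7),
               combineGeneMiRPvalues(0.7, 0.2))
  expect_warning(combineGeneMiRPvalues(0, 0.5), "clipped")
})

test_that("concordance summary counts opposite-direction sets correctly", {
  sets <- data.frame(q_combined = rep(0.01, 6),
                     dir_gene = rep("down", 6), dir_mir = rep("up", 6))
  cs <- concordanceSummary(sets, c(0.05, 0.5))
  expect_equal(cs$curve$pct_opposite, c(100, 100))
  expect_equal(cs$curve$pct_gene_down_mir_up, c(100, 100))
  expect_equal(cs$nSignificant, 6)
  ## coin-flip directions are opposite about half the time
  set.seed(11)
  flip <- data.frame(
    q_combined = runif(1000, 0, 0.04),
    dir_gene = sample(c("up", "down"), 1000, TRUE),
    dir_mir = sample(c("up", "down"), 1000, TRUE))
  pct <- concordanceSummary(flip, 0.05)$curve$pct_opposite
  expect_lt(abs(pct - 50), 6)
  ## no sets below cutoff: percentages are missing, not zero
  none <- concordanceSummary(sets, 0.001)$curve
  expect_true(is.na(none$pct_opposite))
  expect_error(concordanceSummary(sets, numeric()), "empty")
})

test_that("buildGeneMiRSets composes the pipeline and handles no targets", {
  set.seed(12)
  genes <- paste0("g", 1:300)
  sg <- fitFeatureStats(matrix(rnorm(300 * 10), 300, 10,
                               dimnames = list(genes, NULL)),
                        rep(0:1, each = 5))
  sm <- fitFeatureStats(matrix(rnorm(30 * 10), 30, 10,
                               dimnames = list(paste0("m", 1:30), NULL)),
                        rep(0:1, each = 5))
  tg <- data.frame(mirna = rep(paste0("m", 1:30), each = 20),
                   gene = sample(genes, 600, TRUE))
  gs <- list(A = genes[1:40], B = genes[41:80])
  res <- buildGeneMiRSets(gs, tg, sg, sm, nPerm = 200, seed = 1)
  expect_equal(res$set_id, c("A", "B"))
  expect_true(all(res$p_gene > 0 & res$p_gene <= 1))
  ## same seed reproduces the permutation p-values
  res2 <- buildGeneMiRSets(gs, tg, sg, sm, nPerm = 200, seed = 1)
  expect_equal(res$p_gene, res2$p_gene)
  expect_equal(res$p_mir, res2$p_mir)
  ## without a target table every miR set is empty: no combined p produced
  res0 <- buildGeneMiRSets(gs, NULL, sg, sm, nPerm = 200, seed = 1)
  expect_equal(res0$n_mirs, c(0L, 0L))
  expect_true(all(is.na(res0$p_combined)))
})
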