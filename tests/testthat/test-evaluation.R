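# Linkage intervals, ranks, pooled ROC, Wilcoxon, LOOCV machinery.

test_that("buildInterval balances around the gene and spills at ends", {
  G <- 1000
  cat <- GeneCatalog(sprintf("g%04d", 1:G), rep("1", G), 1:G)
  net <- WeightedNetwork(1:(G - 1), 2:G, rep(0.5, G - 1), nGenes = G)
  iv <- buildInterval(500, cat, net, 100)
  expect_length(iv, 100)
  expect_false(500 %in% iv)
  expect_identical(iv, setdiff(450:550, 500L))
  # at the chromosome start the interval is downstream only
  iv2 <- buildInterval(1, cat, net, 100)
  expect_identical(iv2, 2:101)
  # non-network genes are skipped for the next nearest network gene
  net2 <- WeightedNetwork(seq(1, G - 2, by = 2), seq(3, G, by = 2),
                          rep(0.5, length(seq(1, G - 2, by = 2))),
                          nGenes = G)   # odd genes only
  iv3 <- buildInterval(501, cat, net2, 10)
  expect_true(all(iv3 %% 2 == 1))
  expect_identical(sort(iv3), as.integer(setdiff(seq(491, 511, 2), 501)))
  # chromosome too short
  catS <- GeneCatalog(c("a", "b", "c"), rep("1", 3), 1:3)
  netS <- WeightedNetwork(c(1, 2), c(2, 3), c(0.5, 0.5))
  expect_error(buildInterval(2, catS, netS, 100), "only 2 network genes")
})

test_that("rankOf is pessimistic on ties and antitone in the gene's score", {
  cand <- 1:101
  s <- c(100, seq_len(100))          # gene 1 strictly highest
  expect_equal(rankOf(1, cand, s), 2L)  # tied with candidate 101 (score 100)
  s[1] <- 101
  expect_equal(rankOf(1, cand, s), 1L)
  # 60 strictly above, 40 tied: rank = 60 + 40 + 1 = 101
  s2 <- c(0, rep(1, 60), rep(0, 40))
  expect_equal(rankOf(1, 1:101, s2), 101L)
  # all distinct: 1 + #higher
  withr::local_seed(31)
  s3 <- sample(101)
  expect_equal(rankOf(7, 1:101, s3), 1L + sum(s3 > s3[7]))
  # raising the gene's score never worsens its rank
  base <- runif(101)
  r <- vapply(seq(0, 1, 0.1), function(delta) {
    s4 <- base; s4[50] <- s4[50] + delta
    rankOf(50, 1:101, s4)
  }, integer(1))
  expect_true(all(diff(r) <= 0))
  expect_error(rankOf(200, cand, s), "among the candidates")
})

test_that("pooled AUC equals the concordant-pair oracle, with tie handling", {
  withr::local_seed(17)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)   # heavy ties
    labels <- runif(n) < 0.3
    if (!any(labels)) labels[1] <- TRUE
    if (all(labels)) labels[1] <- FALSE
    roc <- pooledROC(scores, labels = labels)
    expect_equal(roc$auc, bruteAUC(scores, labels))
    expect_equal(utils::tail(roc$curve$tpr, 1), 1)
    expect_equal(utils::tail(roc$curve$fpr, 1), 1)
    expect_true(all(diff(roc$curve$tpr) >= 0), info = "tpr monotone")
  }
  # separable: AUC exactly 1
  expect_equal(pooledROC(c(5, 4, 1, 0), labels = c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  # all-identical scores: AUC 0.5 with a warning
  expect_warning(r0 <- pooledROC(rep(1, 6),
                                 labels = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)),
                 "identical")
  expect_equal(r0$auc, 0.5)
})

test_that("the exact signed-rank test agrees with full enumeration", {
  withr::local_seed(23)
  for (i in 1:50) {
    n <- sample(3:10, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- sample(1:6, n, replace = TRUE)
    if (all(x == y)) x[1] <- x[1] + 1L
    ours <- wilcoxonSignedRank(x, y)
    oracle <- bruteSignedRank(x, y)
    expect_equal(ours$statistic, oracle$statistic)
    expect_equal(ours$p.greater, oracle$p.greater, tolerance = 1e-12)
    expect_equal(ours$p.less, oracle$p.less, tolerance = 1e-12)
  }
  # uniform improvement by 1 in 20 pairs: one-sided p = 2^-20
  res <- wilcoxonSignedRank(rep(2, 20), rep(1, 20))
  expect_equal(res$p.greater, 2^-20)
  # no ties, moderate n: matches stats::wilcox.test exactly
  x <- c(10, 8, 7, 5, 9, 3, 12, 6)
  y <- x - c(1, -2, 3, -4, 5, -6, 7, -8)   # distinct |differences|
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(wilcoxonSignedRank(x, y)$p.value, ref$p.value)
  # normal approximation path is sane for large n
  withr::local_seed(29)
  big <- wilcoxonSignedRank(rnorm(60, 0.5), rnorm(60))
  expect_identical(big$method, "normal")
  expect_true(big$p.value > 0 && big$p.value <= 1)
})

test_that("compareRankings counts direction correctly and degenerates to p = 1", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 4)
  cmp <- compareRankings(a, b)
  expect_equal(cmp$better, 3); expect_equal(cmp$tie, 1)
  expect_equal(cmp$worse, 0)
  same <- compareRankings(a, a)
  expect_equal(same$p.value, 1)
  expect_equal(c(same$better, same$tie, same$worse), c(0, 4, 0))
})

test_that("attenuateUnexpressed zeros exactly the unexpressed complement", {
  res <- new("PropagationResult", disease = "d", label = "x",
             scores = c(0.5, 0.2, 0.9, 0.1))
  att <- attenuateUnexpressed(res, c(2, 4))
  expect_identical(geneScores(att), c(0, 0.2, 0, 0.1))
  expect_identical(geneScores(attenuateUnexpressed(res, 1:4)),
                   geneScores(res))
  expect_identical(geneScores(attenuateUnexpressed(res, integer())),
                   rep(0, 4))
})

test_that("LOOCV honors holdout semantics on a constructed instance", {
  # two diseases share gene 1; holding out one must drop both from the prior
  G <- 60
  cat <- GeneCatalog(sprintf("g%02d", 1:G), rep("1", G), 1:G)
  net <- WeightedNetwork(1:(G - 1), 2:G, rep(0.9, G - 1), nGenes = G,
                         nodes = 1:G)
  sim <- DiseaseSimilarity(matrix(c(1, 0.9, 0.9, 1), 2,
                                  dimnames = list(c("dA", "dB"),
                                                  c("dA", "dB"))))
  assocs <- GeneDiseaseAssociations(c(1, 1), c("dA", "dB"))
  calls <- matrix(TRUE, G, 2, dimnames = list(NULL, c("t1", "t2")))
  prof <- tinyProfiles(calls)
  mas <- matrix(c(80, 20, 80, 20), 2, byrow = TRUE,
                dimnames = list(c("dA", "dB"), c("t1", "t2")))
  asg <- assignTissues(DiseaseTissueMatrix(mas), 40)
  res <- runLOOCV(assocs, asg, cat, net, prof, sim,
                  variants = list(generic = networkVariant("generic")),
                  intervalSize = 20)
  # with every association of gene 1 removed, the prior is empty and all
  # candidate scores are zero: pessimistic ties put the gene last
  expect_equal(unname(res$ranks[, "generic"]), c(21L, 21L))
  # determinism
  res2 <- runLOOCV(assocs, asg, cat, net, prof, sim,
                   variants = list(generic = networkVariant("generic")),
                   intervalSize = 20)
  expect_identical(res$ranks, res2$ranks)
})

test_that("generic-network LOOCV ignores the MAS matrix", {
  b <- smallPlantedBundle()
  res1 <- runLOOCV(b$assocs, b$assign, b$catalog, b$network, b$profiles,
                   b$sim, variants = list(generic = networkVariant("generic")),
                   intervalSize = 60)
  # scramble the tissue columns of the MAS matrix (keeping assignments'
  # retained set identical is not needed: compare on the shared cases)
  perm <- masValues(b$dtm)[, rev(tissueNames(b$dtm))]
  colnames(perm) <- tissueNames(b$dtm)
  asg2 <- assignTissues(DiseaseTissueMatrix(perm), 40)
  res2 <- runLOOCV(b$assocs, asg2, b$catalog, b$network, b$profiles,
                   b$sim, variants = list(generic = networkVariant("generic")),
                   intervalSize = 60, expressedOnly = FALSE)
  shared <- intersect(paste(res1$cases$gene, res1$cases$disease),
                      paste(res2$cases$gene, res2$cases$disease))
  expect_gt(length(shared), 0)
  i1 <- match(shared, paste(res1$cases$gene, res1$cases$disease))
  i2 <- match(shared, paste(res2$cases$gene, res2$cases$disease))
  expect_identical(res1$ranks[i1, "generic"], res2$ranks[i2, "generic"])
})

test_that("NR zero-score rule ranks unexpressed causal genes last among zeros", {
  b <- smallPlantedBundle()
  # force one case's gene unexpressed in its tissue and evaluate NR there
  tr <- b$truth
  g <- tr$causalGene[1]; home <- tr$homeTissue[1]
  calls <- presenceCalls(b$profiles)
  calls[g, home] <- FALSE
  prof2 <- tinyProfiles(calls)
  res <- runLOOCV(b$assocs, b$assign, b$catalog, b$network, prof2, b$sim,
                  variants = list(nr = networkVariant("nr")),
                  intervalSize = 60, expressedOnly = FALSE)
  i <- which(res$cases$gene == g)
  cand <- res$candidates[[i]]
  s <- res$scores$nr[[i]]
  expect_equal(s[match(g, cand)], 0)
  nZero <- sum(s == 0)
  expect_equal(unname(res$ranks[i, "nr"]), length(cand))
  expect_gte(nZero, 1)
})

test_that("k-fold AUC spread is reproducible and degenerates sensibly", {
  b <- smallPlantedBundle()
  ks <- kfoldAucSpread(b$assocs, b$assign, b$catalog, b$network, b$profiles,
                       b$sim, variant = networkVariant("erw", rw = 0.1),
                       k = 5, nPartitions = 3, seed = 7, intervalSize = 60)
  ks2 <- kfoldAucSpread(b$assocs, b$assign, b$catalog, b$network, b$profiles,
                        b$sim, variant = networkVariant("erw", rw = 0.1),
                        k = 5, nPartitions = 3, seed = 7, intervalSize = 60)
  expect_identical(ks$aucs, ks2$aucs)
  expect_equal(ks$sdAUC, sd(ks$aucs))
  expect_error(kfoldAucSpread(b$assocs, b$assign, b$catalog, b$network,
                              b$profiles, b$sim, k = 10000, seed = 1,
                              intervalSize = 60), "exceeds")
  expect_warning(kfoldAucSpread(b$assocs, b$assign, b$catalog, b$network,
                                b$profiles, b$sim,
                                variant = networkVariant("generic"),
                                k = 5, nPartitions = 1, seed = 3,
                                intervalSize = 60), "single partition")
})

test_that("the rw sweep endpoints reproduce the generic and NR limits", {
  b <- plantedBenchmark(syntheticConfig(nGenes = 400L, nTissues = 4L,
                                        nDiseases = 15L, familySize = 5L,
                                        chromSize = 100L, seed = 19),
                        decoysPerGene = 3L)
  sweep <- rwSweep(b$assocs, b$assign, b$catalog, b$network, b$profiles,
                   b$sim, gridStep = 0.5, intervalSize = 60)
  tab <- sweep$table
  generic <- pooledROC(runLOOCV(b$assocs, b$assign, b$catalog, b$network,
                                b$profiles, b$sim,
                                variants = list(g = networkVariant("generic")),
                                intervalSize = 60), "g")$auc
  expect_equal(tab$auc[tab$rw == 1], generic)
  expect_true(sweep$rwStar %in% tab$rw)
  expect_gte(max(tab$auc), generic)
})
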