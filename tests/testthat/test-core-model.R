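# Domain types, validation, and the on-disk formats.

test_that("class validity rejects each invariant violation", {
  expect_error(WeightedNetwork(1, 1, 0.5), "self-loop")
  expect_error(validObject(new("WeightedNetwork", nGenes = 3L,
                               nodes = c(1L, 2L), from = 1L, to = 2L,
                               weight = 1.5)), "weights")
  expect_error(validObject(new("WeightedNetwork", nGenes = 3L,
                               nodes = c(1L, 2L), from = c(1L, 1L),
                               to = c(2L, 2L), weight = c(0.5, 0.6))),
               "duplicate edge")
  expect_error(DiseaseTissueMatrix(matrix(c(60, 50), 1,
                                          dimnames = list("d1", c("a", "b")))),
               "sums to")
  expect_silent(DiseaseTissueMatrix(matrix(c(60, 40), 1,
                                           dimnames = list("d1", c("a", "b")))))
  expect_error(validObject(new("GeneDiseaseAssociations",
                               gene = c(1L, 1L), disease = c("d", "d"))),
               "duplicate association")
  expect_error(DiseaseSimilarity(matrix(c(1, 0.2, 0.4, 1), 2,
                                        dimnames = list(c("a", "b"),
                                                        c("a", "b")))),
               "symmetric")
  expect_error(validObject(GeneCatalog(c("g1", "g2"), c("1", "1"),
                                       c(3, 3))),
               "duplicate genomic position")
})

test_that("negative AD values are floored at construction with a warning", {
  m <- matrix(c(-5, 100), 1, dimnames = list(NULL, c("a", "b")))
  expect_warning(e <- ExpressionMatrix(m), "flooring")
  expect_identical(exprValues(e)[1, ], c(a = 0, b = 100))
})

test_that("sectioned edge-list parsing handles sections, rows and errors", {
  f <- withr::local_tempfile()
  writeLines(c("#liver", "3 7 0.85", "1 2 0.5", "#brain", "2 3 1"), f)
  nets <- readSectionedEdgeLists(f)
  expect_named(nets, c("liver", "brain"))
  liver <- edges(nets$liver)
  expect_equal(liver[liver$from == 3, "weight"], 0.85)
  expect_equal(nrow(edges(nets$brain)), 1L)

  writeLines(c("#t", "3 3 0.5"), f)
  expect_error(readSectionedEdgeLists(f), "line 2: self-loop")
  writeLines(c("#t", "1 2 1.5"), f)
  expect_error(readSectionedEdgeLists(f), "outside \\(0, 1\\]")
  writeLines(c("#t", "1 2 0.4", "2 1 0.4"), f)
  expect_error(readSectionedEdgeLists(f), "duplicate edge")
  writeLines(c("#t", "1 2"), f)
  expect_error(readSectionedEdgeLists(f), "line 2")
  writeLines(c("1 2 0.4"), f)
  expect_error(readSectionedEdgeLists(f), "before any")
})

test_that("edge-list writer round-trips exactly, including empty sections", {
  f <- withr::local_tempfile()
  nets <- list(a = WeightedNetwork(c(1, 2, 5), c(2, 3, 9),
                                   c(0.1, 1, 0.123456789123456789)),
               b = WeightedNetwork(3, 4, 0.5))
  writeSectionedEdgeLists(nets, f)
  back <- readSectionedEdgeLists(f)
  expect_identical(lapply(back, edges), lapply(nets, edges))
  expect_identical(edges(back$a)$weight[1], 0.1)

  empty <- new("WeightedNetwork", nGenes = 0L, nodes = integer(),
               from = integer(), to = integer(), weight = numeric())
  writeSectionedEdgeLists(list(x = empty, y = nets$b), f)
  back <- readSectionedEdgeLists(f)
  expect_identical(numEdges(back$x), 0L)
})

test_that("random reader/writer round trips are bit-exact", {
  withr::local_seed(7)
  for (i in 1:10) {
    nets <- lapply(seq_len(3), function(j) randomNetwork(sample(5:30, 1)))
    names(nets) <- paste0("tissue", seq_along(nets))
    f <- withr::local_tempfile()
    writeSectionedEdgeLists(nets, f)
    back <- readSectionedEdgeLists(f)
    expect_identical(lapply(back, edges), lapply(nets, edges))
  }
})

test_that("TSV readers build typed objects and name offenders", {
  dir <- withr::local_tempdir()
  cat <- GeneCatalog(c("g1", "g2", "g3"), c("1", "1", "2"), c(1, 2, 1))
  writeGeneCatalog(cat, file.path(dir, "catalog.tsv"))
  expect_identical(geneIds(readGeneCatalog(file.path(dir, "catalog.tsv"))),
                   c("g1", "g2", "g3"))

  writeLines(c("gene\tliver\tbrain", "g1\t100\t300", "g2\t0\t250",
               "g3\t500\t10"), file.path(dir, "expr.tsv"))
  e <- readExpressionMatrix(file.path(dir, "expr.tsv"), cat)
  expect_equal(dim(exprValues(e)), c(3L, 2L))
  expect_equal(unname(exprValues(e)[3, "liver"]), 500)
  writeLines(c("gene\tliver", "gX\t1"), file.path(dir, "bad.tsv"))
  expect_error(readExpressionMatrix(file.path(dir, "bad.tsv"), cat), "gX")

  sim <- DiseaseSimilarity(matrix(c(1, 0.3, 0.3, 1), 2,
                                  dimnames = list(c("d1", "d2"),
                                                  c("d1", "d2"))))
  writeLines(c("gene\tdisease", "g1\td1", "g2\td2"),
             file.path(dir, "assoc.tsv"))
  a <- readAssociations(file.path(dir, "assoc.tsv"), cat, sim)
  expect_identical(associations(a)$gene, c(1L, 2L))
  writeLines(c("gene\tdisease", "g1\tdZ"), file.path(dir, "assoc2.tsv"))
  expect_error(readAssociations(file.path(dir, "assoc2.tsv"), cat, sim),
               "dZ")

  writeLines(c("disease\ta\tb", "d1\t60\t40", "d2\t30\t70"),
             file.path(dir, "mas.tsv"))
  m <- readMasMatrix(file.path(dir, "mas.tsv"), sim)
  expect_equal(masValues(m)["d1", "a"], 60)
  writeLines(c("disease\ta\tb", "d1\t60\t50"), file.path(dir, "mas2.tsv"))
  expect_error(readMasMatrix(file.path(dir, "mas2.tsv")), "d1")
})

test_that("TSV writers round-trip the synthetic bundle", {
  b <- generateBundle(syntheticConfig(nGenes = 120L, nTissues = 4L,
                                      nDiseases = 8L, familySize = 4L,
                                      chromSize = 60L, seed = 5))
  dir <- withr::local_tempdir()
  writeBundle(b, dir)
  cat2 <- readGeneCatalog(file.path(dir, "catalog.tsv"))
  expect_identical(geneIds(cat2), geneIds(b$catalog))
  expect_identical(cat2@chrom, b$catalog@chrom)
  e2 <- readExpressionMatrix(file.path(dir, "expression.tsv"), cat2)
  expect_identical(exprValues(e2), exprValues(b$expr))
  s2 <- readDiseaseSimilarity(file.path(dir, "similarity.tsv"))
  expect_identical(simValues(s2), simValues(b$sim))
  m2 <- readMasMatrix(file.path(dir, "mas.tsv"), s2)
  expect_identical(masValues(m2), masValues(b$dtm))
  a2 <- readAssociations(file.path(dir, "associations.tsv"), cat2, s2)
  expect_identical(associations(a2), associations(b$assocs))
  n2 <- readSectionedEdgeLists(file.path(dir, "network.txt"),
                               nGenes = numGenes(cat2))$generic
  expect_identical(edges(n2), edges(b$network))
})
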