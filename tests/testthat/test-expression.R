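# Probe collapsing, presence calls, and the expression-centric statistics.

test_that("collapseProbes averages replicates then takes the max probe", {
  pm <- rbind(pA = c(100, 300, 50), pB = c(150, 690, 80),
              pC = c(10, 20, 900))
  colnames(pm) <- c("s1", "s2", "s3")
  s2t <- c(s1 = "liver", s2 = "liver", s3 = "brain")
  p2g <- c(pA = "g1", pB = "g1", pC = "g2")
  m <- collapseProbes(pm, p2g, s2t)
  # probe A averages to (200, 50); probe B to (420, 80): B has the larger
  # across-tissue mean, so gene g1 keeps probe B everywhere
  expect_equal(m["g1", "liver"], 420)
  expect_equal(m["g1", "brain"], 80)
  expect_equal(m["g2", "brain"], 900)

  # single probe, single sample passes through unchanged
  one <- matrix(123, 1, 1, dimnames = list("p", "s"))
  expect_equal(collapseProbes(one, c(p = "g"), c(s = "t"))["g", "t"], 123)

  # catalog version reports probe-less genes and fills zeros
  cat3 <- GeneCatalog(c("g1", "g2", "g3"), c("1", "1", "1"), 1:3)
  expect_message(e <- collapseProbes(pm, p2g, s2t, cat3), "no probe")
  expect_equal(exprValues(e)[3, ], c(liver = 0, brain = 0))
})

test_that("binarize is inclusive at the threshold and monotone in tau", {
  m <- matrix(c(199.99, 200, 0, 1000), 2,
              dimnames = list(NULL, c("a", "b")))
  p <- binarize(ExpressionMatrix(m), 200)
  expect_identical(as.vector(presenceCalls(p)), c(FALSE, TRUE, FALSE, TRUE))
  # tau -> 0+ limit: everything positive is expressed
  pAll <- binarize(ExpressionMatrix(m + 1), 1e-12)
  expect_true(all(presenceCalls(pAll)))
  # raising tau never adds a call
  withr::local_seed(1)
  mm <- ExpressionMatrix(matrix(runif(200, 0, 500), 20,
                                dimnames = list(NULL, paste0("t", 1:10))))
  taus <- sort(runif(6, 1, 450))
  for (k in seq_len(length(taus) - 1)) {
    lo <- presenceCalls(binarize(mm, taus[k]))
    hi <- presenceCalls(binarize(mm, taus[k + 1]))
    expect_true(all(lo >= hi))
  }
})

test_that("expressionBreadth counts tissues", {
  calls <- cbind(t1 = c(TRUE, FALSE, TRUE), t2 = c(TRUE, FALSE, FALSE),
                 t3 = c(TRUE, FALSE, TRUE))
  p <- tinyProfiles(calls)
  expect_identical(expressionBreadth(p), c(3L, 0L, 2L))
  expect_identical(expressionBreadth(p, 3), 2L)
  expect_error(expressionBreadth(p, 9), "unknown gene")
})

test_that("assignTissues takes the MAS row argmax and flags exclusions", {
  m <- DiseaseTissueMatrix(matrix(c(70, 20, 10,
                                    30, 45, 25), 2, byrow = TRUE,
                                  dimnames = list(c("d1", "d2"),
                                                  c("a", "b", "c"))))
  asg <- assignTissues(m, masThreshold = 60)
  tab <- assignmentTable(asg)
  expect_identical(tab$tissue, c("a", "b"))
  expect_identical(tab$excluded, c(FALSE, TRUE))
})

test_that("expressedFraction counts correctly and errors on empty sets", {
  calls <- cbind(a = c(TRUE, TRUE, FALSE, TRUE), b = rep(FALSE, 4))
  p <- tinyProfiles(calls)
  m <- DiseaseTissueMatrix(matrix(rep(c(80, 20), 4), 4, byrow = TRUE,
                                  dimnames = list(paste0("d", 1:4),
                                                  c("a", "b"))))
  asg <- assignTissues(m, 40)
  assocs <- GeneDiseaseAssociations(1:4, paste0("d", 1:4))
  ef <- expressedFraction(assocs, asg, p)
  expect_equal(ef$fraction, 0.75)
  expect_equal(nrow(ef$expressedSet), 3L)
  expect_error(expressedFraction(assocs, asg, p, masThreshold = 90),
               "no associations")
  # order invariance
  o <- c(3, 1, 4, 2)
  ef2 <- expressedFraction(GeneDiseaseAssociations((1:4)[o],
                                                   paste0("d", 1:4)[o]),
                           asg, p)
  expect_equal(ef2$fraction, ef$fraction)
})

test_that("assignment-permutation null matches a brute-force loop", {
  withr::local_seed(3)
  calls <- matrix(runif(60) < 0.5, 12, 5,
                  dimnames = list(NULL, paste0("t", 1:5)))
  p <- tinyProfiles(calls)
  D <- 8
  mas <- matrix(5, D, 5, dimnames = list(paste0("d", 1:D), paste0("t", 1:5)))
  home <- sample(5, D, replace = TRUE)
  mas[cbind(seq_len(D), home)] <- 80
  asg <- assignTissues(DiseaseTissueMatrix(mas), 40)
  assocs <- GeneDiseaseAssociations(sample(12, D), paste0("d", 1:D))
  pn <- permuteAssignmentNull(assocs, asg, p, nPerm = 300, seed = 99)

  # independent re-implementation of the permutation loop at the same seed
  tab <- associations(assocs)
  tis <- assignmentTable(asg)$tissue
  set.seed(99)
  null2 <- replicate(300, {
    pt <- tis[sample.int(D)]
    mean(calls[cbind(tab$gene, match(pt, colnames(calls)))])
  })
  expect_equal(pn$null, null2)
  expect_equal(pn$p, (1 + sum(null2 >= pn$observed)) / 301)
})

test_that("degenerate single-tissue assignment yields p = 1", {
  calls <- cbind(a = c(TRUE, FALSE), b = c(TRUE, TRUE))
  p <- tinyProfiles(calls)
  mas <- matrix(c(90, 10, 90, 10), 2, byrow = TRUE,
                dimnames = list(c("d1", "d2"), c("a", "b")))
  asg <- assignTissues(DiseaseTissueMatrix(mas), 0)
  assocs <- GeneDiseaseAssociations(1:2, c("d1", "d2"))
  expect_warning(pn <- permuteAssignmentNull(assocs, asg, p, nPerm = 50,
                                             seed = 1), "degenerate")
  expect_equal(pn$p, 1)
})

test_that("an extreme observed fraction reports the add-one bound", {
  # every causal gene expressed only in its own assigned tissue: permuting
  # assignments destroys all matches, so the observed fraction of 1 tops
  # every permutation and p hits 1/(nPerm+1)
  T <- 6
  calls <- diag(TRUE, T); colnames(calls) <- paste0("t", 1:T)
  p <- tinyProfiles(calls)
  mas <- matrix(100 / (T - 1) / 2, T, T,
                dimnames = list(paste0("d", 1:T), paste0("t", 1:T)))
  diag(mas) <- 100 - sum(mas[1, -1])
  asg <- assignTissues(DiseaseTissueMatrix(mas), 0)
  assocs <- GeneDiseaseAssociations(1:T, paste0("d", 1:T))
  pn <- permuteAssignmentNull(assocs, asg, p, nPerm = 400, seed = 8)
  expect_equal(pn$observed, 1)
  expect_lt(pn$p, 0.02)
  expect_equal(pn$p, (1 + sum(pn$null >= 1)) / 401)
})

test_that("matched-random tests agree with a brute-force loop", {
  withr::local_seed(11)
  G <- 30; T <- 4
  ad <- matrix(rlnorm(G * T, log(150), 1), G, T,
               dimnames = list(NULL, paste0("t", 1:T)))
  expr <- ExpressionMatrix(ad)
  prof <- binarize(expr, 200)
  calls <- presenceCalls(prof)
  # pick members lowly expressed in their tissue
  genes <- integer(0); tissues <- character(0)
  for (t in colnames(calls)) {
    low <- which(!calls[, t])
    if (length(low) >= 3) { genes <- c(genes, low[1]); tissues <- c(tissues, t) }
  }
  res <- matchedRandomTests(genes, tissues, prof, expr, nSets = 150,
                            seed = 77)
  # brute-force re-draw with the same seed and sampling scheme
  eligible <- lapply(seq_along(genes), function(k)
    setdiff(which(!calls[, tissues[k]]), genes[k]))
  breadth <- rowSums(calls); level <- rowMeans(ad)
  set.seed(77)
  null2 <- replicate(150, {
    chosen <- integer(length(genes))
    for (k in order(lengths(eligible))) {
      pool <- setdiff(eligible[[k]], chosen)
      chosen[k] <- pool[sample.int(length(pool), 1L)]
    }
    c(mean(breadth[chosen]), mean(level[chosen]))
  })
  expect_equal(res$nullBreadth, null2[1, ])
  expect_equal(res$nullLevel, null2[2, ])
})

test_that("matched-random test flags missing matches and planted extremes", {
  calls <- cbind(a = c(FALSE, TRUE, TRUE), b = c(TRUE, TRUE, FALSE))
  expr <- ExpressionMatrix(matrix(c(0, 300, 300, 300, 300, 0), 3,
                                  dimnames = list(NULL, c("a", "b"))))
  prof <- tinyProfiles(calls)
  expect_error(matchedRandomTests(1, "a", prof, expr, nSets = 5, seed = 1),
               "no other lowly-expressed gene")

  # planted separation: members expressed nowhere else, eligible matches
  # expressed broadly -> breadth p-value at the add-one floor
  withr::local_seed(2)
  T <- 5; G <- 40
  calls <- matrix(TRUE, G, T, dimnames = list(NULL, paste0("t", 1:T)))
  calls[1:5, ] <- FALSE                      # the original set: breadth 0
  calls[6:G, 1] <- FALSE                     # eligible matches in tissue t1
  ad <- ifelse(calls, 500, 10)
  colnames(ad) <- paste0("t", 1:T)
  prof <- tinyProfiles(calls)
  res <- matchedRandomTests(1:5, rep("t1", 5), prof, ExpressionMatrix(ad),
                            nSets = 300, seed = 3)
  expect_lt(res$pBreadth, 0.01)
  expect_equal(res$observedBreadth, 0)
})
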