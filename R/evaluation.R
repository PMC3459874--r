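#' Artificial linkage interval around a gene
#'
#' Builds the candidate decoy set for cross-validation: the `size` network
#' genes genomically nearest to `g` on its chromosome, balanced half
#' upstream / half downstream with spill-over toward the other side at
#' chromosome ends, excluding `g` itself. The scored candidate set of a
#' trial is this interval plus `g`.
#'
#' @param g catalog gene index of the causal gene.
#' @param catalog a [GeneCatalog-class] with genomic order.
#' @param net the generic [WeightedNetwork-class]; only its member genes are
#'   eligible interval candidates.
#' @param size interval size; default 100.
#' @return Integer vector of `size` gene indices (not containing `g`).
#' @export
buildInterval <- function(g, catalog, net, size = 100L) {
  stopifnot(length(g) == 1L, g >= 1L, g <= numGenes(catalog))
  chr <- catalog@chrom[g]
  onChr <- which(catalog@chrom == chr)
  inNet <- intersect(onChr, nodes(net))
  others <- setdiff(inNet, g)
  if (length(others) < size)
    stop(sprintf(
      "chromosome '%s' holds only %d network genes besides gene %d (< %d)",
      chr, length(others), g, size))
  gpos <- catalog@pos[g]
  up <- others[catalog@pos[others] < gpos]
  up <- up[order(catalog@pos[up], decreasing = TRUE)]     # nearest first
  down <- others[catalog@pos[others] > gpos]
  down <- down[order(catalog@pos[down])]
  half <- size %/% 2L
  nUp <- min(length(up), half)
  nDown <- min(length(down), size - nUp)
  nUp <- size - nDown                                     # spill upstream
  if (nUp > length(up))
    stop(sprintf("cannot assemble a %d-gene interval around gene %d", size, g))
  sort(c(up[seq_len(nUp)], down[seq_len(nDown)]))
}

#' Rank of the causal gene among scored candidates
#'
#' Rank by descending score with pessimistic tie handling: the causal gene
#' ranks after every candidate tied with it. Node-removal networks assign
#' exact zeros to all unexpressed candidates, so optimistic tie-breaking
#' would fabricate perfect ranks for unexpressed causal genes; the
#' pessimistic rule makes a zero-scored causal gene rank last among the
#' zeros.
#'
#' @param g catalog index of the causal gene.
#' @param candidates integer vector of scored candidate indices (must
#'   contain `g`).
#' @param scores numeric scores parallel to `candidates` (or a full
#'   catalog-length score vector).
#' @return Integer rank in `[1, length(candidates)]`.
#' @export
rankOf <- function(g, candidates, scores) {
  if (!g %in% candidates) stop("causal gene must be among the candidates")
  s <- if (length(scores) == length(candidates)) scores
       else scores[candidates]
  sg <- s[match(g, candidates)]
  as.integer(sum(s > sg) + sum(s == sg))
}

## --- network variants -------------------------------------------------------

#' Specify a network variant for the benchmark
#'
#' @param method "generic", "nr" (node removal) or "erw" (edge reweight).
#' @param rw penalty factor for "erw".
#' @param attenuate if TRUE, scores of genes not expressed in the case's
#'   tissue are set to 0 in a post-processing step.
#' @return A variant description (list) for [runLOOCV()] and friends.
#' @export
networkVariant <- function(method = c("generic", "nr", "erw"), rw = 0.1,
                           attenuate = FALSE) {
  method <- match.arg(method)
  list(method = method, rw = rw, attenuate = isTRUE(attenuate))
}

#' Default benchmark variants
#'
#' Generic network plus tissue-specific node removal and edge reweighting
#' at the published penalty settings.
#' @return Named list of variant descriptions.
#' @export
defaultVariants <- function() {
  list(generic = networkVariant("generic"),
       nr = networkVariant("nr"),
       `erw:0.1` = networkVariant("erw", rw = 0.1))
}

# cache of normalized operators keyed by variant/tissue
makeOperatorCache <- function(genericNet, profiles) {
  cache <- new.env(parent = emptyenv())
  calls <- presenceCalls(profiles)
  function(variant, tissue) {
    key <- if (variant$method == "generic") "generic"
           else paste(variant$method, variant$rw, tissue, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    net <- switch(variant$method,
      generic = genericNet,
      nr = nodeRemoval(genericNet, which(calls[, tissue])),
      erw = edgeReweight(genericNet, which(calls[, tissue]), variant$rw))
    cache[[key]] <- normalizeNetwork(net, label = key)
    cache[[key]]
  }
}

#' Zero the scores of unexpressed genes
#'
#' Post-processing baseline: set the propagation score of every gene not
#' expressed in the relevant tissue to exactly 0, leaving other scores
#' unchanged. Composable with any network variant; applied to the generic
#' network it is the "attenuated generic" baseline.
#'
#' @param result a [PropagationResult-class].
#' @param expressed integer vector of expressed gene indices.
#' @return A [PropagationResult-class] with attenuated scores.
#' @export
attenuateUnexpressed <- function(result, expressed) {
  stopifnot(is(result, "PropagationResult"))
  s <- result@scores
  s[setdiff(seq_along(s), as.integer(expressed))] <- 0
  new("PropagationResult", disease = result@disease,
      label = paste0(result@label, ":attenuated"), scores = s)
}

# score one case (held-out gene g, disease d, tissue t) under one variant
scoreCase <- function(g, d, tissue, candidates, exclude, variant, getOp,
                      sim, assocs, cfg, calls) {
  wn <- getOp(variant, tissue)
  res <- princeScores(d, wn, sim, assocs, cfg, exclude = exclude)
  if (variant$attenuate)
    res <- attenuateUnexpressed(res, which(calls[, tissue]))
  geneScores(res)[candidates]
}

#' Leave-one-out cross-validation benchmark
#'
#' For every retained gene-disease association `<g,d>`: removes the pair
#' and every other association involving `g`, builds the 100-gene
#' artificial linkage interval around `g`, runs the prioritizer per network
#' variant, and records `g`'s rank among the `size + 1` scored candidates.
#' Genes absent from a node-removal network automatically score 0. With
#' `expressedOnly`, evaluation is restricted to the "expressed disease
#' genes association set" (cases whose causal gene is expressed in its
#' disease's assigned tissue).
#'
#' @param assocs a [GeneDiseaseAssociations-class].
#' @param assign a [TissueAssignment-class].
#' @param catalog a [GeneCatalog-class].
#' @param genericNet the generic [WeightedNetwork-class].
#' @param profiles a [BinaryExpressionProfiles-class].
#' @param sim a [DiseaseSimilarity-class].
#' @param cfg a [PropagationConfig-class].
#' @param variants named list of [networkVariant()] descriptions.
#' @param intervalSize linkage-interval size; default 100.
#' @param expressedOnly restrict to expressed causal genes; default TRUE.
#' @param masThreshold optional MAS threshold override (percent).
#' @return An object of class `loocvResult`: list with `cases` (data.frame
#'   gene/disease/tissue), `ranks` (cases x variants matrix),
#'   `candidates` (list of candidate index vectors) and `scores` (per
#'   variant, list of per-case candidate score vectors).
#' @export
runLOOCV <- function(assocs, assign, catalog, genericNet, profiles, sim,
                     cfg = PropagationConfig(), variants = defaultVariants(),
                     intervalSize = 100L, expressedOnly = TRUE,
                     masThreshold = NULL) {
  tab <- assocWithAssignment(assocs, assign, profiles, masThreshold)
  if (expressedOnly) tab <- tab[tab$expressed, , drop = FALSE]
  if (!nrow(tab)) stop("no evaluation cases retained")
  if (is.null(names(variants)) || any(!nzchar(names(variants))))
    stop("variants must be named")
  calls <- presenceCalls(profiles)
  getOp <- makeOperatorCache(genericNet, profiles)
  full <- associations(assocs)
  candidates <- vector("list", nrow(tab))
  ranks <- matrix(NA_integer_, nrow(tab), length(variants),
                  dimnames = list(NULL, names(variants)))
  scores <- lapply(variants, function(v) vector("list", nrow(tab)))
  for (i in seq_len(nrow(tab))) {
    g <- tab$gene[i]; d <- tab$disease[i]; t <- tab$tissue[i]
    interval <- buildInterval(g, catalog, genericNet, intervalSize)
    cand <- c(interval, g)
    candidates[[i]] <- cand
    exclude <- full[full$gene == g, , drop = FALSE]
    for (v in names(variants)) {
      s <- scoreCase(g, d, t, cand, exclude, variants[[v]], getOp,
                     sim, assocs, cfg, calls)
      scores[[v]][[i]] <- s
      ranks[i, v] <- rankOf(g, cand, s)
    }
  }
  structure(list(cases = tab[, c("gene", "disease", "tissue")],
                 candidates = candidates, ranks = ranks, scores = scores),
            class = "loocvResult")
}

#' Pooled ROC curve and AUC across cross-validation trials
#'
#' Bundles the candidate scores of every trial into one pool (positives:
#' the held-out causal genes; negatives: all other interval candidates,
#' labeled per trial) and computes the ROC step curve and its AUC by the
#' trapezoid rule, which credits ties with 1/2 (the probabilistic
#' Mann-Whitney convention).
#'
#' @param result an object returned by [runLOOCV()], or a numeric score
#'   vector.
#' @param variant variant name to pool (when `result` is a `loocvResult`).
#' @param labels logical vector of positive labels (when `result` is a
#'   score vector).
#' @return List with `auc`, `curve` (data.frame `fpr`, `tpr`, `threshold`),
#'   `nPos`, `nNeg`.
#' @export
pooledROC <- function(result, variant = NULL, labels = NULL) {
  if (inherits(result, "loocvResult")) {
    if (is.null(variant)) variant <- colnames(result$ranks)[1L]
    scores <- unlist(result$scores[[variant]], use.names = FALSE)
    labels <- unlist(lapply(seq_along(result$candidates), function(i)
      result$candidates[[i]] == result$cases$gene[i]), use.names = FALSE)
  } else {
    scores <- as.numeric(result)
    stopifnot(length(labels) == length(scores))
  }
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos < 1L || nNeg < 1L)
    stop("pooled ROC needs at least one positive and one negative")
  if (length(unique(scores)) == 1L)
    warning("all pooled scores identical; AUC is 0.5 by the tie convention")
  r <- rank(scores)                       # ties.method = "average"
  auc <- (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  # step curve over unique thresholds, descending; ties grouped
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- which(!duplicated(grp, fromLast = TRUE))
  curve <- data.frame(fpr = c(0, fp[last] / nNeg),
                      tpr = c(0, tp[last] / nPos),
                      threshold = c(Inf, s[last]))
  list(auc = auc, curve = curve, nPos = nPos, nNeg = nNeg)
}

#' Wilcoxon signed-rank test for paired ranks
#'
#' Zero differences are dropped; |differences| are ranked with average tie
#' ranks. For n <= 25 retained pairs the null distribution of the
#' positive-rank sum is computed exactly by enumerating all 2^n sign
#' assignments via a generating-function recursion (correct under ties);
#' above that, the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y paired numeric vectors.
#' @param exactMax largest n for the exact null; default 25.
#' @return List with `statistic` (positive-rank sum of x - y), `n` (pairs
#'   after zero removal), `p.greater` (P(x > y) direction), `p.less`,
#'   `p.value` (two-sided) and `method`.
#' @export
wilcoxonSignedRank <- function(x, y, exactMax = 25L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = NA_real_, n = 0L, p.greater = 1, p.less = 1,
                p.value = 1, method = "degenerate"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exactMax) {
    s <- as.integer(round(2 * r))         # doubled ranks are integers
    total <- sum(s)
    p <- numeric(total + 1L); p[1L] <- 1
    for (si in s)
      p <- (p + c(numeric(si), p[seq_len(total + 1L - si)])) / 2
    w2 <- as.integer(round(2 * W))
    pG <- sum(p[(w2 + 1L):(total + 1L)])
    pL <- sum(p[seq_len(w2 + 1L)])
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tiec <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                    sum(tiec^3 - tiec) / 48)
    pG <- stats::pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
    pL <- stats::pnorm((W - mu + 0.5) / sigma)
    method <- "normal"
  }
  list(statistic = W, n = n, p.greater = pG, p.less = pL,
       p.value = min(1, 2 * min(pG, pL)), method = method)
}

#' Case-by-case rank comparison of two network variants
#'
#' Counts in how many trials variant A ranked the causal gene better
#' (lower), tied, or worse than variant B, and tests the paired rank
#' difference with the Wilcoxon signed-rank test ([wilcoxonSignedRank()]).
#' Ties are reported separately (and dropped by the test, the classic
#' procedure), so no information is lost.
#'
#' @param ranksA,ranksB integer rank vectors over the same case set, or a
#'   `loocvResult` plus two variant names.
#' @param variantA,variantB variant names when the first argument is a
#'   `loocvResult`.
#' @return List with `better`, `tie`, `worse` (A-centric counts),
#'   `p.value` (two-sided), `p.better` (one-sided, A better) and `test`.
#' @export
compareRankings <- function(ranksA, ranksB = NULL, variantA = NULL,
                            variantB = NULL) {
  if (inherits(ranksA, "loocvResult")) {
    stopifnot(!is.null(variantA), !is.null(variantB))
    ranksB <- ranksA$ranks[, variantB]
    ranksA <- ranksA$ranks[, variantA]
  }
  stopifnot(length(ranksA) == length(ranksB))
  better <- sum(ranksA < ranksB)
  worse <- sum(ranksA > ranksB)
  tie <- length(ranksA) - better - worse
  test <- wilcoxonSignedRank(ranksB, ranksA)   # positive diffs: A better
  list(better = better, tie = tie, worse = worse,
       p.value = test$p.value, p.better = test$p.greater, test = test)
}

#' AUC spread under repeated k-fold cross-validation
#'
#' Replaces leave-one-out with k-fold cross-validation over
#' `nPartitions` independent random (unstratified) partitions of the
#' association set. Within a fold, the fold's associations and every
#' association involving a fold gene are removed from the prior; each
#' partition's cases are pooled into a single AUC, and the standard
#' deviation over partitions is the error bar.
#'
#' @inheritParams runLOOCV
#' @param variant a single [networkVariant()] description.
#' @param k number of folds; default 25.
#' @param nPartitions number of random partitions; default 10.
#' @param seed RNG seed (required).
#' @return List with `meanAUC`, `sdAUC`, `aucs` (one per partition).
#' @export
kfoldAucSpread <- function(assocs, assign, catalog, genericNet, profiles,
                           sim, cfg = PropagationConfig(),
                           variant = networkVariant("generic"), k = 25L,
                           nPartitions = 10L, seed, intervalSize = 100L,
                           expressedOnly = TRUE, masThreshold = NULL) {
  tab <- assocWithAssignment(assocs, assign, profiles, masThreshold)
  if (expressedOnly) tab <- tab[tab$expressed, , drop = FALSE]
  n <- nrow(tab)
  if (k > n) stop(sprintf("k = %d exceeds the %d evaluation cases", k, n))
  if (nPartitions == 1L)
    warning("a single partition yields a degenerate (zero) sd")
  calls <- presenceCalls(profiles)
  getOp <- makeOperatorCache(genericNet, profiles)
  full <- associations(assocs)
  candidates <- lapply(seq_len(n), function(i)
    c(buildInterval(tab$gene[i], catalog, genericNet, intervalSize),
      tab$gene[i]))
  aucs <- withSeed(seed, vapply(seq_len(nPartitions), function(p) {
    fold <- sample(rep_len(seq_len(k), n))
    scores <- vector("list", n)
    for (f in seq_len(k)) {
      idx <- which(fold == f)
      heldGenes <- tab$gene[idx]
      exclude <- rbind(tab[idx, c("gene", "disease")],
                       full[full$gene %in% heldGenes, , drop = FALSE])
      for (i in idx)
        scores[[i]] <- scoreCase(tab$gene[i], tab$disease[i], tab$tissue[i],
                                 candidates[[i]], exclude, variant, getOp,
                                 sim, assocs, cfg, calls)
    }
    pool <- unlist(scores, use.names = FALSE)
    labels <- unlist(lapply(seq_len(n), function(i)
      candidates[[i]] == tab$gene[i]), use.names = FALSE)
    pooledROC(pool, labels = labels)$auc
  }, numeric(1)))
  list(meanAUC = mean(aucs), sdAUC = stats::sd(aucs), aucs = aucs)
}

#' Sweep the edge-reweight penalty and locate its optimum
#'
#' Evaluates the pooled LOOCV AUC of TS-ERW networks over a constant grid
#' of `rw` in \[0,1\], then extends the sweep downward from the smallest
#' positive grid value by successive orders of magnitude, stopping once
#' performance declines and converges to the AUC at rw = 0 (within
#' `convergeTol`). Returns the full table and the argmax.
#'
#' @inheritParams runLOOCV
#' @param gridStep grid spacing in \[0,1\]; default 0.1.
#' @param convergeTol AUC convergence tolerance for the downward extension;
#'   default 0.005.
#' @param minRw hard floor for the downward extension; default 1e-6.
#' @return List with `table` (data.frame `rw`, `auc`) and `rwStar`.
#' @export
rwSweep <- function(assocs, assign, catalog, genericNet, profiles, sim,
                    cfg = PropagationConfig(), gridStep = 0.1,
                    convergeTol = 0.005, minRw = 1e-6, intervalSize = 100L,
                    expressedOnly = TRUE, masThreshold = NULL) {
  aucAt <- function(rw) {
    res <- runLOOCV(assocs, assign, catalog, genericNet, profiles, sim, cfg,
                    variants = list(erw = networkVariant("erw", rw = rw)),
                    intervalSize = intervalSize,
                    expressedOnly = expressedOnly,
                    masThreshold = masThreshold)
    pooledROC(res, "erw")$auc
  }
  grid <- seq(0, 1, by = gridStep)
  aucs <- vapply(grid, aucAt, numeric(1))
  auc0 <- aucs[grid == 0]
  rw <- min(grid[grid > 0])
  prevAuc <- aucs[match(rw, grid)]
  repeat {
    rw <- rw / 10
    if (rw < minRw) break
    a <- aucAt(rw)
    grid <- c(grid, rw); aucs <- c(aucs, a)
    if (a <= prevAuc && abs(a - auc0) <= convergeTol) break
    prevAuc <- a
  }
  o <- order(grid)
  tab <- data.frame(rw = grid[o], auc = aucs[o])
  list(table = tab, rwStar = tab$rw[which.max(tab$auc)])
}
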