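#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `expr`, and restores the previous RNG
#' state, so seeded package functions never disturb the caller's stream.
#' @noRd
withSeed <- function(seed, expr) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  expr
}

#' Empirical p-value with the add-one convention
#'
#' p = (1 + k) / (N + 1) where k counts null statistics at least as extreme
#' as the observation. Zero exceedances out of N therefore report
#' 1 / (N + 1), the "p < 1/(N+1)" bound.
#'
#' @param null numeric vector of null statistics.
#' @param observed observed statistic.
#' @param alternative "greater", "less" or "two.sided" (twice the smaller
#'   one-sided p, capped at 1).
#' @return The empirical p-value.
#' @export
empiricalP <- function(null, observed,
                       alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- length(null)
  pg <- (1 + sum(null >= observed)) / (n + 1)
  pl <- (1 + sum(null <= observed)) / (n + 1)
  switch(alternative, greater = pg, less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}

#' Collapse a probe-level matrix to gene-by-tissue expression
#'
#' Replicate samples of the same tissue are arithmetic-averaged first; then,
#' for each gene, the single probe with the maximal across-tissue mean
#' expression is selected globally, giving the gene one probe in every
#' tissue (this preserves cross-tissue comparability of the gene's values).
#'
#' @param probeMatrix numeric probes x samples matrix of AD units with probe
#'   row names and sample column names.
#' @param probeToGene named character vector mapping probe name to gene id;
#'   probes absent from the map are ignored (each probe maps to at most one
#'   gene).
#' @param sampleToTissue named character vector mapping sample name to
#'   tissue name.
#' @param catalog optional [GeneCatalog-class]; if supplied, the result is
#'   an [ExpressionMatrix-class] over the full catalog, with genes lacking
#'   any probe reported in a message and set to 0 AD.
#' @return A genes x tissues numeric matrix (gene ids as row names), or an
#'   [ExpressionMatrix-class] when `catalog` is given.
#' @export
collapseProbes <- function(probeMatrix, probeToGene, sampleToTissue,
                           catalog = NULL) {
  stopifnot(is.matrix(probeMatrix), !is.null(rownames(probeMatrix)),
            !is.null(colnames(probeMatrix)))
  miss <- setdiff(colnames(probeMatrix), names(sampleToTissue))
  if (length(miss))
    stop(sprintf("sample '%s' has no tissue mapping", miss[1L]))
  tissues <- sampleToTissue[colnames(probeMatrix)]
  tlev <- unique(unname(tissues))
  # average replicate samples per tissue
  byTissue <- matrix(0, nrow(probeMatrix), length(tlev),
                     dimnames = list(rownames(probeMatrix), tlev))
  for (t in tlev)
    byTissue[, t] <- rowMeans(probeMatrix[, tissues == t, drop = FALSE])
  probes <- intersect(rownames(probeMatrix), names(probeToGene))
  byTissue <- byTissue[probes, , drop = FALSE]
  genes <- unname(probeToGene[probes])
  # global probe choice: the probe maximizing its across-tissue mean
  probeMean <- rowMeans(byTissue)
  keep <- vapply(split(seq_along(probes), genes),
                 function(ix) ix[which.max(probeMean[ix])], integer(1))
  m <- byTissue[keep, , drop = FALSE]
  rownames(m) <- names(keep)
  if (is.null(catalog)) return(m)
  noProbe <- setdiff(geneIds(catalog), rownames(m))
  if (length(noProbe))
    message(sprintf("%d catalog gene(s) have no probe (e.g. '%s'); set to 0",
                    length(noProbe), noProbe[1L]))
  full <- matrix(0, numGenes(catalog), ncol(m),
                 dimnames = list(NULL, colnames(m)))
  hit <- match(rownames(m), geneIds(catalog))
  if (anyNA(hit))
    stop(sprintf("probe maps to unknown gene '%s'",
                 rownames(m)[which(is.na(hit))[1L]]))
  full[hit, ] <- m
  ExpressionMatrix(full)
}

#' Binarize an expression matrix into presence calls
#'
#' A gene is called expressed in a tissue iff its AD value is at least
#' `tau` ("at least" is inclusive: AD = tau is expressed). The pipeline
#' default tau = 200 AD units is the published presence threshold.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param tau positive AD threshold; default 200.
#' @return A [BinaryExpressionProfiles-class].
#' @examples
#' e <- ExpressionMatrix(matrix(c(199.99, 200), 1,
#'                              dimnames = list(NULL, c("liver", "brain"))))
#' presenceCalls(binarize(e))    # FALSE, TRUE
#' @export
binarize <- function(expr, tau = 200) {
  stopifnot(is(expr, "ExpressionMatrix"), length(tau) == 1L, tau > 0)
  new("BinaryExpressionProfiles", calls = exprValues(expr) >= tau,
      tau = as.numeric(tau))
}

#' Expression breadth: number of tissues a gene is expressed in
#'
#' @param profiles a [BinaryExpressionProfiles-class].
#' @param gene optional vector of catalog gene indices; default all genes.
#' @return Integer vector of tissue counts.
#' @export
expressionBreadth <- function(profiles, gene = NULL) {
  stopifnot(is(profiles, "BinaryExpressionProfiles"))
  calls <- presenceCalls(profiles)
  if (is.null(gene)) gene <- seq_len(nrow(calls))
  if (any(gene < 1L | gene > nrow(calls)))
    stop("unknown gene index in expressionBreadth()")
  as.integer(rowSums(calls[gene, , drop = FALSE]))
}

#' Assign each disease its maximal-association-score tissue
#'
#' The assigned tissue is the argmax of the disease's MAS row (first
#' maximum on exact ties); diseases whose MAS does not exceed `masThreshold`
#' are flagged excluded, not dropped.
#'
#' @param dtm a [DiseaseTissueMatrix-class].
#' @param masThreshold MAS threshold in percent; retained diseases satisfy
#'   MAS > threshold. Default 0.
#' @return A [TissueAssignment-class].
#' @export
assignTissues <- function(dtm, masThreshold = 0) {
  v <- masValues(dtm)
  best <- max.col(v, ties.method = "first")
  mas <- v[cbind(seq_len(nrow(v)), best)]
  new("TissueAssignment", disease = rownames(v),
      tissue = colnames(v)[best], mas = as.numeric(mas),
      excluded = mas <= masThreshold, threshold = as.numeric(masThreshold))
}

# internal: retained association table with assigned tissue and presence call
assocWithAssignment <- function(assocs, assign, profiles,
                                masThreshold = NULL) {
  tab <- associations(assocs)
  i <- match(tab$disease, assign@disease)
  if (anyNA(i))
    stop(sprintf("disease '%s' has no tissue assignment",
                 tab$disease[which(is.na(i))[1L]]))
  excl <- if (is.null(masThreshold)) assign@excluded[i]
          else assign@mas[i] <= masThreshold
  tab$tissue <- assign@tissue[i]
  tab <- tab[!excl, , drop = FALSE]
  calls <- presenceCalls(profiles)
  tab$expressed <- calls[cbind(tab$gene, match(tab$tissue, colnames(calls)))]
  tab
}

#' Fraction of disease genes expressed in their disease's assigned tissue
#'
#' For every retained gene-disease association (disease MAS above
#' threshold), checks whether the causal gene is expressed in the tissue
#' assigned to the disease, and returns the fraction together with the
#' surviving pairs (the "expressed disease genes association set").
#'
#' @param assocs a [GeneDiseaseAssociations-class].
#' @param assign a [TissueAssignment-class].
#' @param profiles a [BinaryExpressionProfiles-class].
#' @param masThreshold optional MAS threshold in percent overriding the one
#'   stored in `assign`.
#' @return List with elements `fraction` (in \[0,1\]), `nRetained`,
#'   `expressedSet` (data.frame of surviving gene/disease pairs) and
#'   `table` (all retained pairs with their presence call).
#' @export
expressedFraction <- function(assocs, assign, profiles, masThreshold = NULL) {
  tab <- assocWithAssignment(assocs, assign, profiles, masThreshold)
  if (!nrow(tab))
    stop("no associations retained at this MAS threshold")
  list(fraction = mean(tab$expressed), nRetained = nrow(tab),
       expressedSet = tab[tab$expressed, c("gene", "disease")],
       table = tab)
}

#' Permutation null for the expressed fraction
#'
#' Permutes the tissue-assignment vector (one tissue per retained disease)
#' across diseases, preserving the bias of tissues associated with many
#' diseases, and recomputes the expressed fraction per permutation. The
#' observed fraction is tested against the upper tail with the add-one
#' convention, so zero exceedances of `nPerm` report p = 1/(nPerm+1).
#'
#' @inheritParams expressedFraction
#' @param nPerm number of permutations; default 10000.
#' @param seed RNG seed (required).
#' @return List with `p`, `observed`, `null` (vector of length `nPerm`) and
#'   `nRetained`.
#' @export
permuteAssignmentNull <- function(assocs, assign, profiles, nPerm = 10000,
                                  seed, masThreshold = NULL) {
  tab <- assocWithAssignment(assocs, assign, profiles, masThreshold)
  if (!nrow(tab)) stop("no associations retained at this MAS threshold")
  dis <- unique(tab$disease)
  tis <- tab$tissue[match(dis, tab$disease)]
  if (length(unique(tis)) < 2L)
    warning("degenerate assignment vector: fewer than 2 distinct tissues")
  calls <- presenceCalls(profiles)
  tcol <- match(colnames(calls), colnames(calls))  # identity, for clarity
  di <- match(tab$disease, dis)
  observed <- mean(tab$expressed)
  null <- withSeed(seed, vapply(seq_len(nPerm), function(i) {
    pt <- tis[sample.int(length(tis))]
    mean(calls[cbind(tab$gene, match(pt[di], colnames(calls)))])
  }, numeric(1)))
  list(p = empiricalP(null, observed, "greater"), observed = observed,
       null = null, nRetained = nrow(tab))
}

#' Matched-random tests for lowly expressed disease genes
#'
#' For a set of disease genes lowly expressed in their assigned tissues,
#' builds `nSets` random gene sets matched in size and per-member tissue
#' constraint: each member is replaced by another gene that is also lowly
#' expressed (AD below the calling threshold) in the same tissue, sampled
#' without replacement within one set and with replacement across sets.
#' Two-sided empirical p-values compare the original set's mean expression
#' breadth and mean across-tissue AD level with the matched null.
#'
#' @param genes integer vector of catalog gene indices (the original set).
#' @param tissues character vector, the assigned tissue per member (parallel
#'   to `genes`).
#' @param profiles a [BinaryExpressionProfiles-class].
#' @param expr the [ExpressionMatrix-class] the profiles were derived from.
#' @param nSets number of random sets; default 10000.
#' @param seed RNG seed (required).
#' @return List with `pBreadth`, `pLevel`, observed and null statistics.
#' @export
matchedRandomTests <- function(genes, tissues, profiles, expr, nSets = 10000,
                               seed) {
  stopifnot(length(genes) == length(tissues), length(genes) >= 1L)
  calls <- presenceCalls(profiles)
  ad <- exprValues(expr)
  ti <- match(tissues, colnames(calls))
  if (anyNA(ti))
    stop(sprintf("unknown tissue '%s'", tissues[which(is.na(ti))[1L]]))
  if (any(calls[cbind(genes, ti)]))
    stop("every member must be lowly expressed in its tissue")
  eligible <- lapply(seq_along(genes), function(k) {
    e <- setdiff(which(!calls[, ti[k]]), genes[k])
    if (!length(e))
      stop(sprintf("no other lowly-expressed gene in tissue '%s'",
                   tissues[k]))
    e
  })
  breadth <- as.integer(rowSums(calls))
  level <- rowMeans(ad)
  obsBreadth <- mean(breadth[genes])
  obsLevel <- mean(level[genes])
  drawSet <- function() {
    chosen <- integer(length(genes))
    for (k in order(lengths(eligible))) {   # tightest constraints first
      pool <- setdiff(eligible[[k]], chosen)
      if (!length(pool))
        stop(sprintf("matched sampling exhausted in tissue '%s'",
                     tissues[k]))
      chosen[k] <- pool[sample.int(length(pool), 1L)]
    }
    chosen
  }
  stats <- withSeed(seed, vapply(seq_len(nSets), function(i) {
    s <- drawSet()
    c(mean(breadth[s]), mean(level[s]))
  }, numeric(2)))
  list(pBreadth = empiricalP(stats[1L, ], obsBreadth, "two.sided"),
       pLevel = empiricalP(stats[2L, ], obsLevel, "two.sided"),
       observedBreadth = obsBreadth, observedLevel = obsLevel,
       nullBreadth = stats[1L, ], nullLevel = stats[2L, ])
}
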