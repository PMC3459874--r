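#' Logistic prior transform
#'
#' L(x) = 1 / (1 + exp(c*x + b)). With the default c = -15 and
#' b = log(9999), L(0) = 1e-4 and L(1) ~ 0.997: dissimilar diseases
#' contribute essentially nothing while near-identical phenotypes give a
#' prior close to 1.
#'
#' @param x phenotypic similarity in \[0,1\].
#' @param cfg a [PropagationConfig-class] supplying `c` and `b`.
#' @return Numeric vector of prior scores in (0,1).
#' @export
logisticPrior <- function(x, cfg = PropagationConfig()) {
  1 / (1 + exp(cfg@c * x + cfg@b))
}

#' Build the prior score vector for a query disease
#'
#' For each gene with at least one usable disease association, the prior is
#' L(sim(q, d*)) where d* is the gene's associated disease most similar to
#' the query q; genes with no usable association get exactly 0. Usable
#' excludes the pairs listed in `exclude` (the held-out association and, in
#' cross-validation, every association of the held-out gene) and, unless
#' `cfg@useSelfSimilarity` is set, the query disease itself.
#'
#' @param query disease id (must be present in `sim`).
#' @param sim a [DiseaseSimilarity-class].
#' @param assocs a [GeneDiseaseAssociations-class].
#' @param cfg a [PropagationConfig-class].
#' @param exclude optional data.frame with columns `gene`, `disease`: the
#'   associations to ignore.
#' @param nGenes length of the output vector (catalog size).
#' @return Numeric prior vector Y of length `nGenes` in \[0,1\].
#' @export
buildPrior <- function(query, sim, assocs, cfg = PropagationConfig(),
                       exclude = NULL, nGenes) {
  sv <- simValues(sim)
  if (!query %in% rownames(sv))
    stop(sprintf("unknown disease '%s'", query))
  tab <- associations(assocs)
  if (!is.null(exclude) && nrow(exclude))
    tab <- tab[!paste(tab$gene, tab$disease) %in%
                 paste(exclude$gene, exclude$disease), , drop = FALSE]
  if (!cfg@useSelfSimilarity)
    tab <- tab[tab$disease != query, , drop = FALSE]
  bad <- setdiff(tab$disease, rownames(sv))
  if (length(bad))
    stop(sprintf("unknown disease '%s' in associations", bad[1L]))
  y <- numeric(nGenes)
  if (nrow(tab)) {
    s <- sv[query, tab$disease]
    best <- vapply(split(s, tab$gene), max, numeric(1))
    y[as.integer(names(best))] <- logisticPrior(best, cfg)
  }
  y
}

#' Symmetric degree normalization of a weighted network
#'
#' Returns the operator W'(u,v) = w(u,v) / sqrt(d(u) d(v)) with
#' d(x) = sum_y w(x,y) the weighted degree, as a sparse symmetric matrix
#' over the full catalog index space. Weighted degree (not edge count) is
#' used so that edge-reweighted networks, whose weights carry the tissue
#' signal, are normalized consistently. Zero-weight edges are dropped and
#' zero-degree nodes contribute no entries; the operator's spectral radius
#' is at most 1.
#'
#' @param net a [WeightedNetwork-class] with at least one node.
#' @param label network label stored on the result.
#' @return A [NormalizedNetwork-class].
#' @export
normalizeNetwork <- function(net, label = "network") {
  stopifnot(is(net, "WeightedNetwork"))
  if (!length(nodes(net))) stop("network has no nodes")
  G <- max(net@nGenes, 1L)
  pos <- net@weight > 0
  f <- net@from[pos]; t <- net@to[pos]; w <- net@weight[pos]
  d <- numeric(G)
  agg <- rowsum(c(w, w), c(f, t))
  d[as.integer(rownames(agg))] <- agg[, 1L]
  wn <- w / sqrt(d[f] * d[t])
  mat <- Matrix::sparseMatrix(i = c(f, t), j = c(t, f), x = c(wn, wn),
                              dims = c(G, G))
  new("NormalizedNetwork", mat = mat, nodes = nodes(net), label = label)
}

#' Iterative network propagation of a prior (PRINCE)
#'
#' Computes F via the smoothing recurrence F^0 = Y,
#' F^{t+1}(v) = alpha * sum_u W'(u,v) F^t(u) + (1 - alpha) * Y(v), run for
#' `cfg@iterations` steps (default 10, the published setting). The prior is
#' restricted to network nodes first, so genes absent from the network
#' score exactly 0.
#'
#' @param wn a [NormalizedNetwork-class] from [normalizeNetwork()].
#' @param y numeric prior vector (length = catalog size).
#' @param cfg a [PropagationConfig-class].
#' @param query disease id recorded on the result.
#' @return A [PropagationResult-class].
#' @export
propagate <- function(wn, y, cfg = PropagationConfig(), query = "") {
  stopifnot(is(wn, "NormalizedNetwork"), nrow(wn@mat) == length(y))
  if (!all(is.finite(y))) stop("prior contains non-finite values")
  y0 <- numeric(length(y))
  y0[wn@nodes] <- y[wn@nodes]
  f <- y0
  a <- cfg@alpha
  for (i in seq_len(cfg@iterations))
    f <- a * as.numeric(wn@mat %*% f) + (1 - a) * y0
  f[-wn@nodes] <- 0
  new("PropagationResult", disease = query, label = wn@label, scores = f)
}

#' Exact fixed point of the propagation recurrence
#'
#' Solves F* = (1 - alpha) (I - alpha W')^{-1} Y by a dense linear solve,
#' restricted to the network's nodes (genes outside score exactly 0). This
#' is the test oracle for [propagate()]: the iterates converge to F*
#' geometrically at rate alpha. Guarded to networks of at most `maxNodes`
#' nodes.
#'
#' @inheritParams propagate
#' @param maxNodes dense-solve guard; default 2000.
#' @return A [PropagationResult-class] whose residual
#'   `||F* - alpha W' F* - (1-alpha) Y||_inf` is at most ~1e-10.
#' @export
closedFormScores <- function(wn, y, cfg = PropagationConfig(), query = "",
                             maxNodes = 2000L) {
  stopifnot(is(wn, "NormalizedNetwork"), nrow(wn@mat) == length(y))
  nd <- wn@nodes
  if (length(nd) > maxNodes)
    stop(sprintf("dense closed form guarded to <= %d nodes", maxNodes))
  a <- cfg@alpha
  W <- as.matrix(wn@mat[nd, nd, drop = FALSE])
  ysub <- y[nd]
  fsub <- solve(diag(length(nd)) - a * W, (1 - a) * ysub)
  f <- numeric(length(y))
  f[nd] <- fsub
  res <- max(abs(fsub - a * as.numeric(W %*% fsub) - (1 - a) * ysub))
  if (res > 1e-8)
    warning(sprintf("closed-form residual %.3g unexpectedly large", res))
  new("PropagationResult", disease = query,
      label = paste0(wn@label, ":closed-form"), scores = f)
}

#' Score all genes for one query disease on one network
#'
#' Convenience wrapper: prior construction followed by propagation.
#'
#' @inheritParams buildPrior
#' @param wn a [NormalizedNetwork-class].
#' @return A [PropagationResult-class].
#' @export
princeScores <- function(query, wn, sim, assocs, cfg = PropagationConfig(),
                         exclude = NULL) {
  y <- buildPrior(query, sim, assocs, cfg, exclude, nGenes = nrow(wn@mat))
  propagate(wn, y, cfg, query = query)
}
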