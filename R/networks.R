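#' Tissue-specific network by node removal (NR)
#'
#' Removes from the network every protein not expressed in the tissue,
#' together with all edges adjacent to it; surviving edges keep their
#' original confidence weights.
#'
#' @param net a [WeightedNetwork-class] (the generic network).
#' @param expressed integer vector of catalog gene indices expressed in the
#'   tissue.
#' @return A [WeightedNetwork-class] over `nodes(net)` intersected with
#'   `expressed`.
#' @export
nodeRemoval <- function(net, expressed) {
  stopifnot(is(net, "WeightedNetwork"))
  expressed <- as.integer(expressed)
  keepNodes <- intersect(nodes(net), expressed)
  keep <- net@from %in% keepNodes & net@to %in% keepNodes
  new("WeightedNetwork", nGenes = net@nGenes, nodes = sort(keepNodes),
      from = net@from[keep], to = net@to[keep], weight = net@weight[keep])
}

#' Tissue-specific network by edge reweighting (ERW)
#'
#' Keeps the topology of the generic network and multiplies each edge's
#' confidence by `rw` once per endpoint not expressed in the tissue:
#' w'(i,j) = w(i,j) * rw^n with n in {0,1,2}. `rw` is interpreted as the
#' probability that a gene below the expression threshold is nonetheless
#' expressed. At rw = 1 the network is unchanged; at rw = 0 edges touching
#' an unexpressed gene get weight exactly 0 but are retained structurally,
#' so node sets and score-vector dimensions stay fixed across an rw sweep
#' (propagation treats weight-0 edges as absent).
#'
#' @param net a [WeightedNetwork-class].
#' @param expressed integer vector of expressed gene indices.
#' @param rw penalty factor in \[0,1\].
#' @return A [WeightedNetwork-class] with identical topology and reweighted
#'   confidences.
#' @export
edgeReweight <- function(net, expressed, rw) {
  stopifnot(is(net, "WeightedNetwork"), length(rw) == 1L)
  if (is.na(rw) || rw < 0 || rw > 1) stop("rw must lie in [0, 1]")
  expressed <- as.integer(expressed)
  n <- (!(net@from %in% expressed)) + (!(net@to %in% expressed))
  new("WeightedNetwork", nGenes = net@nGenes, nodes = net@nodes,
      from = net@from, to = net@to, weight = net@weight * rw^n)
}

#' Topological statistics of a (tissue) network
#'
#' Connected components are computed over edges with weight strictly
#' greater than 0; a node whose incident edges all have weight 0 counts as
#' its own singleton component. Mean edges per expressed protein divides
#' the positive-weight edge count by the number of network nodes that are
#' expressed.
#'
#' @param net a [WeightedNetwork-class].
#' @param expressed integer vector of expressed gene indices; defaults to
#'   all network nodes.
#' @return List with `nodeCount`, `edgeCount` (positive-weight edges),
#'   `nComponents`, `giantSize`, `componentSizes`,
#'   `meanEdgesPerExpressed`.
#' @export
networkStats <- function(net, expressed = nodes(net)) {
  stopifnot(is(net, "WeightedNetwork"))
  pos <- net@weight > 0
  nn <- length(nodes(net))
  g <- igraph::graph_from_data_frame(
    data.frame(from = net@from[pos], to = net@to[pos]),
    directed = FALSE, vertices = data.frame(name = nodes(net)))
  comp <- igraph::components(g)
  sizes <- as.integer(comp$csize)
  nExpr <- length(intersect(nodes(net), as.integer(expressed)))
  list(nodeCount = nn, edgeCount = sum(pos),
       nComponents = length(sizes),
       giantSize = if (length(sizes)) max(sizes) else 0L,
       componentSizes = sort(sizes, decreasing = TRUE),
       meanEdgesPerExpressed = if (nExpr) sum(pos) / nExpr else NA_real_)
}

#' Per-tissue network statistics with Pearson correlations
#'
#' Tabulates [networkStats()] across tissue networks and reports the
#' Pearson correlation between the expressed-protein count and (a) the
#' edge count and (b) the mean edges per expressed protein. A
#' zero-variance column makes the corresponding correlation undefined
#' (reported as NA).
#'
#' @param networks named list of [WeightedNetwork-class], one per tissue.
#' @param expressedSets named list of expressed gene-index vectors, aligned
#'   with `networks`.
#' @return List with `table` (one row per tissue) and `correlations`
#'   (named numeric: `expressedVsEdges`, `expressedVsMeanEdges`).
#' @export
statsReport <- function(networks, expressedSets) {
  stopifnot(length(networks) >= 3L,
            identical(names(networks), names(expressedSets)))
  rows <- lapply(names(networks), function(t) {
    s <- networkStats(networks[[t]], expressedSets[[t]])
    data.frame(tissue = t,
               nExpressed = length(intersect(nodes(networks[[t]]),
                                             as.integer(expressedSets[[t]]))),
               nodeCount = s$nodeCount, edgeCount = s$edgeCount,
               nComponents = s$nComponents, giantSize = s$giantSize,
               meanEdgesPerExpressed = s$meanEdgesPerExpressed)
  })
  tab <- do.call(rbind, rows)
  safeCor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  list(table = tab,
       correlations = c(
         expressedVsEdges = safeCor(tab$nExpressed, tab$edgeCount),
         expressedVsMeanEdges = safeCor(tab$nExpressed,
                                        tab$meanEdgesPerExpressed)))
}

#' Build tissue-specific networks for every tissue
#'
#' Convenience wrapper applying [nodeRemoval()] or [edgeReweight()] per
#' tissue of a set of binary profiles.
#'
#' @param net the generic [WeightedNetwork-class].
#' @param profiles a [BinaryExpressionProfiles-class].
#' @param method "nr" or "erw".
#' @param rw penalty factor for "erw"; ignored for "nr".
#' @return Named list of [WeightedNetwork-class], one per tissue.
#' @export
buildTissueNetworks <- function(net, profiles, method = c("nr", "erw"),
                                rw = 0.1) {
  method <- match.arg(method)
  calls <- presenceCalls(profiles)
  out <- lapply(colnames(calls), function(t) {
    expressed <- which(calls[, t])
    if (method == "nr") nodeRemoval(net, expressed)
    else edgeReweight(net, expressed, rw)
  })
  names(out) <- colnames(calls)
  out
}
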