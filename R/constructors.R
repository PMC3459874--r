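#' Construct a gene catalog
#'
#' @param geneIds character vector of external gene ids, in catalog index
#'   order (index 1..G).
#' @param chrom chromosome label per gene.
#' @param pos ordinal genomic position per gene within its chromosome.
#' @return A [GeneCatalog-class] object.
#' @examples
#' GeneCatalog(c("g1", "g2", "g3"), chrom = c("1", "1", "2"), pos = c(1, 2, 1))
#' @export
GeneCatalog <- function(geneIds, chrom, pos) {
  new("GeneCatalog", geneIds = as.character(geneIds),
      chrom = as.character(chrom), pos = as.integer(pos))
}

#' Construct a weighted undirected network
#'
#' Edges are canonicalized to `from < to`. By default the node set is the
#' union of edge endpoints; pass `nodes` to include isolated nodes.
#'
#' @param from,to integer vectors of catalog gene indices (one edge per
#'   entry; order within a pair is irrelevant).
#' @param weight numeric vector of confidences in (0,1] (ERW-derived
#'   networks may carry exact zeros).
#' @param nGenes catalog size; defaults to the largest index seen.
#' @param nodes optional integer vector of node indices (must cover all
#'   endpoints).
#' @return A [WeightedNetwork-class] object.
#' @examples
#' WeightedNetwork(from = c(1, 2), to = c(2, 3), weight = c(0.9, 0.4))
#' @export
WeightedNetwork <- function(from, to, weight, nGenes = NULL, nodes = NULL) {
  from <- as.integer(from); to <- as.integer(to); weight <- as.numeric(weight)
  if (any(from == to))
    stop(sprintf("self-loop at gene %d", from[which(from == to)[1L]]))
  lo <- pmin(from, to); hi <- pmax(from, to)
  o <- order(lo, hi)
  lo <- lo[o]; hi <- hi[o]; weight <- weight[o]
  if (is.null(nodes)) nodes <- sort(unique(c(lo, hi)))
  else nodes <- sort(unique(as.integer(nodes)))
  if (is.null(nGenes)) nGenes <- if (length(nodes)) max(nodes) else 0L
  new("WeightedNetwork", nGenes = as.integer(nGenes), nodes = nodes,
      from = lo, to = hi, weight = weight)
}

#' Construct an expression matrix
#'
#' Negative entries (microarray artifacts) are floored to 0 with a warning;
#' the stored matrix is non-negative.
#'
#' @param values numeric genes x tissues matrix of AD units with tissue
#'   column names.
#' @return An [ExpressionMatrix-class] object.
#' @export
ExpressionMatrix <- function(values) {
  values <- as.matrix(values)
  if (any(values < 0)) {
    warning(sprintf("flooring %d negative AD entries to 0", sum(values < 0)))
    values[values < 0] <- 0
  }
  new("ExpressionMatrix", values = values)
}

#' Construct a gene-disease association set
#'
#' @param gene integer vector of catalog gene indices.
#' @param disease character vector of disease ids.
#' @return A [GeneDiseaseAssociations-class] object.
#' @export
GeneDiseaseAssociations <- function(gene, disease) {
  new("GeneDiseaseAssociations", gene = as.integer(gene),
      disease = as.character(disease))
}

#' Construct a disease similarity matrix
#'
#' @param values symmetric numeric matrix in \[0,1\] with disease dimnames.
#' @return A [DiseaseSimilarity-class] object.
#' @export
DiseaseSimilarity <- function(values) {
  new("DiseaseSimilarity", values = as.matrix(values))
}

#' Construct a disease-by-tissue MAS matrix
#'
#' @param values numeric diseases x tissues matrix in percent; rows must sum
#'   to 100 (tolerance 1e-6).
#' @return A [DiseaseTissueMatrix-class] object.
#' @export
DiseaseTissueMatrix <- function(values) {
  new("DiseaseTissueMatrix", values = as.matrix(values))
}

#' Construct a propagation configuration
#'
#' @param alpha network-vs-prior weight in (0,1); default 0.9.
#' @param iterations number of propagation iterations; default 10.
#' @param c logistic slope for the prior transform; default -15.
#' @param b logistic offset; default log(9999) so L(0) = 1e-4.
#' @param useSelfSimilarity if TRUE, sim(q,q) may serve as prior evidence
#'   for genes associated with the query disease itself; default FALSE.
#' @return A [PropagationConfig-class] object.
#' @examples
#' cfg <- PropagationConfig()           # the published parameterization
#' PropagationConfig(alpha = 0.5, iterations = 50)
#' @export
PropagationConfig <- function(alpha = 0.9, iterations = 10L, c = -15,
                              b = log(9999), useSelfSimilarity = FALSE) {
  new("PropagationConfig", alpha = as.numeric(alpha),
      iterations = as.integer(iterations), c = as.numeric(c),
      b = as.numeric(b), useSelfSimilarity = isTRUE(useSelfSimilarity))
}
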