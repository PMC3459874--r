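#' Accessors for tsprince classes
#'
#' Small accessor generics in the Bioconductor style; prefer these over
#' direct slot access.
#'
#' @param x an object of one of the tsprince classes.
#' @return `numGenes`, `numEdges`: integer scalars. `geneIds`,
#'   `tissueNames`, `diseaseIds`: character vectors. `nodes`: integer
#'   vector of node indices. `edges`, `associations`, `assignmentTable`:
#'   data.frames. `exprValues`, `simValues`, `masValues`: numeric matrices.
#'   `presenceCalls`: logical matrix. `adThreshold`: numeric scalar.
#'   `geneScores`: numeric vector.
#' @name accessors
NULL

#' @rdname accessors
setMethod("numGenes", "GeneCatalog", function(x) length(x@geneIds))
#' @rdname accessors
setMethod("numGenes", "WeightedNetwork", function(x) x@nGenes)
#' @rdname accessors
setMethod("geneIds", "GeneCatalog", function(x) x@geneIds)
#' @rdname accessors
setMethod("nodes", "WeightedNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("nodes", "NormalizedNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("edges", "WeightedNetwork", function(x)
  data.frame(from = x@from, to = x@to, weight = x@weight))
#' @rdname accessors
setMethod("numEdges", "WeightedNetwork", function(x) length(x@from))
#' @rdname accessors
setMethod("tissueNames", "ExpressionMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("tissueNames", "BinaryExpressionProfiles",
          function(x) colnames(x@calls))
#' @rdname accessors
setMethod("tissueNames", "DiseaseTissueMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)
#' @rdname accessors
setMethod("presenceCalls", "BinaryExpressionProfiles", function(x) x@calls)
#' @rdname accessors
setMethod("adThreshold", "BinaryExpressionProfiles", function(x) x@tau)
#' @rdname accessors
setMethod("associations", "GeneDiseaseAssociations", function(x)
  data.frame(gene = x@gene, disease = x@disease))
#' @rdname accessors
setMethod("diseaseIds", "DiseaseSimilarity", function(x) rownames(x@values))
#' @rdname accessors
setMethod("diseaseIds", "DiseaseTissueMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("diseaseIds", "GeneDiseaseAssociations",
          function(x) unique(x@disease))
#' @rdname accessors
setMethod("simValues", "DiseaseSimilarity", function(x) x@values)
#' @rdname accessors
setMethod("masValues", "DiseaseTissueMatrix", function(x) x@values)
#' @rdname accessors
setMethod("geneScores", "PropagationResult", function(x) x@scores)
#' @rdname accessors
setMethod("assignmentTable", "TissueAssignment", function(x)
  data.frame(disease = x@disease, tissue = x@tissue, mas = x@mas,
             excluded = x@excluded))

setMethod("show", "GeneCatalog", function(object) {
  cat(sprintf("GeneCatalog with %d genes on %d chromosome(s)\n",
              length(object@geneIds), length(unique(object@chrom))))
})

setMethod("show", "WeightedNetwork", function(object) {
  w <- object@weight
  cat(sprintf("WeightedNetwork: %d nodes, %d edges (catalog of %d genes)\n",
              length(object@nodes), length(object@from), object@nGenes))
  if (length(w))
    cat(sprintf("  weights: min %.4g, median %.4g, max %.4g; %d zero-weight\n",
                min(w), stats::median(w), max(w), sum(w == 0)))
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix (AD units): %d genes x %d tissues\n",
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "BinaryExpressionProfiles", function(object) {
  cat(sprintf(
    "BinaryExpressionProfiles: %d genes x %d tissues at tau = %g AD\n",
    nrow(object@calls), ncol(object@calls), object@tau))
  cat(sprintf("  %.1f%% of calls are 'expressed'\n",
              100 * mean(object@calls)))
})

setMethod("show", "GeneDiseaseAssociations", function(object) {
  cat(sprintf(
    "GeneDiseaseAssociations: %d pairs, %d genes, %d diseases\n",
    length(object@gene), length(unique(object@gene)),
    length(unique(object@disease))))
})

setMethod("show", "DiseaseSimilarity", function(object) {
  cat(sprintf("DiseaseSimilarity: %d diseases\n", nrow(object@values)))
})

setMethod("show", "DiseaseTissueMatrix", function(object) {
  cat(sprintf(
    "DiseaseTissueMatrix (MAS, %%): %d diseases x %d tissues\n",
    nrow(object@values), ncol(object@values)))
})

setMethod("show", "PropagationConfig", function(object) {
  cat(sprintf(
    "PropagationConfig: alpha = %g, iterations = %d, c = %g, b = %g\n",
    object@alpha, object@iterations, object@c, object@b))
})

setMethod("show", "NormalizedNetwork", function(object) {
  cat(sprintf("NormalizedNetwork '%s': %d nodes, %d nonzero entries\n",
              object@label, length(object@nodes),
              Matrix::nnzero(object@mat)))
})

setMethod("show", "PropagationResult", function(object) {
  s <- object@scores
  cat(sprintf("PropagationResult for '%s' on '%s': %d genes\n",
              object@disease, object@label, length(s)))
  cat(sprintf("  score range [%.4g, %.4g], %d exact zeros\n",
              min(s), max(s), sum(s == 0)))
})

setMethod("show", "TissueAssignment", function(object) {
  cat(sprintf(
    "TissueAssignment: %d diseases (threshold MAS > %g%%; %d excluded)\n",
    length(object@disease), object@threshold, sum(object@excluded)))
})
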