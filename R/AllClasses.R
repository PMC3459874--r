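#' @import methods
#' @importFrom stats setNames
NULL

#' Gene catalog with genomic order
#'
#' Holds the ordered set of genes the pipeline operates on. Genes are
#' referenced everywhere by their 1-based catalog index; slot `geneIds`
#' carries the external identifiers (e.g. Entrez) in index order. Each gene
#' has exactly one genomic position, given as a chromosome label plus an
#' ordinal position along that chromosome; ordinals need not be contiguous
#' but must be unique within a chromosome. The genomic order is what the
#' artificial linkage intervals of the benchmark are built from.
#'
#' @slot geneIds character vector of external gene identifiers, one per
#'   catalog index.
#' @slot chrom character vector, chromosome label per gene.
#' @slot pos integer vector, ordinal position of the gene along its
#'   chromosome.
#' @export
setClass("GeneCatalog",
  representation(geneIds = "character", chrom = "character", pos = "integer"))

setValidity("GeneCatalog", function(object) {
  n <- length(object@geneIds)
  if (length(object@chrom) != n || length(object@pos) != n)
    return("geneIds, chrom and pos must have equal length")
  if (anyNA(object@geneIds) || anyNA(object@chrom) || anyNA(object@pos))
    return("NA values are not allowed")
  if (anyDuplicated(object@geneIds))
    return("gene identifiers must be unique")
  dup <- anyDuplicated(paste(object@chrom, object@pos))
  if (dup)
    return(sprintf("duplicate genomic position for gene index %d", dup))
  TRUE
})

#' Weighted undirected gene network
#'
#' An undirected weighted graph over catalog gene indices; the substrate of
#' all propagation. Edges are stored once in canonical orientation
#' (`from < to`). Confidence weights of input networks lie in (0,1]; the
#' edge-reweight construction may lower weights to exactly 0 while keeping
#' the edge structurally, so the class admits \[0,1\]. Self-loops and
#' duplicate edges are invalid.
#'
#' @slot nGenes integer, size of the underlying gene catalog (indices run
#'   1..nGenes).
#' @slot nodes sorted integer vector of node indices present in the network.
#' @slot from,to integer vectors of edge endpoints with `from < to`.
#' @slot weight numeric vector of edge confidences in \[0,1\].
#' @export
setClass("WeightedNetwork",
  representation(nGenes = "integer", nodes = "integer",
                 from = "integer", to = "integer", weight = "numeric"))

setValidity("WeightedNetwork", function(object) {
  m <- length(object@from)
  if (length(object@to) != m || length(object@weight) != m)
    return("from, to and weight must have equal length")
  if (length(object@nGenes) != 1L || is.na(object@nGenes) || object@nGenes < 0L)
    return("nGenes must be a single non-negative integer")
  if (is.unsorted(object@nodes, strictly = TRUE) && length(object@nodes) > 1L)
    return("nodes must be sorted and unique")
  if (length(object@nodes) &&
      (min(object@nodes) < 1L || max(object@nodes) > object@nGenes))
    return("nodes must lie in 1..nGenes")
  if (m) {
    if (anyNA(object@weight) || any(object@weight < 0) || any(object@weight > 1))
      return("edge weights must lie in [0, 1]")
    if (any(object@from >= object@to)) {
      bad <- which(object@from >= object@to)[1L]
      if (object@from[bad] == object@to[bad])
        return(sprintf("self-loop at gene %d", object@from[bad]))
      return("edges must be stored with from < to")
    }
    if (!all(object@from %in% object@nodes) || !all(object@to %in% object@nodes))
      return("edge endpoints must be listed in nodes")
    key <- paste(object@from, object@to)
    if (anyDuplicated(key))
      return(sprintf("duplicate edge (%s)", key[anyDuplicated(key)]))
  }
  TRUE
})

#' Gene-by-tissue expression matrix (AD units)
#'
#' Expression intensities in Affymetrix average-difference (AD) units.
#' Rows are catalog gene indices, columns are tissues. Entries are
#' non-negative; negative microarray artifacts are floored to zero at load
#' time with a warning.
#'
#' @slot values numeric matrix, genes x tissues, non-negative, with unique
#'   tissue column names.
#' @export
setClass("ExpressionMatrix", representation(values = "matrix"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (anyNA(v)) return("NA expression values are not allowed")
  if (any(v < 0)) return("negative AD values are not allowed (floor at load)")
  tn <- colnames(v)
  if (is.null(tn) || anyDuplicated(tn) || any(!nzchar(tn)))
    return("tissue names must be present and unique")
  TRUE
})

#' Binary expression profiles
#'
#' Gene-by-tissue presence calls derived deterministically from an
#' [ExpressionMatrix] at threshold `tau`: a gene is called expressed in a
#' tissue iff its AD value is at least `tau` (inclusive).
#'
#' @slot calls logical matrix, genes x tissues.
#' @slot tau numeric, the AD threshold used (default in the pipeline: 200).
#' @export
setClass("BinaryExpressionProfiles",
  representation(calls = "matrix", tau = "numeric"))

setValidity("BinaryExpressionProfiles", function(object) {
  if (!is.logical(object@calls)) return("calls must be logical")
  if (anyNA(object@calls)) return("NA calls are not allowed")
  tn <- colnames(object@calls)
  if (is.null(tn) || anyDuplicated(tn)) return("tissue names must be unique")
  if (length(object@tau) != 1L || object@tau <= 0)
    return("tau must be a single positive number")
  TRUE
})

#' Gene-disease association set
#'
#' The known causal links between catalog genes and diseases. Duplicate
#' pairs are invalid; cross-references against a catalog and a disease
#' similarity matrix are enforced by the readers/validators that have that
#' context.
#'
#' @slot gene integer vector of catalog gene indices.
#' @slot disease character vector of disease identifiers (opaque strings,
#'   matched exactly and case-sensitively).
#' @export
setClass("GeneDiseaseAssociations",
  representation(gene = "integer", disease = "character"))

setValidity("GeneDiseaseAssociations", function(object) {
  if (length(object@gene) != length(object@disease))
    return("gene and disease must have equal length")
  if (anyNA(object@gene) || anyNA(object@disease))
    return("NA associations are not allowed")
  if (length(object@gene) && any(object@gene < 1L))
    return("gene indices must be positive")
  dup <- anyDuplicated(paste(object@gene, object@disease))
  if (dup)
    return(sprintf("duplicate association (gene %d, %s)",
                   object@gene[dup], object@disease[dup]))
  TRUE
})

#' Disease-disease phenotypic similarity
#'
#' Symmetric matrix of phenotypic similarities in \[0,1\] between diseases.
#' The diagonal is stored as 1 but is never used as prior evidence for a
#' query disease against itself unless explicitly enabled.
#'
#' @slot values numeric symmetric matrix with disease ids as dimnames.
#' @export
setClass("DiseaseSimilarity", representation(values = "matrix"))

setValidity("DiseaseSimilarity", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("similarity matrix must be square")
  if (is.null(rownames(v)) || is.null(colnames(v)) ||
      !identical(rownames(v), colnames(v)))
    return("row and column disease names must be present and identical")
  if (anyDuplicated(rownames(v))) return("disease names must be unique")
  if (anyNA(v) || any(v < 0) || any(v > 1))
    return("similarities must lie in [0, 1]")
  if (!isSymmetric(unname(v), tol = 1e-12))
    return("similarity matrix must be symmetric")
  TRUE
})

#' Disease-by-tissue association scores (MAS matrix)
#'
#' Tissue association scores per disease, in percent, normalized per
#' disease: every row sums to 100 (tolerance 1e-6). The maximal entry of a
#' row is the disease's maximal association score (MAS) and defines its
#' assigned tissue.
#'
#' @slot values numeric matrix, diseases x tissues, entries >= 0, rows
#'   summing to 100.
#' @export
setClass("DiseaseTissueMatrix", representation(values = "matrix"))

setValidity("DiseaseTissueMatrix", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    return("disease row names must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    return("tissue column names must be present and unique")
  if (anyNA(v) || any(v < 0)) return("MAS entries must be >= 0")
  s <- rowSums(v)
  off <- which(abs(s - 100) > 1e-6)
  if (length(off))
    return(sprintf("MAS row '%s' sums to %.8g, not 100", rownames(v)[off[1L]],
                   s[off[1L]]))
  TRUE
})

#' Propagation parameters
#'
#' Parameters of the PRINCE propagation and of the logistic transform that
#' maps phenotypic similarity to a prior score,
#' L(x) = 1 / (1 + exp(c*x + b)).
#'
#' @slot alpha numeric in (0,1), weight of the network term versus the
#'   prior (default 0.9).
#' @slot iterations positive integer, number of propagation iterations
#'   (default 10).
#' @slot c numeric, logistic slope (default -15).
#' @slot b numeric, logistic offset (default log(9999), so that
#'   L(0) = 1e-4).
#' @slot useSelfSimilarity logical; if FALSE (default) the similarity of the
#'   query disease to itself is never used as prior evidence.
#' @export
setClass("PropagationConfig",
  representation(alpha = "numeric", iterations = "integer",
                 c = "numeric", b = "numeric", useSelfSimilarity = "logical"))

setValidity("PropagationConfig", function(object) {
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
    return("alpha must lie strictly between 0 and 1")
  if (length(object@iterations) != 1L || object@iterations < 1L)
    return("iterations must be a positive integer")
  if (length(object@c) != 1L || length(object@b) != 1L)
    return("c and b must be single numbers")
  TRUE
})

#' Degree-normalized propagation operator
#'
#' The symmetric degree-normalized weight operator
#' W'(u,v) = w(u,v) / sqrt(d(u) d(v)) with d the weighted degree, stored as
#' a sparse matrix over the full catalog index space together with the node
#' membership of the underlying network. Zero-weight edges are dropped:
#' propagation treats them as absent.
#'
#' @slot mat sparse symmetric numeric matrix (nGenes x nGenes).
#' @slot nodes integer vector of network node indices.
#' @slot label character label of the network variant.
#' @export
setClass("NormalizedNetwork",
  representation(mat = "Matrix", nodes = "integer", label = "character"))

#' Per-gene propagation scores for one query disease
#'
#' The result of running PRINCE for one query disease over one network
#' variant. Scores cover the full catalog; genes absent from the network
#' carry score exactly 0.
#'
#' @slot disease character, the query disease id.
#' @slot label character, network label (e.g. "generic", "erw:0.1:liver").
#' @slot scores numeric vector of length nGenes, all finite.
#' @export
setClass("PropagationResult",
  representation(disease = "character", label = "character",
                 scores = "numeric"))

setValidity("PropagationResult", function(object) {
  if (!all(is.finite(object@scores))) return("scores must all be finite")
  TRUE
})

#' Disease-to-tissue assignment
#'
#' Per disease, the tissue attaining the row maximum of the MAS matrix
#' (the assigned tissue) together with that MAS value; diseases whose MAS
#' falls at or below the chosen threshold are flagged excluded rather than
#' dropped.
#'
#' @slot disease character vector of disease ids.
#' @slot tissue character vector, assigned tissue per disease.
#' @slot mas numeric vector, the maximal association score (percent).
#' @slot excluded logical vector, TRUE where mas <= threshold.
#' @slot threshold numeric, the MAS threshold used (percent).
#' @export
setClass("TissueAssignment",
  representation(disease = "character", tissue = "character",
                 mas = "numeric", excluded = "logical", threshold = "numeric"))

setValidity("TissueAssignment", function(object) {
  n <- length(object@disease)
  if (length(object@tissue) != n || length(object@mas) != n ||
      length(object@excluded) != n)
    return("disease, tissue, mas and excluded must have equal length")
  if (anyDuplicated(object@disease)) return("disease ids must be unique")
  TRUE
})
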