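#' @rdname accessors
#' @export
setGeneric("numGenes", function(x) standardGeneric("numGenes"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))
#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
#' @rdname accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))
#' @rdname accessors
#' @export
setGeneric("tissueNames", function(x) standardGeneric("tissueNames"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("presenceCalls", function(x) standardGeneric("presenceCalls"))
#' @rdname accessors
#' @export
setGeneric("adThreshold", function(x) standardGeneric("adThreshold"))
#' @rdname accessors
#' @export
setGeneric("associations", function(x) standardGeneric("associations"))
#' @rdname accessors
#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))
#' @rdname accessors
#' @export
setGeneric("simValues", function(x) standardGeneric("simValues"))
#' @rdname accessors
#' @export
setGeneric("masValues", function(x) standardGeneric("masValues"))
#' @rdname accessors
#' @export
setGeneric("geneScores", function(x) standardGeneric("geneScores"))
#' @rdname accessors
#' @export
setGeneric("assignmentTable", function(x) standardGeneric("assignmentTable"))
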