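#' Read a multi-section edge-list file of tissue networks
#'
#' Parses the released tissue-network dialect: sections introduced by a
#' line starting with `#` (the tissue name), followed by rows of
#' whitespace-separated `<gene index> <gene index> <confidence>` triples.
#' Gene indices are 1-based. Confidences are raw (not normalized) and must
#' lie in (0,1]. A duplicate edge within a section, a self-loop, or a
#' malformed row is an error reported with its line number.
#'
#' @param path path to the sectioned edge-list text file.
#' @param nGenes optional catalog size; defaults per network to the largest
#'   index seen in its section.
#' @return Named list of [WeightedNetwork-class] objects, one per section,
#'   in file order.
#' @seealso [writeSectionedEdgeLists()] for the inverse.
#' @export
readSectionedEdgeLists <- function(path, nGenes = NULL) {
  lines <- readLines(path)
  out <- list()
  cur <- NULL
  from <- to <- integer(); weight <- numeric(); seen <- character()
  flush <- function() {
    if (is.null(cur)) return()
    out[[cur]] <<- WeightedNetwork(from, to, weight, nGenes = nGenes)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      flush()
      cur <- trimws(sub("^#", "", ln))
      if (!nzchar(cur)) stop(sprintf("line %d: empty section name", i))
      if (cur %in% names(out))
        stop(sprintf("line %d: duplicate section '%s'", i, cur))
      from <- to <- integer(); weight <- numeric(); seen <- character()
      next
    }
    if (is.null(cur))
      stop(sprintf("line %d: edge row before any '#' section header", i))
    f <- strsplit(ln, "[ \t]+")[[1L]]
    if (length(f) != 3L)
      stop(sprintf("line %d: expected 3 fields, got %d", i, length(f)))
    u <- suppressWarnings(as.integer(f[1L]))
    v <- suppressWarnings(as.integer(f[2L]))
    w <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(u) || is.na(v) || is.na(w))
      stop(sprintf("line %d: malformed row '%s'", i, ln))
    if (u == v) stop(sprintf("line %d: self-loop at gene %d", i, u))
    if (u < 1L || v < 1L)
      stop(sprintf("line %d: gene indices must be >= 1", i))
    if (w <= 0 || w > 1)
      stop(sprintf("line %d: confidence %g outside (0, 1]", i, w))
    key <- paste(min(u, v), max(u, v))
    if (key %in% seen)
      stop(sprintf("line %d: duplicate edge (%s) in section '%s'",
                   i, key, cur))
    seen <- c(seen, key)
    from <- c(from, u); to <- c(to, v); weight <- c(weight, w)
  }
  flush()
  if (!length(out)) stop("no sections found in file")
  out
}

#' Write tissue networks as a multi-section edge-list file
#'
#' Inverse of [readSectionedEdgeLists()]. Weights are serialized with 17
#' significant digits so the round trip is bit-exact. Edges are written in
#' canonical order (ascending `from`, then `to`).
#'
#' @param networks named list of [WeightedNetwork-class] objects; names are
#'   the section (tissue) headers.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSectionedEdgeLists <- function(networks, path) {
  stopifnot(is.list(networks), length(networks) >= 1L,
            !is.null(names(networks)), all(nzchar(names(networks))))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(networks)) {
    net <- networks[[nm]]
    stopifnot(is(net, "WeightedNetwork"))
    writeLines(paste0("#", nm), con)
    if (numEdges(net))
      writeLines(sprintf("%d %d %.17g", net@from, net@to, net@weight), con)
  }
  invisible(path)
}

## --- plain TSV readers -----------------------------------------------------

readTsvMatrix <- function(path) {
  as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                              row.names = 1L, check.names = FALSE,
                              quote = "", comment.char = ""))
}

#' Read a gene catalog from TSV
#'
#' Expects columns `gene`, `chrom`, `pos`; rows in catalog index order.
#'
#' @param path TSV file path.
#' @return A [GeneCatalog-class] object.
#' @export
readGeneCatalog <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "",
                          comment.char = "", colClasses = "character")
  need <- c("gene", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop("catalog TSV must have columns gene, chrom, pos")
  GeneCatalog(df$gene, df$chrom, as.integer(df$pos))
}

#' Read an expression matrix from TSV
#'
#' Rows are genes keyed by catalog id (first column), columns are tissues.
#' Every row id must be a catalog gene; genes without a row receive 0 AD in
#' all tissues. Negative entries are floored to 0 with a warning.
#'
#' @param path TSV file path (header row of tissue names; first column gene
#'   ids).
#' @param catalog a [GeneCatalog-class]; output rows follow catalog order.
#' @return An [ExpressionMatrix-class] with `numGenes(catalog)` rows.
#' @export
readExpressionMatrix <- function(path, catalog) {
  m <- readTsvMatrix(path)
  storage.mode(m) <- "double"
  unknown <- setdiff(rownames(m), geneIds(catalog))
  if (length(unknown))
    stop(sprintf("unknown gene id '%s' in expression matrix", unknown[1L]))
  full <- matrix(0, nrow = numGenes(catalog), ncol = ncol(m),
                 dimnames = list(NULL, colnames(m)))
  full[match(rownames(m), geneIds(catalog)), ] <- m
  ExpressionMatrix(full)
}

#' Read gene-disease associations from TSV
#'
#' Expects columns `gene` (catalog gene id) and `disease`. Unknown genes,
#' and (when `sim` is given) diseases absent from the similarity matrix,
#' are validation errors naming the offender.
#'
#' @param path TSV file path.
#' @param catalog a [GeneCatalog-class].
#' @param sim optional [DiseaseSimilarity-class] to cross-check disease ids.
#' @return A [GeneDiseaseAssociations-class] object.
#' @export
readAssociations <- function(path, catalog, sim = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "",
                          comment.char = "", colClasses = "character")
  if (!all(c("gene", "disease") %in% names(df)))
    stop("association TSV must have columns gene, disease")
  idx <- match(df$gene, geneIds(catalog))
  if (anyNA(idx))
    stop(sprintf("unknown gene id '%s' in associations",
                 df$gene[which(is.na(idx))[1L]]))
  if (!is.null(sim)) {
    bad <- setdiff(df$disease, diseaseIds(sim))
    if (length(bad))
      stop(sprintf("disease '%s' absent from similarity matrix", bad[1L]))
  }
  GeneDiseaseAssociations(idx, df$disease)
}

#' Read a disease similarity matrix from TSV
#'
#' @param path TSV file path (square matrix; first column and header are
#'   disease ids).
#' @return A [DiseaseSimilarity-class] object.
#' @export
readDiseaseSimilarity <- function(path) {
  m <- readTsvMatrix(path)
  storage.mode(m) <- "double"
  DiseaseSimilarity(m)
}

#' Read a disease-by-tissue MAS matrix from TSV
#'
#' Rows must sum to 100 (percent scores normalized per disease); a row that
#' does not is a validation error naming the disease.
#'
#' @param path TSV file path (rows diseases, columns tissues).
#' @param sim optional [DiseaseSimilarity-class] to cross-check disease ids.
#' @return A [DiseaseTissueMatrix-class] object.
#' @export
readMasMatrix <- function(path, sim = NULL) {
  m <- readTsvMatrix(path)
  storage.mode(m) <- "double"
  if (!is.null(sim)) {
    bad <- setdiff(rownames(m), diseaseIds(sim))
    if (length(bad))
      stop(sprintf("disease '%s' absent from similarity matrix", bad[1L]))
  }
  DiseaseTissueMatrix(m)
}

## --- plain TSV writers -----------------------------------------------------

writeTsvMatrix <- function(m, path, idColumn) {
  # 17 significant digits => numeric round trips are bit-exact
  fm <- matrix(sprintf("%.17g", m), nrow = nrow(m), dimnames = dimnames(m))
  df <- data.frame(rownames(m), fm, check.names = FALSE)
  names(df)[1L] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pipeline tables as TSV
#'
#' Writers mirroring the TSV readers; each returns the path invisibly.
#'
#' @param x the object to serialize.
#' @param path output file path.
#' @param catalog a [GeneCatalog-class] used to translate gene indices back
#'   to external ids.
#' @name tsv-writers
NULL

#' @rdname tsv-writers
#' @export
writeGeneCatalog <- function(x, path) {
  df <- data.frame(gene = x@geneIds, chrom = x@chrom, pos = x@pos)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tsv-writers
#' @export
writeExpressionMatrix <- function(x, path, catalog) {
  m <- exprValues(x)
  rownames(m) <- geneIds(catalog)
  writeTsvMatrix(m, path, "gene")
}

#' @rdname tsv-writers
#' @export
writeAssociations <- function(x, path, catalog) {
  df <- data.frame(gene = geneIds(catalog)[x@gene], disease = x@disease)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tsv-writers
#' @export
writeDiseaseSimilarity <- function(x, path)
  writeTsvMatrix(simValues(x), path, "disease")

#' @rdname tsv-writers
#' @export
writeMasMatrix <- function(x, path)
  writeTsvMatrix(masValues(x), path, "disease")
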