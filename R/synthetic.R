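#' Configuration for the synthetic input generator
#'
#' The defaults describe the study conditions every planted benchmark in
#' this package runs under: a scale-free-ish interactome of 3000 genes, 12
#' tissues with roughly half the genes present per tissue (30% housekeeping
#' plus a 30% per-tissue chance for the rest), 200 single-gene diseases
#' grouped into phenotypically similar families of 5 sharing a home tissue,
#' AD magnitudes drawn from right-skewed lognormals rejected to the
#' designed side of the 200-AD threshold (so binarization recovers the
#' design exactly), and MAS rows concentrating 70% on the home tissue.
#'
#' In `"planted"` mode each family additionally has a few *anchor*
#' diseases: phenotypically similar to the whole family but with flat MAS
#' rows, so they are excluded from evaluation and serve purely as prior
#' carriers in cross-validation (when a member association is held out, its
#' siblings and the anchors still supply the propagation prior). Every
#' member's causal gene attaches to the family anchors' genes with moderate
#' confidence, forming the tissue-active disease module.
#'
#' @param nGenes catalog size.
#' @param nTissues number of tissues.
#' @param housekeepingFrac fraction of genes expressed in every tissue.
#' @param tissueFrac per-tissue expression probability for non-housekeeping
#'   genes.
#' @param nDiseases number of evaluated diseases (one causal gene each);
#'   anchor diseases come on top.
#' @param familySize evaluated diseases per phenotypic family (share a home
#'   tissue and a network neighborhood).
#' @param anchorsPerFamily anchor diseases per family.
#' @param simWithin,simBetween disease similarity inside / between
#'   families (anchors included).
#' @param masHome percent of a disease's MAS row on its home tissue; the
#'   remainder is spread evenly.
#' @param paEdges,paPower preferential-attachment parameters of the
#'   network generator (edges per new node; attachment exponent).
#' @param weightShape1,weightShape2 Beta law for edge confidences.
#' @param memberWeight confidence of the edges from each causal gene to its
#'   family's anchor genes.
#' @param decoysPerGene decoy genes planted genomically next to each causal
#'   gene; 0 disables decoys (see [plantedBenchmark()]).
#' @param decoyWeight confidence of decoy-to-anchor edges. Decoys attach to
#'   the anchors with higher confidence than the causal genes do but are
#'   unexpressed in the home tissue: the generic network misranks them
#'   above the causal gene, tissue-specific networks demote them.
#' @param decoyTissueFrac probability a decoy is expressed in each tissue
#'   other than the home tissue.
#' @param unexpressedCausalFrac fraction of causal genes forced unexpressed
#'   in their home tissue (the "confounded" variant emulating the observed
#'   17-29% of lowly expressed disease genes).
#' @param tau AD presence threshold.
#' @param adExpressedMeanlog,adExpressedSdlog,adUnexpressedMeanlog,adUnexpressedSdlog
#'   lognormal location/scale for AD values of expressed/unexpressed calls.
#' @param chromSize approximate genes per chromosome (must exceed the
#'   benchmark interval size).
#' @param masThreshold MAS threshold (percent) baked into the bundle's
#'   tissue assignment; anchor diseases fall below it by construction.
#' @param mode `"planted"` couples causal genes, families and expression to
#'   the home tissue; `"independent"` assigns home tissues independently of
#'   all gene data (for null calibration of the expression statistics);
#'   `"uniform-expressed"` draws each disease's home tissue uniformly among
#'   the tissues where its causal gene is expressed (the null of the
#'   disease-tissue permutation test).
#' @param seed RNG seed (mandatory).
#' @return A list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(nGenes = 3000L, nTissues = 12L,
                            housekeepingFrac = 0.3, tissueFrac = 0.3,
                            nDiseases = 200L, familySize = 5L,
                            anchorsPerFamily = 2L,
                            simWithin = 0.8, simBetween = 0.05,
                            masHome = 70, paEdges = 3L, paPower = 1,
                            weightShape1 = 5, weightShape2 = 2,
                            memberWeight = 0.6,
                            decoysPerGene = 0L, decoyWeight = 0.95,
                            decoyTissueFrac = 0.5,
                            unexpressedCausalFrac = 0,
                            tau = 200, adExpressedMeanlog = log(600),
                            adExpressedSdlog = 0.8,
                            adUnexpressedMeanlog = log(60),
                            adUnexpressedSdlog = 0.9, chromSize = 150L,
                            masThreshold = 40,
                            mode = c("planted", "independent",
                                     "uniform-expressed"),
                            seed) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- list(nGenes = as.integer(nGenes), nTissues = as.integer(nTissues),
              housekeepingFrac = housekeepingFrac, tissueFrac = tissueFrac,
              nDiseases = as.integer(nDiseases),
              familySize = as.integer(familySize),
              anchorsPerFamily = as.integer(anchorsPerFamily),
              simWithin = simWithin,
              simBetween = simBetween, masHome = masHome,
              paEdges = as.integer(paEdges), paPower = paPower,
              weightShape1 = weightShape1, weightShape2 = weightShape2,
              memberWeight = memberWeight,
              decoysPerGene = as.integer(decoysPerGene),
              decoyWeight = decoyWeight,
              decoyTissueFrac = decoyTissueFrac,
              unexpressedCausalFrac = unexpressedCausalFrac, tau = tau,
              adExpressedMeanlog = adExpressedMeanlog,
              adExpressedSdlog = adExpressedSdlog,
              adUnexpressedMeanlog = adUnexpressedMeanlog,
              adUnexpressedSdlog = adUnexpressedSdlog,
              chromSize = as.integer(chromSize),
              masThreshold = masThreshold, mode = match.arg(mode),
              seed = as.integer(seed))
  stopifnot(cfg$nGenes > 0L, cfg$nTissues > 0L, cfg$nDiseases > 0L,
            cfg$housekeepingFrac >= 0, cfg$housekeepingFrac <= 1,
            cfg$tissueFrac >= 0, cfg$tissueFrac <= 1,
            cfg$simWithin >= 0, cfg$simWithin <= 1,
            cfg$simBetween >= 0, cfg$simBetween <= 1,
            cfg$masHome > 0, cfg$masHome <= 100,
            cfg$unexpressedCausalFrac >= 0, cfg$unexpressedCausalFrac <= 1)
  class(cfg) <- "syntheticConfig"
  cfg
}

# lognormal draws rejected to one side of tau
rejectLognormal <- function(n, meanlog, sdlog, tau, below) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  repeat {
    bad <- if (below) x >= tau else x < tau
    if (!any(bad)) return(x)
    x[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
  }
}

#' Generate a full synthetic input bundle
#'
#' Produces every input the pipeline reads -- network, expression atlas,
#' presence design, disease similarity, gene-disease associations, MAS
#' matrix, genomic order -- with controllable tissue-specific structure:
#' a preferential-attachment network with Beta-distributed confidences;
#' housekeeping genes expressed everywhere and other genes in random
#' tissue subsets; diseases in phenotypic families whose causal genes form
#' a module around the family anchors, active in the family's home tissue;
#' MAS rows concentrated on the home tissue; genes randomly permuted into
#' chromosomes large enough for interval construction, with any decoys
#' placed genomically next to their causal gene. AD magnitudes are drawn on
#' the designed side of the threshold, so `binarize(expr, tau)` reproduces
#' the design exactly. Regeneration at the same seed is byte-identical.
#'
#' @param cfg a [syntheticConfig()].
#' @return A list (the bundle) with elements `catalog`, `network`, `expr`,
#'   `profiles`, `assocs`, `sim`, `dtm`, `assign`, `truth` (home tissue,
#'   family and causal gene per evaluated disease, anchor genes/diseases,
#'   decoy map, design call matrix) and `config`.
#' @export
generateBundle <- function(cfg) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  withSeed(cfg$seed, {
    G <- cfg$nGenes; T <- cfg$nTissues; D <- cfg$nDiseases
    tissues <- sprintf("tissue%02d", seq_len(T))
    diseases <- sprintf("disease%03d", seq_len(D))

    ## network: preferential attachment + Beta confidences
    g <- igraph::sample_pa(G, power = cfg$paPower, m = cfg$paEdges,
                           directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    ew <- pmax(stats::rbeta(nrow(el), cfg$weightShape1, cfg$weightShape2),
               1e-6)
    edges <- data.frame(from = pmin(el[, 1L], el[, 2L]),
                        to = pmax(el[, 1L], el[, 2L]), weight = ew)
    edges <- edges[!duplicated(paste(edges$from, edges$to)), ]

    ## expression design
    hk <- sample.int(G, round(cfg$housekeepingFrac * G))
    design <- matrix(stats::runif(G * T) < cfg$tissueFrac, G, T,
                     dimnames = list(NULL, tissues))
    design[hk, ] <- TRUE

    ## diseases, families, causal genes
    nFam <- ceiling(D / cfg$familySize)
    family <- rep(seq_len(nFam), each = cfg$familySize)[seq_len(D)]
    famHome <- sample(tissues, nFam, replace = TRUE)
    pool <- setdiff(seq_len(G), hk)
    # degenerate all-housekeeping configs fall back to the full catalog
    if (length(pool) < D) pool <- seq_len(G)
    if (length(pool) < D)
      stop("infeasible config: fewer genes than diseases")
    causal <- sample(pool, D)
    pool <- setdiff(pool, causal)
    homeTissue <- famHome[family]

    planted <- cfg$mode == "planted"
    anchorGenes <- anchorDiseases <- character(0)
    anchorFamily <- integer(0)
    if (planted) {
      # causal genes expressed in their home tissue (minus the confounded
      # fraction, forced unexpressed there)
      design[cbind(causal, match(homeTissue, tissues))] <- TRUE
      nConf <- round(cfg$unexpressedCausalFrac * D)
      confounded <- if (nConf) sample.int(D, nConf) else integer()
      if (nConf)
        design[cbind(causal[confounded],
                     match(homeTissue[confounded], tissues))] <- FALSE
      # anchors: per-family prior-carrier diseases, excluded from
      # evaluation (flat MAS rows), whose genes seed the family module
      nA <- nFam * cfg$anchorsPerFamily
      if (length(pool) < nA)
        stop("infeasible config: not enough genes for family anchors")
      anchorGenes <- sample(pool, nA)
      pool <- setdiff(pool, anchorGenes)
      anchorFamily <- rep(seq_len(nFam), each = cfg$anchorsPerFamily)
      anchorDiseases <- sprintf("anchor%03d", seq_len(nA))
      design[cbind(anchorGenes, match(famHome[anchorFamily], tissues))] <-
        TRUE
      # module edges: each member gene attaches to its family's anchors
      a1 <- rep(anchorGenes, times = D)[
        rep(anchorFamily, times = D) == rep(family, each = nA)]
      m1 <- rep(causal, each = cfg$anchorsPerFamily)
      edges <- rbind(edges,
                     data.frame(from = pmin(m1, a1), to = pmax(m1, a1),
                                weight = cfg$memberWeight))
    } else {
      confounded <- integer()
      # every causal gene expressed somewhere, so eligibility is never empty
      none <- causal[rowSums(design[causal, , drop = FALSE]) == 0L]
      if (length(none))
        design[cbind(none, sample.int(T, length(none), replace = TRUE))] <-
          TRUE
      if (cfg$mode == "uniform-expressed")
        homeTissue <- vapply(causal, function(cg) {
          e <- tissues[design[cg, ]]
          e[sample.int(length(e), 1L)]
        }, character(1))
      else
        homeTissue <- sample(tissues, D, replace = TRUE)
    }

    ## decoys: attach to the family anchors with high confidence, sit
    ## genomically next to the causal gene, but are unexpressed at home
    decoys <- stats::setNames(rep(list(integer()), D), diseases)
    if (planted && cfg$decoysPerGene > 0L) {
      need <- D * cfg$decoysPerGene
      if (length(pool) < need)
        stop("infeasible config: not enough genes to plant decoys")
      picked <- sample(pool, need)
      dedges <- vector("list", D)
      for (i in seq_len(D)) {
        dg <- picked[((i - 1L) * cfg$decoysPerGene + 1L):
                       (i * cfg$decoysPerGene)]
        decoys[[i]] <- dg
        design[dg, ] <- stats::runif(length(dg) * T) < cfg$decoyTissueFrac
        design[dg, match(homeTissue[i], tissues)] <- FALSE
        fa <- anchorGenes[anchorFamily == family[i]]
        de <- expand.grid(from = dg, to = fa)
        dedges[[i]] <- data.frame(from = pmin(de$from, de$to),
                                  to = pmax(de$from, de$to),
                                  weight = cfg$decoyWeight)
      }
      edges <- rbind(edges, do.call(rbind, dedges))
    }
    # planted edges override any preferential-attachment duplicate
    edges <- edges[!duplicated(paste(edges$from, edges$to),
                               fromLast = TRUE), ]
    network <- WeightedNetwork(edges$from, edges$to, edges$weight,
                               nGenes = G, nodes = seq_len(G))

    ## genomic order: permute into chromosomes, then pull decoys next to
    ## their causal gene so they land inside its linkage interval
    nChrom <- max(1L, round(G / cfg$chromSize))
    sizes <- rep(G %/% nChrom, nChrom)
    extra <- G - sum(sizes)
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    chromOfSlot <- rep(sprintf("chr%02d", seq_len(nChrom)), sizes)
    posOfSlot <- unlist(lapply(sizes, seq_len), use.names = FALSE)
    geneAtSlot <- sample.int(G)
    slotOfGene <- integer(G); slotOfGene[geneAtSlot] <- seq_len(G)
    protected <- logical(G)
    protected[slotOfGene[causal]] <- TRUE
    for (i in seq_len(D)) {
      if (!length(decoys[[i]])) next
      gs <- slotOfGene[causal[i]]
      chrSlots <- which(chromOfSlot == chromOfSlot[gs])
      near <- chrSlots[order(abs(chrSlots - gs))]
      near <- setdiff(near, gs)
      for (dg in decoys[[i]]) {
        target <- near[!protected[near]][1L]
        if (is.na(target)) stop("no free slot near causal gene for decoy")
        # swap decoy into the target slot
        cur <- slotOfGene[dg]
        displaced <- geneAtSlot[target]
        geneAtSlot[target] <- dg; geneAtSlot[cur] <- displaced
        slotOfGene[dg] <- target; slotOfGene[displaced] <- cur
        protected[target] <- TRUE
      }
    }
    catalog <- GeneCatalog(sprintf("gene%05d", seq_len(G)),
                           chrom = chromOfSlot[slotOfGene],
                           pos = posOfSlot[slotOfGene])

    ## AD values on the designed side of tau
    ad <- matrix(0, G, T, dimnames = list(NULL, tissues))
    nOn <- sum(design)
    ad[design] <- rejectLognormal(nOn, cfg$adExpressedMeanlog,
                                  cfg$adExpressedSdlog, cfg$tau, FALSE)
    ad[!design] <- rejectLognormal(G * T - nOn, cfg$adUnexpressedMeanlog,
                                   cfg$adUnexpressedSdlog, cfg$tau, TRUE)
    expr <- ExpressionMatrix(ad)
    profiles <- binarize(expr, cfg$tau)

    ## similarity: block structure over families (anchors included)
    allDiseases <- c(diseases, anchorDiseases)
    allFamily <- c(family, anchorFamily)
    nD <- length(allDiseases)
    sim <- matrix(cfg$simBetween, nD, nD,
                  dimnames = list(allDiseases, allDiseases))
    for (f in unique(allFamily)) {
      idx <- which(allFamily == f)
      sim[idx, idx] <- cfg$simWithin
    }
    diag(sim) <- 1
    sim <- DiseaseSimilarity(sim)

    ## MAS: concentrated on the home tissue for evaluated diseases,
    ## flat (below any practical threshold) for anchors
    mas <- matrix((100 - cfg$masHome) / (T - 1L), nD, T,
                  dimnames = list(allDiseases, tissues))
    mas[cbind(seq_len(D), match(homeTissue, tissues))] <- cfg$masHome
    if (length(anchorDiseases))
      mas[(D + 1L):nD, ] <- 100 / T
    dtm <- DiseaseTissueMatrix(mas)
    assocs <- GeneDiseaseAssociations(c(causal, anchorGenes), allDiseases)

    list(catalog = catalog, network = network, expr = expr,
         profiles = profiles, assocs = assocs, sim = sim, dtm = dtm,
         assign = assignTissues(dtm, cfg$masThreshold),
         truth = list(disease = diseases, family = family,
                      homeTissue = homeTissue, causalGene = causal,
                      anchorGenes = anchorGenes,
                      anchorDiseases = anchorDiseases,
                      anchorFamily = anchorFamily,
                      decoys = decoys, confounded = confounded,
                      design = design, housekeeping = hk),
         config = cfg)
  })
}

#' Planted decoy benchmark
#'
#' A bundle in which tissue information is necessary for good
#' prioritization: each causal gene gets `decoysPerGene` decoy genes that
#' sit inside its linkage interval, attach to the family's anchor genes
#' with higher confidence than the causal gene itself, but are unexpressed
#' in the home tissue. The generic network therefore misranks the decoys
#' above the causal gene, while tissue-specific networks demote their
#' edges -- the mechanism by which a network that better represents the
#' disease-related tissue improves prioritization.
#'
#' @param cfg a [syntheticConfig()]; its `decoysPerGene` is raised to
#'   `decoysPerGene` if smaller.
#' @param decoysPerGene default number of planted decoys per causal gene
#'   (default 5).
#' @return A bundle as from [generateBundle()]; `truth$decoys` maps each
#'   disease to its decoy genes.
#' @export
plantedBenchmark <- function(cfg, decoysPerGene = 5L) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  if (cfg$mode != "planted")
    stop("the planted benchmark requires mode = 'planted'")
  if (cfg$decoysPerGene < decoysPerGene)
    cfg$decoysPerGene <- as.integer(decoysPerGene)
  generateBundle(cfg)
}

#' Write a synthetic bundle to disk in the pipeline's file formats
#'
#' Emits every format the readers consume: the generic network as a
#' single-section edge list, per-tissue NR and ERW networks as sectioned
#' edge lists, and TSVs for catalog, expression, associations, similarity
#' and MAS.
#'
#' @param bundle a bundle from [generateBundle()].
#' @param dir output directory (created if missing).
#' @param rw penalty for the emitted ERW networks; default 0.1.
#' @return The directory path, invisibly.
#' @export
writeBundle <- function(bundle, dir, rw = 0.1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeSectionedEdgeLists(list(generic = bundle$network), p("network.txt"))
  writeGeneCatalog(bundle$catalog, p("catalog.tsv"))
  writeExpressionMatrix(bundle$expr, p("expression.tsv"), bundle$catalog)
  writeAssociations(bundle$assocs, p("associations.tsv"), bundle$catalog)
  writeDiseaseSimilarity(bundle$sim, p("similarity.tsv"))
  writeMasMatrix(bundle$dtm, p("mas.tsv"))
  nr <- buildTissueNetworks(bundle$network, bundle$profiles, "nr")
  # zero-weight ERW edges are structural; the interchange format requires
  # confidences in (0,1], so emitted ERW networks drop exact zeros
  erw <- lapply(buildTissueNetworks(bundle$network, bundle$profiles, "erw",
                                    rw = rw), dropZeroEdges)
  writeSectionedEdgeLists(nr, p("nr_networks.txt"))
  writeSectionedEdgeLists(erw, p("erw_networks.txt"))
  invisible(dir)
}

#' Drop zero-weight edges from a network
#'
#' @param net a [WeightedNetwork-class].
#' @return The network without its weight-0 edges (node set unchanged).
#' @export
dropZeroEdges <- function(net) {
  keep <- net@weight > 0
  new("WeightedNetwork", nGenes = net@nGenes, nodes = net@nodes,
      from = net@from[keep], to = net@to[keep], weight = net@weight[keep])
}
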