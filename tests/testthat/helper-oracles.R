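# Fixtures and independent oracles used across the suite.

# small deterministic networks ------------------------------------------------

pathNetwork <- function(n = 3, w = 1) {
  WeightedNetwork(seq_len(n - 1), 2:n, rep(w, n - 1), nGenes = n)
}

triangleNetwork <- function(w = c(0.5, 0.6, 0.7)) {
  WeightedNetwork(c(1, 1, 2), c(2, 3, 3), w, nGenes = 3)
}

starNetwork <- function(leaves = 4, w = 1) {
  WeightedNetwork(rep(1, leaves), 1 + seq_len(leaves), rep(w, leaves),
                  nGenes = leaves + 1)
}

# Erdos-Renyi-ish random weighted network over n nodes (>= 1 edge)
randomNetwork <- function(n, p = 2 / n, wmin = 0.05) {
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample.int(nrow(pairs), 1L)] <- TRUE
  WeightedNetwork(pairs[keep, 1L], pairs[keep, 2L],
                  runif(sum(keep), wmin, 1), nGenes = n,
                  nodes = seq_len(n))
}

# oracle: step-by-step propagation recurrence on a dense matrix ---------------

brutePropagate <- function(net, y, alpha = 0.9, iterations = 10) {
  G <- numGenes(net)
  W <- matrix(0, G, G)
  e <- edges(net)
  for (k in seq_len(nrow(e))) {
    W[e$from[k], e$to[k]] <- e$weight[k]
    W[e$to[k], e$from[k]] <- e$weight[k]
  }
  d <- rowSums(W)
  Wn <- matrix(0, G, G)
  for (u in seq_len(G)) for (v in seq_len(G))
    if (W[u, v] > 0) Wn[u, v] <- W[u, v] / sqrt(d[u] * d[v])
  y0 <- numeric(G)
  y0[nodes(net)] <- y[nodes(net)]
  f <- y0
  for (i in seq_len(iterations))
    f <- alpha * as.numeric(Wn %*% f) + (1 - alpha) * y0
  f[setdiff(seq_len(G), nodes(net))] <- 0
  f
}

# oracle: AUC by explicit concordant-pair counting (ties count 1/2) -----------

bruteAUC <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# oracle: exact signed-rank null by enumerating all 2^n sign assignments ------

bruteSignedRank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  allW <- apply(subsets, 1, function(s) sum(r[as.logical(s)]))
  list(statistic = W,
       p.greater = mean(allW >= W),
       p.less = mean(allW <= W))
}

# oracle: connected components via union-find ---------------------------------

bruteComponents <- function(net) {
  parent <- seq_len(numGenes(net))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  e <- edges(net)
  for (k in which(e$weight > 0)) {
    a <- find(e$from[k]); b <- find(e$to[k])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(nodes(net), find, integer(1))
  sizes <- as.integer(table(roots))
  list(n = length(sizes), sizes = sort(sizes, decreasing = TRUE))
}

# small expression fixture -----------------------------------------------------

tinyProfiles <- function(calls) {
  # calls: logical matrix with tissue colnames
  new("BinaryExpressionProfiles", calls = calls, tau = 200)
}

# a small planted bundle shared by slower tests (cached per session)
smallPlantedBundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- plantedBenchmark(syntheticConfig(
        nGenes = 600L, nTissues = 6L, nDiseases = 40L, familySize = 5L,
        chromSize = 120L, seed = 42))
    cache
  }
})

ksCriticalOneSided <- function(n, alpha = 0.01) sqrt(log(1 / alpha) / (2 * n))

# one-sided KS-style distance testing super-uniformity: sup_x (ECDF(x) - x)
ksPlus <- function(p) {
  p <- sort(p)
  n <- length(p)
  max(seq_len(n) / n - p)
}
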