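# tsprince

Tissue-specific protein-interaction networks for disease-gene
prioritization.

## The problem

Network-based gene prioritization ranks the genes inside a disease-linked
genomic interval by how close they lie, in a protein-protein interaction
(PPI) network, to genes causing phenotypically similar diseases. The
standard approach uses one static, tissue-agnostic interactome — yet most
hereditary diseases manifest in one or a few tissues, and the active PPI
network of a hepatocyte is not that of a neuron. `tsprince` builds
**tissue-specific PPI networks** from a generic weighted interactome plus
binary expression profiles, runs the **PRINCE** propagation prioritizer
over them, and quantifies how much the tissue information improves the
ranking of true causal genes. It is aimed at computational biologists who
want to benchmark, extend or stress-test tissue-aware prioritization
without assembling the original proprietary datasets: a synthetic-data
generator with planted tissue-specific signal makes every stage testable
end to end.

## The model

A gene is *expressed* in a tissue when its intensity reaches τ = 200
Affymetrix average-difference (AD) units. Two constructions turn the
generic network into a tissue network:

* **NR (node removal)** — delete every protein not expressed in the
  tissue, with all adjacent edges; surviving edges keep their confidence
  weights.
* **ERW (edge reweight)** — keep the topology and multiply each edge's
  confidence by a penalty *rw* ∈ [0,1] once per unexpressed endpoint:
  w′(i,j) = w(i,j)·rwⁿ, n ∈ {0,1,2}. *rw* is the probability that a gene
  below the threshold is nonetheless expressed; rw = 1 recovers the
  generic network, rw = 0 is NR.

PRINCE scores a query disease *q* by smoothing a phenotype-derived prior
over the network. Each gene *v* with a known association gets prior
Y(v) = L(sim(q, d\*)) where d\* is its associated disease most similar to
*q* and L(x) = 1/(1 + e^(cx+b)) (c = −15, b = ln 9999, so L(0) = 10⁻⁴);
all other genes get Y(v) = 0. With W′ the symmetrically degree-normalized
weight matrix, w′(u,v) = w(u,v)/√(d(u)d(v)), the score is iterated

    F⁰ = Y,   F^(t+1) = α · W′ F^t + (1 − α) · Y

for 10 iterations at α = 0.9. The benchmark holds out each gene-disease
association ⟨g,d⟩ (plus every other association of *g*), scores an
artificial linkage interval of the 100 network genes genomically nearest
to *g*, and compares networks by pooled ROC/AUC, by per-case rank
(Wilcoxon signed-rank), and by repeated 25-fold cross-validation spread.
Running the prioritizer once per tissue network also ranks tissues per
disease — the basis for inferring disease-tissue associations, tested
against a permutation null.

## Worked example

Generate a benchmark with planted tissue-specific signal — each causal
gene's linkage interval contains decoy genes that attach to the disease
module with *higher* confidence but are unexpressed in the disease's home
tissue — then compare generic and tissue-specific prioritization:

```r
library(tsprince)

bundle <- plantedBenchmark(syntheticConfig(nGenes = 600, nTissues = 6,
                                           nDiseases = 40, familySize = 5,
                                           chromSize = 120, seed = 42))
bundle$network
#> WeightedNetwork: 600 nodes, 2271 edges (catalog of 600 genes)
#>   weights: min 0.1408, median 0.7724, max 0.997; 0 zero-weight
bundle$profiles
#> BinaryExpressionProfiles: 600 genes x 6 tissues at tau = 200 AD
#>   55.9% of calls are 'expressed'

res <- runLOOCV(bundle$assocs, bundle$assign, bundle$catalog,
                bundle$network, bundle$profiles, bundle$sim,
                variants = list(generic = networkVariant("generic"),
                                nr = networkVariant("nr"),
                                `erw:0.1` = networkVariant("erw", rw = 0.1)),
                intervalSize = 60)
sapply(colnames(res$ranks), function(v) pooledROC(res, v)$auc)
#>   generic        nr   erw:0.1
#> 0.8580833 0.9892917 0.9884792
```

The generic network is fooled by the decoys (AUC 0.86); both
tissue-specific variants demote them (AUC 0.99). Case by case:

```r
cmp <- compareRankings(res, variantA = "erw:0.1", variantB = "generic")
unlist(cmp[c("better", "tie", "worse", "p.value")])
#>  better     tie   worse  p.value
#>      40       0       0  3.3e-08
```

TS-ERW ranks the true causal gene better than generic PRINCE in all 40
cases (Wilcoxon signed-rank p = 3.3e-08). Ranking tissues per disease
recovers the planted disease-tissue associations:

```r
tr  <- rankTissuesAll(bundle$assocs, bundle$assign, bundle$catalog,
                      bundle$network, bundle$profiles, bundle$sim,
                      intervalSize = 60)
agg <- topTissueAgreement(tr, bundle$assign)
pn  <- tissuePermutationNull(tr, bundle$profiles, bundle$assign,
                             nPerm = 1000, seed = 1)
c(fracFirst = agg$fracFirst, p = pn$p)
#> fracFirst         p
#>     1.000  0.000999
```

The assigned tissue is ranked first for every disease; the permutation
null (random tissues drawn among those where the causal gene is
expressed) never reaches the observed count, so p = 1/1001.

A command-line interface over the same functions ships in
`inst/scripts/tsprince` (subcommands `synth`, `build-ts-nets`,
`net-stats`, `prince`, `benchmark`, `expressed-fraction`,
`infer-tissues`); every run writes a manifest JSON with config, seeds and
input digests.

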