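---
title: "Tissue-specific network propagation for disease-gene prioritization: methods and design"
author: "tsprince"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-specific network propagation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsprince)
```

# The model

`tsprince` implements propagation-based prioritization of candidate
disease genes over tissue-specific protein-interaction networks. Three
ingredients define the method.

**Presence calls.** A gene is considered expressed in a tissue when its
microarray intensity is at least τ Affymetrix average-difference (AD)
units; the default τ = 200 is the classical presence threshold for this
platform, and the comparison is inclusive (`binarize()`). Probe-level
input is reduced first by arithmetic-averaging replicate samples per
tissue and then selecting, per gene, a single probe
(`collapseProbes()`). We select the probe with the maximal *across-tissue
mean*, so each gene is measured by one probe in every tissue. A per-tissue
maximum would be the other defensible reading of "the probe with the
maximal expression level"; we chose the global rule because mixing probes
across tissues would break the cross-tissue comparability on which the
binary profiles and the expression-breadth statistic rest.

**Tissue networks.** Given the generic weighted interactome and the set
of genes expressed in a tissue, `nodeRemoval()` (NR) deletes unexpressed
proteins and their edges, while `edgeReweight()` (ERW) keeps the topology
and multiplies each edge confidence by a penalty rw once per unexpressed
endpoint, w′ = w·rwⁿ with n ∈ {0,1,2}. rw is interpreted as the
probability that a gene below the threshold is expressed after all, which
is why the two limits are exact identities: rw = 1 returns the generic
network bit-for-bit and rw = 0 is node removal (both identities are
enforced by tests). ERW at rw = 0 keeps the zero-weight edges
*structurally* so that node sets and score-vector dimensions stay fixed
across a sweep of rw; propagation drops zero-weight edges when it builds
its operator, so the retained zeros are inert.

**Propagation.** For a query disease q, each gene with a usable
association receives the prior Y(v) = L(sim(q, d\*)), d\* being its
associated disease most similar to q, through the logistic
L(x) = 1/(1+e^{cx+b}). The published slope is c = −15; the offset is not
printed alongside it, so we fix b = ln 9999 following the original
propagation method this builds on, which pins L(0) = 10⁻⁴ — a dissimilar
disease contributes essentially nothing, while L(1) ≈ 0.997. Both
constants sit in `PropagationConfig()` rather than being hard-coded. The
network operator is the symmetric degree normalization
w′(u,v) = w(u,v)/√(d(u)d(v)) with *weighted* degrees d(x) = Σ w(x,y);
using edge counts instead would ignore precisely the signal ERW encodes
in its weights. Scores follow F⁰ = Y,
F^{t+1} = α·W′F^t + (1−α)·Y with α = 0.9 and 10 iterations, the
published setting. Because ρ(αW′) ≤ α < 1 the recurrence contracts to a
unique fixed point F\* = (1−α)(I−αW′)⁻¹Y independent of initialization;
we start from Y by convention. `closedFormScores()` computes F\* by a
dense solve (guarded to 2000 nodes) purely as a test oracle — the suite
checks ‖F₁₀ − F\*‖∞ ≤ α¹⁰‖Y‖∞ and near-exact agreement at 200
iterations. Genes absent from a network score exactly 0, which is what
makes node-removal networks penalize unexpressed candidates.

# The benchmark

Leave-one-out cross-validation (`runLOOCV()`) removes one association
⟨g,d⟩ *and every other association of g* — otherwise a second disease
caused by the same gene would leak the answer into the prior. We also
never use sim(q,q) itself as prior evidence (configurable via
`useSelfSimilarity`); with it, genes co-associated with the query would
receive the near-maximal prior L(1) even in cross-validation, which is a
different and easier task than locating a novel gene.

Candidates are an artificial linkage interval: the 100 network genes
genomically nearest to g, balanced 50/50 up- and downstream with
spill-over at chromosome ends, plus g itself (101 scored). Ranks use
**pessimistic tie handling** — g ranks after every candidate tied with
it. This matters because NR networks produce many exact zeros: an
optimistic rule would hand a perfect rank to an unexpressed causal gene
that the method in fact scored 0, inverting the intended penalty.

Pooled ROC curves concatenate all trials' scores (positives: held-out
causal genes, labeled per trial); the AUC uses the Mann–Whitney
convention, crediting ties ½, so all-identical scores give exactly 0.5.
The per-case comparison reports better/tie/worse counts, with ties shown
separately and dropped by the Wilcoxon signed-rank test (the classic
procedure). The signed-rank test is implemented in-package: with tied
|differences| no exact p-value is available from `stats::wilcox.test`,
so we enumerate the 2ⁿ sign-assignment null through a
generating-function recursion (exact up to n = 25 pairs, correct under
ties) and fall back to the tie-corrected, continuity-corrected normal
approximation above that. Brute-force enumeration is the test oracle.
`kfoldAucSpread()` replaces leave-one-out with k-fold partitions
(unstratified simple random, k = 25, 10 partitions by default) to put an
error bar on the AUC, and `rwSweep()` scans rw over a constant grid and
then downward by orders of magnitude, stopping when performance declines
and converges to the rw = 0 level.

For disease-tissue inference (`rankTissuesAll()`), the prioritizer runs
once per tissue ERW network (rw = 0.1, the setting with stable positive
behavior across association sets) and tissues are ordered by the causal
gene's relative rank, or alternatively by its absolute score, which
differentiates tissues more finely. Tied tissues share a competition
rank ("1,2,2,4"); since a tie at the top then counts as "ranked first"
for every tied tissue, `topTissueAgreement()` reports both that
accounting and the strict one (assigned tissue uniquely first), so
neither reading of the headline agreement fraction is lost. The
permutation null redraws each disease's tissue uniformly among the
tissues where its causal gene is expressed — the right reference given
that evaluation is restricted to expressed causal genes — and all
empirical p-values in the package use the add-one convention
(1+k)/(N+1), so zero exceedances of 10,000 permutations report the bound
10⁻⁴, never 0.

# The synthetic generator

`generateBundle()` produces every input the pipeline reads, with a known
ground truth. What it emulates, and how the defaults were chosen:

* **Interactome** — preferential attachment (3 edges per node, linear
  attachment) for a heavy-tailed degree distribution; Beta(5,2)
  confidences. 3000 genes keeps a 200-case benchmark comfortably fast
  while leaving the linkage intervals (100 genes within ~150-gene
  chromosomes) non-degenerate.
* **Expression** — 30% housekeeping genes expressed everywhere; other
  genes expressed per tissue with probability 0.3, giving ~50% presence
  calls per tissue, inside the range real atlases show. AD magnitudes
  are lognormal draws rejected to the designed side of τ, so
  `binarize()` recovers the designed calls *exactly*; we deliberately
  traded marginal realism of the AD distribution for a crisp, testable
  correspondence between the continuous matrix and the binary truth.
* **Diseases** — 200 single-gene diseases in families of 5 sharing a
  home tissue and a similarity block (0.8 within, 0.05 between — on the
  logistic's scale, priors of 0.94 versus 2·10⁻⁴). Each family also has
  2 *anchor* diseases: phenotypically similar prior carriers whose flat
  MAS rows keep them out of evaluation, so held-out cases always retain
  prior support. Member genes attach to the anchors' genes with moderate
  confidence (0.6), forming the tissue-active module.
* **MAS matrix** — 70% on the home tissue, remainder spread evenly; rows
  sum to 100 by construction, and the default 40% threshold retains
  exactly the evaluated diseases.
* **Decoys** (`plantedBenchmark()`) — per causal gene, 5 genes placed
  genomically inside its interval, attached to the family anchors with
  *higher* confidence (0.95) than the causal gene itself, but
  unexpressed in the home tissue (and expressed elsewhere with
  probability 0.5). One propagation hop from the prior carriers beats
  two, so the generic network ranks decoys above the causal gene, while
  any tissue-aware construction demotes them — the precise mechanism by
  which tissue information is supposed to help. The decoys never touch
  an evaluated causal gene directly, so no score flows back into the
  held-out gene through them.
* **Null modes** — `mode = "independent"` draws disease-tissue
  assignments independently of all gene data (the exchangeable null of
  the expressed-fraction permutation test); `mode = "uniform-expressed"`
  draws each assignment uniformly among the causal gene's expressed
  tissues (the exact null of the tissue permutation test). The
  calibration tests check *super*-uniformity of the resulting p-values
  with a one-sided Kolmogorov–Smirnov-style distance, because add-one
  p-values on discrete statistics are conservative by construction; a
  two-sided uniformity test would reject them for being conservative,
  which is not a calibration failure.

What the generator does **not** emulate: probe-level noise structure,
correlated expression between interacting proteins, diseases with
multiple causal genes, text-mined similarity/MAS artifacts, or the
confidence-calibration quirks of real interactome scoring. Passing the
planted benchmark therefore shows the machinery is correct and that the
tissue signal, where present in this idealized form, is recovered — it
does not by itself predict effect sizes on real data.

# Numerical and interface choices

* Gene indices are 1-based in files and internally; identifiers are
  opaque, matched exactly and case-sensitively.
* Edge weights serialize with 17 significant digits, so reader/writer
  round trips are bit-exact (verified on 60-tissue bundles).
* Negative AD inputs (microarray artifacts) are floored to 0 with a
  warning at construction.
* MAS rows must sum to 100 within 10⁻⁶; violations are errors naming the
  disease.
* Degenerate inputs degrade explicitly: a single-tissue assignment
  vector warns and yields p = 1; all-identical pooled scores warn and
  yield AUC 0.5; a single k-fold partition warns and yields sd 0;
  zero-variance columns make a Pearson correlation NA rather than an
  error.
* Components in `networkStats()` are defined over strictly positive
  edges; an expressed node whose incident weights are all zero is its
  own singleton component.
* All randomized routines take an explicit seed, restore the caller's
  RNG state, and are reproducible run-to-run; the CLI fans one top-level
  seed out per stage and writes a manifest (config, seeds, input
  digests) beside every output.

The test suite runs its heavier checks at reduced problem sizes chosen
as the package's own trade-off between resolution and turnaround: the
planted benchmark at 600 genes/40 cases for unit-level properties and at
the full 3000 genes/200 cases for the end-to-end reproduction; null
calibration at 200 replicates with 199 permutations each, which bounds
the attainable p-value resolution at 1/200 and is reflected in the
one-sided distance threshold used.

# Known limitations

mRNA presence is a proxy for protein presence; the threshold τ is global
rather than gene-specific; ERW's independence assumption (each endpoint
unexpressed independently with probability rw) ignores co-regulation;
and the disease-tissue ranking inherits any bias in the MAS-style
assignment it is compared against. The package quantifies prioritization
under these assumptions; it does not test them.
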