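---
title: "Methods: network-based horizontal integration of transcriptomics layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based horizontal integration of transcriptomics layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexweave)
```

# The model

`coexweave` treats each transcriptomics dataset (a *layer*) as a weighted
gene co-expression network and integrates datasets at the network level.
The underlying assumptions are:

* expression matrices are **normalized** and, where several batches exist,
  batch-corrected upstream — the package performs neither;
* co-expression is meaningfully captured by pairwise correlation across
  samples, and only **strong positive** correlation (the working grid is
  0.9–1.0) is evidence of co-regulation — negative and weak correlations
  never form edges;
* genes are matched across layers by **exact identifier**; harmonizing
  symbols across platforms is the user's responsibility.

Working on the network representation rather than the expression values
makes the integration indifferent to the layers' data types and scales:
a microarray layer and an RNA-seq layer contribute comparable objects
(thresholded correlation graphs), so neither's technical variance structure
can dominate the joint analysis.

## Group Fold-Changes

GFCs summarize each gene's expression trend over the condition groups
defined by one annotation column. With group means
$m_g(x_i)$ over label set $X$:

* **no controls**:
  $\mathrm{GFC}(g, x_i) = \dfrac{m_g(x_i)}{\frac{1}{|X|}\sum_{x_j \in X} m_g(x_j)}$.
  The denominator is the mean of the numerators, so each gene's GFCs
  average exactly 1 — a useful algebraic identity that the test suite
  asserts at $10^{-9}$.
* **with controls**:
  $\mathrm{GFC}(g, x_i, n) = \dfrac{m_g(x_{i,n})}{m_g(x_{c,n})}$
  within each layer $n$ independently, with control group $x_{c,n}$. The
  control column is identically 1. Because the reference is layer-local,
  this mode absorbs differences in per-condition sample sizes and in the
  condition spaces of the layers; it is the recommended mode whenever the
  layers are not well matched.

GFCs are raw ratios, exactly as defined — not log fold-changes (an optional
`log2` flag transforms the ratios on request, but is off by default). Both
modes are invariant to positive rescaling of a gene, which is what makes
them comparable across platforms with different dynamic ranges. Means are
taken on the expression values as given; the package takes no position on
whether the input is on linear or log scale, and documents that choice as
the user's. A zero denominator (possible in normalized data containing
zeros) yields an explicit undefined marker (`NA`) with a warning — never a
clamped or epsilon-padded value — and such genes are excluded from module
summaries downstream.

## Variance filter and the elbow suggestion

The per-layer variance filter keeps the top-$n$ most variant genes
(skippable by setting $n$ to the gene count). `suggest_topvar()` proposes
$n$ from the ranked $\log_{10}$-variance curve: the curve is smoothed with
a centered moving average (window $\max(5, 1\%\ \text{of genes})$, forced
odd) and the rank with the **largest magnitude of the discrete second
difference** of the smoothed curve — the dominant bend — is suggested.
All local maxima of the second-difference magnitude are reported so a user
can prefer an earlier or later elbow; the dominant one is the single
defensible default suggestion when the curve has one clear shoulder. A
curve with no detectable inflection (e.g. exactly linear in the log) falls
back to the full gene count with a warning. The procedure is
scale-equivariant: rescaling all variances shifts the log curve without
moving its inflections. Ties in variance are broken by lexicographic gene
identifier so the filter is deterministic.

## Cutoff statistics and scale-free fit

For each candidate cutoff the package reports four criteria: the
scale-free-topology $R^2$, edge count, node count (non-isolated genes) and
connected-component count. Thresholded edge sets are nested along the
grid, so edge and node counts are monotone non-increasing — a property the
test suite checks on random inputs.

$R^2$ is the coefficient of determination of the least-squares fit of
$\log_{10}(\text{frequency})$ on $\log_{10}(\text{degree})$ over the
**distinct positive degrees** with their raw frequencies — not a binned
histogram and not the complementary cumulative distribution; this is the
simplest reproducible reading of the logged node-degree distribution, and
it is a package decision, not an externally fixed convention. With fewer
than two distinct degrees the fit is undefined and marked `NA`; a flat
log-frequency profile is fit exactly by a horizontal line and reported as
$R^2 = 1$.

The guide table is the product; choosing the cutoff is deliberately left
to the user, balancing a high $R^2$ against keeping enough genes and
avoiding the "hairball" of an over-dense network. `select_cutoff()` is a
labelled convenience heuristic only: among cutoffs retaining at least a
third of the maximal node count it takes the best $R^2$, preferring the
sparser network on ties.

## Thresholding and integration

An edge requires a **signed** coefficient $\ge$ cutoff; the comparison is
inclusive so a pair sitting exactly at a published cutoff (e.g. 0.982)
keeps its edge. Isolated genes are dropped from the node set.

Two integration modes:

* **union** — node and edge sets are unions over layers; holistic view
  including layer-specific co-expression.
* **intersection** — one layer is the reference; the result's node and
  edge sets are exactly the reference's, and each edge is annotated with
  its presence and weight in every other layer, so the question becomes
  "how does the reference network change elsewhere?".

Multi-edges are resolved to the minimum (default), mean or maximum of the
per-layer weights. Minimum is the default because it approximates the true
co-expression by its lower bound and thins the network, which helps the
subsequent community detection. The mean is computed over the layers that
contain the edge — absence from a layer is structural information, never
weight 0 — and over all layers at once, so no policy depends on layer
order. Every integrated edge keeps its full per-layer provenance
(`w_<layer>` attributes), making integration decisions auditable and the
intersection mode's comparisons queryable. For intersection mode the
resolved weight is recomputed by policy over present layers (the
reference's own weight remains available in the provenance); this is an
interpretation choice, as the weight source for reference-mode edges is
genuinely open.

## Modules, labels, summaries, hubs

Community detection maximizes weighted modularity; the default is Leiden
at resolution 1.0 with a fixed default seed of 1, and the seed is always
recorded in the partition, so identical inputs and seeds give identical
partitions. Louvain, fast-greedy, edge-betweenness, walktrap and infomap
are exposed as alternatives through the same interface.

Modules smaller than `min_size` (default 25 genes) are dissolved into the
unassigned pool — small communities on a thresholded graph are more often
threshold artifacts than biology. Module labels are colour names from a
fixed list, assigned by descending module size with ties broken by the
lexicographically smallest member gene; labels are therefore a pure
function of the partition, and consistently renaming genes permutes
memberships but not the label sequence.

The module summary is the module × (layer, group) matrix of mean GFCs over
the module's genes, averaging **defined values only**: a gene missing from
a layer, or with an undefined GFC, contributes nothing to that layer's
cells (no zero-fill — absence of measurement is not absence of change).
Condition columns are ordered by agglomerative hierarchical clustering of
their mean-GFC profiles on Euclidean distance. Complete linkage is the
default (configurable); the linkage behind such heatmap dendrograms is not
externally fixed, so this is a package default, not a convention.
Undefined cells trigger pairwise-complete distances with a warning.

Hub genes are ranked within the module-induced subgraph by **weighted
degree** (sum of incident edge weights) — the simplest defensible hub
notion, flagged as such; unweighted degree and betweenness (with distances
taken as inverse weights) are available. Ties break lexicographically.

## Enrichment

Module interpretation uses one-sided hypergeometric over-representation
against GMT collections: with universe size $N$, set size $K$ and module
size $n$ (all after intersection with the universe), the p-value for an
observed overlap $k$ is $P(X \ge k)$, $X \sim \mathrm{Hyper}(N, K, n)$.
The default universe is the node set of the integrated network — the
object actually being interpreted — and can be overridden (e.g. to all
measured genes); the universe choice is reported in every result row.
Benjamini–Hochberg adjustment is applied per module across all sets of one
collection, matching the downstream per-module filtering: terms with
adjusted $p \le 0.1$, the 5 smallest per module (both configurable). A
module with nothing passing is simply absent from the filtered output.
TF-target enrichment runs the identical machinery on TF-keyed GMT
libraries, entirely offline, and can additionally report which target
pairs are wired in the integrated network.

# The synthetic benchmark

`generate_layers()` plants ground truth for end-to-end testing. Module
genes share a per-module latent factor: gene $g$ in sample $s$ is
$\mathrm{effect}(m, \mathrm{grp}(s)) \cdot (10 + \sqrt{\rho}\, z_{m,s} +
\sqrt{1-\rho}\, e_{g,s})$ with $z, e \sim N(0, \sigma^2)$, giving
within-module, within-group correlation $\approx \rho$; background genes
are independent noise. The defaults define the standard benchmark: 2
layers, 5 modules × 40 genes, 200 background genes, 3 groups (ctrl/A/B) ×
10 samples, $\rho = 0.95$, $\sigma = 1$, seed 1. The baseline offset of 10
keeps all values positive (so control-anchored GFC denominators are well
behaved) and makes the group effect dominate the noise the way a real
regulated module dominates its sampling noise; effect multipliers cycle
2.0 / 0.5 / 1.5 over the non-control groups so every module has a distinct,
recoverable condition pattern and module 1 carries a 2.0 effect in group A.
Latent factors are drawn independently per layer: layers agree on *which*
genes co-express, not on sample values, mirroring independent studies of
shared biology.

What the generator does **not** emulate: count-distribution realism
(negative-binomial mean–variance coupling), platform-specific effects
(probe saturation, length bias), partially overlapping gene panels, or
correlated background structure. Passing the planted-recovery tests
therefore demonstrates that the pipeline's algebra and wiring are correct
and that clearly separable co-expression structure is recovered — not that
the method's thresholds are well calibrated for any particular real
platform pair, which remains a per-dataset judgement via the cutoff guide.

# Numerical and determinism choices

* Inclusive threshold on the signed coefficient; negative correlation is
  outside the model.
* Undefined is explicit: constant genes correlate as `NA` and never enter
  networks; zero GFC denominators yield `NA` plus a warning; $R^2$ with one
  distinct degree is `NA`; empty post-threshold networks are valid, warned
  objects (clustering one is a clear error, not a crash).
* All tie-breaks are lexicographic (variance ranks, boundary ranks, hub
  scores, enrichment terms at equal adjusted p), making every output
  deterministic and TSV artifacts byte-stable.
* Every stochastic step takes a seed, runs under it in an isolated RNG
  scope, and records it; the pipeline's `run_record.json` captures
  parameters, seeds, package/R versions and input digests, so the record
  plus inputs reproduce every output exactly.

The test suite exercises these properties at deliberately small problem
sizes — the standard benchmark (400 genes × 60 samples across 2 layers)
for end-to-end recovery, 10–60-node random graphs for the network algebra,
and universes of at most 25 genes for exhaustive hypergeometric
enumeration — sizes chosen so every oracle can be brute-forced exactly
while still covering the structural cases (ties, NA markers, empty
graphs) that dominate correctness.

# Known limitations

* Exact-identifier gene matching only; no ortholog or probe mapping.
* No automatic cutoff selection beyond the labelled heuristic; the guide
  table is advisory by design.
* GFCs are descriptive ratios; no inferential statistics on group
  differences are attached.
* Enrichment is over-representation only (no ranked/GSEA mode, no
  depletion testing), and TF enrichment depends entirely on the quality of
  the supplied target libraries.
* The union of very dense layer networks can still produce a hairball no
  clustering algorithm resolves; the cutoff guide's edge counts are the
  instrument for catching this before integration.
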