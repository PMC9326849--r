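---
title: "Annotating cis-regulatory elements by heterogeneous network embedding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating cis-regulatory elements by heterogeneous network embedding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regoa)
```

## The problem

Most of the genome is non-coding, and a large share of trait-associated
variation falls into cis-regulatory elements (REs) — enhancers and
promoters — rather than genes. Gene Ontology annotation, however, is a
gene-level resource. The usual workaround, transferring the nearest
gene's annotation to a peak, ignores that REs regulate distal genes,
multiple genes, and different genes in different cellular contexts.

`regoa` annotates REs directly. It integrates four sources into one
heterogeneous network — the GO `is_a` hierarchy, gene-to-term
annotations, a protein–protein interaction (PPI) network and a
context-specific gene regulatory network (GRN) of TF→RE binding and
RE→target-gene regulation — embeds all nodes into a common vector space,
and calls a GO term for an RE when two independent lines of evidence
agree: the embedding similarity exceeds a per-term calibrated threshold,
and at least one of the RE's target genes carries the term.

## The heterogeneous network

Nodes have four types: GO terms (T), genes/proteins (G), regulatory
elements (R) and transcription factors (F). Seven typed edge sets
connect them:

* `isa` (T–T): child term to parent term, `is_a` relations only. Other
  GO relations (`part_of`, `regulates`, ...) are sparse, frequently
  cross-namespace, and are ignored; each namespace (BP, MF, CC) is
  processed as its own network.
* `annotated` (G–T): gene-to-term annotations after True-Path-Rule
  closure — a gene annotated by a term is annotated by all of the term's
  ancestors, so `GOA_g(G) = GOA_raw(G) ∪ ⋃_{t∈GOA_raw(G)} anc(t)`.
* `interacts` (G–G): weighted PPI edges.
* `binds` (F–R) and `regulates` (R–G): the two GRN layers.
  Chromatin-regulator recruitment rows are dropped at load time.
* Two inferred edge sets: `indirect_annotated` (R–T) holds whenever the
  RE regulates some gene annotated by the term, and `coregulates`
  (R–R) whenever two REs share a target gene.

The union of the closed annotation sets over an RE's target genes,
`GOA_raw(R) = ⋃_{G ∈ reg(R)} GOA_g(G)`, is the regulation-derived
annotation; being a union of ancestor-closed sets it is itself closed.

A TF symbol yields a TF node distinct from the same symbol's gene node
(`split_tf_gene = TRUE`), so the binding role and the gene-product role
receive independent embeddings; a flag collapses them if desired.

## Meta-path-guided random walks

Walks are constrained by meta-paths — ordered node-type sequences. The
eight defaults are RT, FRF, RGGR, GRFRG, GTT, GTG, GTTG and GGG, each
extended to the walk length by tiling its printed repetition pattern
(FRF → F,R,F,R,F,...; RGGR → R,G,G,R,R,G,G,R,...; GTT → G,T,T,T,...;
RT does not repeat). Where the tiling juxtaposes two symbols of the same
type, the boundary step is a real edge: the G–G boundary of GTTG walks a
PPI edge, and the R–R boundary of RGGR walks a `coregulates` edge.

At each step the walker samples a neighbor connected by the edge type
the meta-path requires between the current and next node type,
proportionally to edge weight (`weighted = FALSE` switches to uniform).
Dead ends truncate a walk; sub-`min_length` walks are dropped. On
ablation networks (e.g. no PPI) `default_metapaths(net)` keeps only the
meta-paths whose full tiled expansion is walkable.

## Skip-gram training

The corpus of walks is fed to skip-gram with negative sampling: for a
context window of `window` nodes (randomly reduced per position, as in
word2vec), each (context, center) pair receives one positive update and
`negatives` noise updates, with noise drawn from the unigram
distribution raised to 3/4. Occurrences of nodes more frequent than
`sample` (default `1e-3`) are down-sampled by the standard word2vec
rule, which stops the most frequent node types from dominating the
co-occurrence statistics. Training is single-threaded SGD with a
linearly decaying learning rate, implemented in C++ with an internal
RNG, so a fixed seed reproduces the vectors bit for bit. Orderings that
feed the RNG (vocabulary, edge tables) are locale-independent.

The reported vector of a node is the average of its input and output
vectors (`vectors = "average"`): the objective optimizes input–output
dot products, and for node pairs whose evidence is mostly direct
co-occurrence — REs and terms in the short RT walks — the averaged form
reflects the trained quantity much more directly than input vectors
alone. `vectors = "input"` gives classical word2vec behavior.

`typed_negatives` enables heterogeneous negative sampling: noise nodes
are drawn only among nodes of the same type as the positive. See
*Design choices* below for why it is off by default.

## Calibration and RE annotation

Similarity between a node and a term is True-Path-Rule-aware:

```
sim(v, T) = max over T' in des(T) ∪ {T} of cos(x_v, x_T')
```

so closeness to any specialization of T counts as closeness to T.

Because deep terms and shallow terms live at very different similarity
scales, each term gets its own threshold, calibrated on gene function
prediction: `Thres(T)` maximizes the f1 of predicting T's annotated
genes by `sim(G, T) > t` over the embedded gene universe. f1 only
changes where `t` crosses an observed similarity, so the search runs
over midpoints of consecutive sorted similarities plus the endpoints −1
and 1; among equally optimal candidates the largest (most stringent) is
returned. Terms with no annotated gene, or never embedded, stay
uncalibrated and are excluded.

The embedding-derived annotation of an RE is
`Anno(R) = {T : sim(R, T) > Thres(T)}` together with all ancestors of
its members (closed by construction), and the final resource records the
intersection:

```
GOA_re(R) = GOA_embed(R) ∩ GOA_raw(R)
```

Both operands are ancestor-closed, hence so is the result. The
intersection is deliberately conservative: an embedding call survives
only when the RE's own target genes support the term.

## Evaluation

`split_goa()` partitions the deduplicated (gene, term) pairs of the
closed annotation map 80/20 at random. The training side drives network
assembly and threshold calibration; held-out pairs are scored by
`sim(G, T)` against `neg_ratio` negatives per positive sampled uniformly
from pairs absent from the full closed map, and summarized as AUROC via
the rank statistic. We split the closed map (rather than the raw,
pre-closure pairs) because the calibration gold standard
`G_standard(T) = {G : T ∈ GOA_g(G)}` is defined on the closed map;
splitting raw pairs leaves only hard leaf-level positives and measures a
different, strictly harder task.

## Enrichment of genomic region sets

Given a region set, each region is assigned to its nearest annotated RE
if the distance (0 for overlapping or book-ended intervals, else the gap
between closest ends) is strictly below 1 kb; ties break to the lower RE
start. With `N` assigned regions, a term carried by `k ≥ 1` of their REs
is tested with the upper binomial tail

```
P(t) = Pr(X >= k),  X ~ Binomial(N, p(t))
```

where the background `p(t)` is the genome-wide fraction of annotated REs
carrying `t`. Benjamini–Hochberg correction is applied over the tested
terms and rows are sorted by increasing FDR. Terms with `k = 0` cannot
be enriched and are not tested.

## Application drivers

* **ChIP-seq TF annotation** (`run_chip`): the top 15 000 peaks by
  −log10 p (or all, if fewer) are enriched; terms with FDR below
  `theta = 5e-8` plus their ancestors form the prediction, evaluated
  against the TF's own closed GO annotation by precision, recall, f1
  and AvgMSS — the mean, over predicted terms, of each term's maximum
  semantic similarity to any gold-standard term, using a Wang-style
  measure (S-values decaying by 0.8 per `is_a` edge).
* **Differential ATAC-seq** (`run_atac`): peaks whose openness ratio
  between two conditions exceeds `phi = 2` in either direction (zero
  denominators count as infinite ratio) and whose larger openness
  exceeds 2 are enriched.
* **GWAS trait similarity** (`run_gwas`): each trait's significant SNPs
  (1-bp regions) are enriched; the profile keeps terms with FDR below
  `fdr_cut = 0.05` (configurable; a permissive cut suits small SNP
  sets), and two traits are compared by the Jaccard index of their
  enriched term sets. Two empty sets give 0, flagged with a warning.

## The planted-community benchmark

`make_planted_world()` generates a fully synthetic test bed whose layers
share one community structure: by default 2 communities, each owning a
15-term subtree under a common root, 20 genes annotated by 1–3 of the
subtree's terms, 10 REs regulating 1–3 community genes, and 3 TFs
binding 3–6 community REs; every generated edge is redirected across
communities with probability `cross_edge_rate` (default 0.05). RE loci
are 200 bp intervals spaced 1 kb apart on a toy chromosome, small enough
that quadratic test oracles stay fast; PPI scores are drawn on a
STRING-like 400–999 scale and GRN weights near 1. TSS positions are
emitted for the proximal/distal regulation split
(`filter_regulates_by_distance`, 5 kb cut).

The generator emulates the statistical skeleton real inputs share —
community-correlated layers, weighted edges, a DAG with multi-parent
terms — but not their scale or their noise character: real GOA is far
sparser per gene universe, real PPI score distributions are bimodal,
real GRNs have hub TFs and heavy-tailed target counts, and real
ontologies are far deeper. Passing the planted-recovery tests therefore
demonstrates that the machinery integrates correlated layers correctly,
not that a particular AUROC will transfer to genome-scale data.

Tests and the acceptance script run this world at its default size
(about 100 network nodes, ~2 300 walks per run), keeping a full
pipeline run under a second and the whole replicated benchmark in
seconds.

## Design choices

* **Walk length.** Default `length = 5`, `walks_per_start = 20`. With
  long walks (40 nodes) the gene–term co-occurrence mass of the
  GTT/GTG/GTTG paths dominates the corpus by two orders of magnitude
  over the RT path (which cannot repeat and always yields 2-node
  walks). Converged training then drives gene–term similarities far
  above RE–term similarities, the gene-calibrated thresholds land above
  every RE score, and the embedding-derived RE sets empty out. Short
  walks keep the per-path co-occurrence budget balanced, and the lost
  long-range context is largely recovered through window-level mixing
  across many short walks.
* **Negative sampling.** Homogeneous by default. Typed
  (metapath2vec++-style) sampling raises held-out gene-function AUROC
  at long walk lengths, but on the planted benchmark it also makes the
  single-layer networks (annotation+GRN only) match or beat the full
  network at gene function prediction, inverting the expected
  integration ordering; with the default configuration the full network
  dominates both ablations consistently. Users focused purely on gene
  function prediction may prefer `typed_negatives` with longer walks.
* **Calibration universe.** All embedded training genes; overridable.
* **Strict inequalities** are used both in `G_predict(T, t)` and
  `Anno(R)`, and the nearest-RE rule is strictly `< max_dist`.
* **Degenerate inputs.** REs without embeddings receive empty embedding
  sets (warning); terms annotated to every gene calibrate to −1
  (anything passes, harmless after intersection); all-zero openness
  rows are never differential; empty region sets return empty tables
  with a warning rather than errors.
* **Determinism.** Every stochastic stage takes a seed and restores the
  caller's RNG state; builds rerun byte-identically and independently
  of the session locale.

## Limitations

* The intersection rule means an RE with unannotated target genes can
  never be annotated, whatever its embedding neighborhood — inherited
  sparsity of the input annotation is not overcome, only refined.
* Thresholds are calibrated on genes but applied to REs; the two score
  distributions differ systematically (genes have direct annotation
  edges, REs only inferred ones), which is why corpus balance matters
  and why recall on REs is sensitive to the walk configuration.
* GRN inference itself is out of scope: the package consumes a GRN, it
  does not estimate one.
* Single-threaded training is built for the network sizes of one
  cellular context, not for multi-million-node corpora.
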