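---
title: "Methods: integrative analysis of stepwise cell transformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative analysis of stepwise cell transformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepomics)
```

`stepomics` analyses three-stage isogenic transformation designs: a baseline
cell state, an immortalized intermediate, and a fully transformed state.
This vignette documents the statistical model of each stage, the synthetic
data generator that backs the test suite, the numerical choices that the
code makes where the methodology leaves room, and the limitations we know
about.

## Differential expression and co-expression pathways

Each later stage is compared against the baseline (never against the
preceding stage): `ratio_step1` is the stage-2/stage-1 fold ratio and
`ratio_step2` the stage-3/stage-1 ratio. Ratios are computed from replicate
means on the linear scale, while significance comes from Welch's
unequal-variance two-sample *t*-test on log2 values with Welch–Satterthwaite
degrees of freedom — the appropriate model for independent, approximately
log-normal abundance measurements whose variances need not match between
stages. No multiple-testing correction is applied by default: the caller
gates on the per-gene *p*-value at `alpha = 0.05` together with the fold
gates `fc_up = 2`, `fc_down = 0.5` (always reciprocal by default). A
Benjamini–Hochberg option (`adjust = "BH"`) is available but off by default.

A gene is a DEG iff at least one step call is non-`ns`. The eight non-null
call patterns over `{up, down, ns}^2` are mapped onto seven co-expression
pathway labels by a configurable table (`default_pathway_mapping()`); the
default merges the two discordant reversal patterns, (up, down) and
(down, up), into the single label ii. The mapping is data, not code: the
correspondence of sign patterns to labels is a labelling convention, so it
ships as a table the user can replace.

**Power at two replicates.** With two replicates per stage the Welch test
has 1–2 degrees of freedom, so its two-sided 5% critical value lies between
4.3 and 12.7. At the generator defaults (planted mean |log2 ratio| 1.5,
replicate noise SD 0.25 — a 6-SD effect) the per-step detection power is
only ≈ 0.5: the noisy two-point variance estimate, not the effect size, is
the limiting factor, and no distribution of planted magnitudes with mean 1.5
lifts exact-label recovery anywhere near 95%. This is a property of the
two-replicate design itself, faithfully reproduced here. Two consequences:

* the test suite asserts the ≥ 95% pathway-label recovery bound as stated
  and that check fails under the default two-replicate conditions — it
  passes at three or more replicates, which raises power to ≈ 0.99 (the
  step-fraction recovery test runs at four replicates for exactly this
  reason);
* recovery of structures owned by the *downstream* stages (driver TFs,
  hubs, bottlenecks) is assessed from the planted DEG table
  (`gold_deg_table()`), i.e. conditionally on a correct expression stage, so
  that the expression stage's power ceiling does not masquerade as an
  association- or network-stage defect. The end-to-end path on called DEGs
  is still exercised by the pipeline tests, and the acceptance script
  reports both the end-to-end recoveries and the stage-conditional ones.

## Chromatin signal and promoter states

Coverage is binned into 100-bp non-overlapping windows on a shared grid.
Within each ChIP target the stage tracks are quantile-normalized
(rank-mean substitution, computed with `limma::normalizeQuantiles`): after
normalization the sorted intensity multisets of a target's samples are
identical, exactly so for tie-free intensities and up to tie averaging for
counts. Targets are then brought to a common scale by z-scoring each track
to mean 0, SD 1, which makes the single threshold z > 1.65 (the 95th
percentile under normality) comparable across antibodies with very
different global enrichment.

A mark is present at a promoter-stage iff all three criteria hold:

1. a peak summit within ±500 bp of the TSS (boundaries inclusive; BED-style
   0-based half-open coordinates; the window is symmetric, so strand only
   affects the sign of the reported offset);
2. z-score of the track at the summit bin above `zmin = 1.65`;
3. subsampling dispersion below `max_dispersion = 0.15`.

Dispersion quantifies the fragility of a peak under reduced sequencing
depth: the raw counts in the bins around the summit are binomially thinned
to fractions 0.9/0.7/0.5 (three replicates each by default), each recovered
intensity is rescaled by its fraction, and dispersion is the coefficient of
variation across all subsamples. Under this count model dispersion scales
like `1/sqrt(total reads)`, so it is only asymptotically invariant to
uniform intensity scaling; an all-zero region returns `Inf` and therefore
fails the gate. Readers accept both narrow- and broad-peak dialects: a
missing summit column falls back to the interval midpoint.

The five presence bits map onto seven states. With A = number of active
marks (H3K4me3, H3K9ac, H3K27ac), P = Pol II, R = H3K27me3:

| R | condition            | state               |
|---|----------------------|---------------------|
| 0 | P and A ≥ 2          | active              |
| 0 | P and A = 1          | weakly_active       |
| 0 | no P and A ≥ 2       | transcription_prone |
| 0 | single mark or P alone | ambiguous         |
| 0 | nothing              | empty               |
| 1 | no active evidence   | repressed           |
| 1 | any active evidence  | bivalent            |

The last row is a closure decision: combinations with H3K27me3 plus exactly
one active mark (or Pol II alone) are not covered by the
active/weakly-active/transcription-prone definitions, but the semantics of
bivalency — repressive and active evidence at once — argues for classing
them bivalent. `bivalent_closure = FALSE` reclassifies those eleven
combinations as ambiguous instead. Either way the classifier is a total
function on all 32 combinations with exactly seven reachable labels, which
the test suite checks exhaustively.

The ordered state triple across the three stages is a gene's transition
cluster (at most 7³ = 343 are possible); presence calls use the ±500-bp
criterion while display profiles (`median_profile()`) use ±1.5 kb — the two
windows serve different purposes (calling vs. visualization) and both are
exposed as parameters.

## Regulatory association and integration

TF selection applies two filters: regulon coverage strictly greater than
`min_cover = 0.10` of at least one pathway's DEGs (the denominator is the
pathway, not the regulon), and Pol II presence at the TF's own promoter in
at least one stage (`polII_stages = "all"` requires every stage; the stage
is otherwise unspecified, so "any" is the permissive default). Enrichment is
the upper-tail hypergeometric probability of the observed regulon-pathway
overlap against the expression universe; only over-representation is tested
because the association of interest is positive regulatory coverage.
`-log10(p)` is capped at 300 to keep clustering distances finite. Rows and
columns of the association matrix are ordered by agglomerative hierarchical
clustering with average linkage on Euclidean distances — a conventional,
deterministic choice; both are configurable.

Chromatin-state clusters are integrated with pathways through the Pearson
residuals `(O − E)/√E` of their contingency table over the genes common to
both inputs; the residual sum of squares equals the chi-square statistic,
which the tests verify against `chisq.test`. Cells with residual above 2
(≈ one-sided 97.7%) are flagged enriched. A degenerate table (single row or
column) yields all-zero residuals and a warning rather than an error.

## GRN assembly and topological reduction

The network layers are kept provenance-tagged: undirected
`interaction` edges (kept only between DEGs), directed `regulon` edges
(selected TF to DEG target), and directed `oncogene_chip` edges from the
oncogene node to its high-confidence targets (peaks with −log10 *p* ≥ 300
whose summit lies within ±1000 bp of a TSS; the window is a package default
since peak-to-promoter assignment conventions vary). The same gene pair may
carry one edge per provenance; duplicates within a provenance collapse.

The topological metrics are computed on the undirected skeleton (the Hubba
family of metrics has no directed variant): MNC, DMNC with ε = 1.7, and the
BottleNeck score with BFS trees built under deterministic sorted-neighbor
ordering (each newly discovered vertex hangs under its smallest-id
discoverer; a node is a bottleneck in a tree when its subtree exceeds a
quarter of that tree's nodes). All three are checked against brute-force
oracles on hundreds of random graphs. Reduction keeps the union of the
top-`k_hubs` nodes by MNC, top-`k_hubs` by DMNC, and top-`k_bottlenecks` by
BottleNeck (ties broken by degree, then id) and returns the induced
subgraph, so no edge between retained nodes is ever lost. The defaults
(`k_hubs = 32`, `k_bottlenecks = 10`) match the default generator geometry
below, selecting ≈ 5% of nodes; users wanting a gentler reduction simply
raise the k's.

## The synthetic study generator

`simulate_study()` plants every structure the pipeline is asked to recover.

* **Expression.** 2000 genes; baseline log2 abundance N(8, 1.5); 35% of
  genes carry a pathway label, split so that the expected fractions of DEGs
  changing at step 1 / step 2 / both mirror a mostly-late-changing design
  (≈ 47/65/12%); planted |log2 ratios| are N(1.5, 0.225) in magnitude;
  replicate noise N(0, 0.25); two replicates per stage.
* **Chromatin.** One linear chromosome, TSSs 10 kb apart so ±1.5 kb windows
  never overlap. Each pathway has a fixed planted state trajectory (e.g.
  bivalent → active → active for early induction, active → empty → empty for
  early shutdown); non-DEGs hold a constant state. Each state's defining
  marks are emitted jointly per promoter-stage with probability
  `state_emission = 0.95` — jointly rather than per mark, so a single
  emission failure produces an empty promoter instead of silently morphing
  one state into another, and per-stage state recovery is bounded below by
  the emission rate itself. Planted peak bins draw ~200 reads over a
  negative-binomial background of mean 8, so the z > 1.65 gate separates
  them by construction. Driver-TF promoters emit deterministically: they
  anchor the regulatory layer, and the Pol II filter is exercised by decoy
  TFs instead. Decoy peaks are planted both away from TSSs (real signal,
  wrong place) and at promoters lacking the mark (weak signal failing the z
  and dispersion gates); both rates are configurable and can be set to zero
  for exact-recovery tests.
* **Regulons and network.** 14 driver TFs (two per pathway, themselves genes
  of that pathway) with ≈ 75% — never below 50% — of their targets inside
  their pathway, co-drivers disjoint; 11 decoy TFs with regulons mostly
  outside the DEG set, roughly half of them at Pol II-free promoters. The
  interaction network is modular: communities aligned with the
  co-expression pathways (co-expressed genes interact preferentially), each
  community a clique of 8 engineered hub genes plus a preferential-
  attachment spoke tree, each spoke attached to exactly one hub. Consecutive
  communities are joined only through designated bottleneck connector
  genes, and the two largest communities sit at the ends of the chain so
  every connector separates more than a quarter of the graph. All planted
  regulatory target sets (driver regulons, the oncogene cistrome) and the
  per-hub spoke attachments are sampled as (distance-2) independent sets in
  the spoke trees: the regulatory layers stay orthogonal to the engineered
  topological roles, each hub's maximum neighborhood component is exactly
  its clique, and recovery of hubs and bottlenecks genuinely tests the
  metrics rather than accidents of the wiring. The oncogene is a driver of a
  late-changing pathway; its ChIP peaks carry −log10 *p* ∈ [300, 600] at the
  designated targets, with sub-threshold and mislocated decoys.

All randomness flows from the single `seed` (sub-stages use fixed small
offsets so they are reproducible standalone and composed); identical seeds
give byte-identical written bundles, which the test suite checks by
checksum.

**What the generator does not emulate.** Read-level artifacts (mappability,
GC bias, fragment-length effects), overlapping or bidirectional promoters,
enhancer signal away from TSSs, correlated replicate noise, batch effects,
and regulons that overlap the interaction core. Passing recovery tests
therefore demonstrate the correctness of the statistical machinery under
the stated model, not robustness to every artifact of real ChIP-seq or
microarray data.

## Problem sizes and runtime

The default study (2000 genes, 15 tracks of 200,000 bins, ≈ 700-node
network) runs the full pipeline in well under a minute on one CPU; the test
suite uses this size for recovery and determinism checks and smaller
configurations (80–500 genes) elsewhere. Exhaustive oracle comparisons use
all 32 mark combinations, hypergeometric margins up to N = 25, and ≥ 200
random graphs with up to 8 nodes.

## Known limitations

* The two-replicate Welch design caps DEG sensitivity near 50% at the
  default effect size (see above); with `adjust = "BH"` it drops further.
  Designs with ≥ 3 replicates recover > 95% of planted labels.
* Dispersion is a count-based coefficient of variation; for very shallow
  tracks the background counts dominate the peak window and the gate loses
  discrimination.
* The bivalent closure is a convention; the eleven affected combinations
  are rare in the generator but may matter on real data, hence the switch.
* Hierarchical-clustering leaf orders are deterministic but depend on the
  input row order through `hclust` tie handling; the partition structure
  (tested via `cutree`) does not.
* BottleNeck scores depend on the stated BFS tie-breaking convention;
  other shortest-path-tree constructions give slightly different scores on
  graphs with many equal-length paths.
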