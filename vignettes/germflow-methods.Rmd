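---
title: "Scoring spermatogenesis progression from single-cell data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring spermatogenesis progression from single-cell data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

germflow analyses whole-testis single-cell RNA-seq with one organising
question: how far through spermatogenesis does each germ cell get, and how
does that distribution — together with the somatic and immune composition —
change across samples of different ages? This vignette documents the model
behind each stage, the parameters that matter, the numerical conventions,
and the choices we made where the design was genuinely open. It states no
empirical result beyond what the package's tests and acceptance script
themselves compute.

## Quality control

Testis tissue transcribes at very high rates, so a fixed upper bound on
genes per cell is inappropriate; instead the upper threshold is derived
from each sample's own distribution of detected genes. A cell is kept when
all three hold:

* mitochondrial percentage ≤ `max_pct_mito` (default 5; the filter removes
  only cells strictly *above* the cutoff),
* detected genes > `min_genes` (default 200, exclusive — a cell with
  exactly 200 genes is removed),
* detected genes < *n*, with *n* computed per sample on the pre-filter
  distribution.

Two rules for *n* are provided: `q3`, the third quartile itself (the
default, the literal reading of "largest value of the third quartile"), and
`tukey_fence`, Q3 + 1.5·(Q3 − Q1), since an "interquartile range
calculation" often denotes the fence. The `q3` rule deliberately discards
the top quarter of cells; the fence keeps the bulk and removes outliers.
The rule in force is recorded in the filter report, and the pipeline
default is `tukey_fence` because on data with an injected low-quality
population the q3 rule removes a quarter of perfectly healthy cells.
Quartiles use the linear-interpolation definition (type 7: interpolation
between order statistics at position 1 + p(n − 1)) so that thresholds are
bit-reproducible across implementations. The three criteria are
conjunctive, so their order of application is immaterial.

## Normalization, clustering and typing

Expression is log-normalized (counts ÷ cell total × 10,000, then natural
log1p); zero-count cells map to all-zero columns rather than NaNs. The
top 2,000 genes by variance of log expression (ties broken
lexicographically by gene id) feed a PCA (genes centred and unit-scaled;
20 components; the sign of each axis fixed so its largest-magnitude
loading is positive, making the embedding deterministic).

Clustering operates on a symmetrized exact kNN graph (Euclidean,
`k_neighbors = 15` by default) and offers two deterministic,
permutation-invariant methods:

* **label propagation** (default): cells are visited in a canonical order
  (lexicographic on their embedding coordinates), each adopting the most
  frequent label among its neighbours, ties to the smallest label, until a
  fixed point. This resolves well-separated populations crisply — two
  separated blobs give exactly two clusters, one blob gives one — but a
  *connected* differentiation continuum collapses into a single cluster.
* **leiden**: igraph's Leiden algorithm under the modularity objective,
  run on the canonically ordered graph with a fixed RNG state (hence
  equally deterministic and permutation-invariant). Modularity partitions
  a connected continuum into segments, which is exactly what root-cluster
  selection needs; the flip side is that even a single homogeneous blob is
  split into a handful of communities.

The atlas-level clustering used for cell typing uses label propagation;
the trajectory stage uses Leiden internally (see below). We make no claim
that either reproduces any particular dataset's cluster count — cluster
granularity is dataset-dependent plumbing here, not a result.

Cell types are assigned at cluster level, not per cell: for each candidate
type, the mean log expression of its marker genes is averaged per cluster
and z-scored across clusters; a cluster takes the arg-max type if that
z-score reaches `z_threshold` (default 1.0 — permissive enough that small
somatic clusters, which can only be one or two standard deviations above
the rest, are still called), otherwise "unknown". The default panel maps
ddx4 → spermatogonia, sycp3 → spermatocytes, ccnb3 → spermatids,
tssk6 → spermatozoa, gsdf → Sertoli, star → Leydig, tagln/acta2 → smooth
muscle, hbba1 → blood, mpeg1.1 → macrophage, and lck → lymphocyte (lck is
our addition: the panel needs at least one lymphoid marker and the pan-T
kinase is the conventional zebrafish choice). Marker tables use a
one-vs-rest Wilcoxon rank-sum test per gene (normal approximation with tie
and continuity correction — cross-checked against `stats::wilcox.test` in
the test suite), Benjamini–Hochberg adjustment within each cluster, and
the rank-biserial correlation 2·AUC − 1 as effect size.

## Flood pseudotime and the differentiation score

The germ-cell graph uses k = round(√n) neighbours — 200 at 40,000 cells,
88 at 7,744 — floored at 2 and capped at n − 1. Flood pseudotime runs
`n_simulations = 50` stochastic replicates: in each, every non-root cell
is retained independently with probability `cells_per_step_fraction = 0.8`;
roots are visited at step 0; at each step an unvisited retained cell
becomes visited when at least `min_visited_neighbors = 2` of its
neighbours are visited (one suffices for cells with fewer than two
retained neighbours). A cell's pseudotime is the mean over replicates of
(visit step ÷ that replicate's maximum step), min–max rescaled to [0, 1].
Cells never visited in any replicate are flagged and pinned at 1; if more
than 5% of cells are flagged they are excluded from the rescaling and a
warning is emitted. With subsampling off (fraction 1, quorum 1) the
procedure reduces exactly to breadth-first-search hop distance, which the
test suite verifies against an independently coded BFS oracle.

The forward flood roots in the two clusters highest in mean *ddx4*
(spermatogonia); the reverse flood roots in the single cluster highest in
*tssk6* (spermatozoa). Root-cluster ties are broken by the smaller cluster
id and reported. The per-cell differentiation score is
D = (pt_fwd + (1 − pt_rev)) / 2, min–max rescaled over the object, so both
bounds are attained: 0 marks the most spermatogonial state, 1 the most
differentiated spermatozoa state. For objects that lack spermatozoa
entirely, the reverse marker falls back tssk6 → ccnb3 → sycp3 (first
marker actually expressed); which cluster truly anchored the reverse flood
in such data is unknowable from marker logic alone, so the fallback order
is a documented convention, not a claim.

Whether the final min–max normalization should be global per object or per
sample is an open choice; we normalize globally per scored object and note
that per-sample normalization would erase exactly the cross-sample
differences the score exists to show.

## Aligning a truncated object to the reference

Samples whose germ cells occupy a distinct transcriptional state cannot be
scored jointly with the reference, so they are scored separately and then
aligned. The incomplete object's most differentiated germ stage present
(determined by typing its own clusters) is matched into the reference:
shared genes are jointly standardized across both cell sets, cells are
projected onto shared principal axes (20 by default), and each matched
cell adopts the *mean* reference score of its `n_neighbors = 15` nearest
reference cells. The scaling constant M is the maximum adopted score and
all of the object's scores are rescaled multiplicatively,
D_scaled = D · M — the literal reading of scaling by the matched maximum.

Two design notes. First, anchor-based integration is deliberately replaced
by joint standardization + shared PCA + neighbour transfer: it is simple,
deterministic, and adequate for estimating one scalar M; it does not
attempt to correct batch structure. Second, averaging over a small
neighbourhood rather than copying the single nearest neighbour matters
because M is a *maximum*: over hundreds of matched cells, a max of
single-neighbour scores is an extreme-value statistic of the flood's
per-cell noise and lands systematically above the reference score at the
truncation frontier, while the neighbourhood mean keeps M within the
tolerance the truncation-recovery checks use. This mirrors standard
practice in label transfer, where predictions average over a weighted
neighbour set.

## Composition outputs

Score profiles bin D into `n_bins = 10` equal half-open bins [i/n,
(i+1)/n), the last bin closed so D = 1 is counted; per-sample counts
become percentages (each sample sums to 100 exactly), and an age's profile
is the unweighted mean over that age's replicate samples — averaging after
per-sample normalization, so a small replicate counts as much as a large
one. Composition tables map fine types onto broad categories (the four
germ stages collapse to "germ"; unmapped types go to "other" with a
warning) and report counts and percentages per sample and per age.

## The synthetic generator

The generator emulates the structure the analysis assumes, not any real
dataset. Its defaults are the study conditions used throughout the tests:

* **Design**: six samples at 5, 12, 20, 22 and 27 months; all but one
  complete (t_max = 1.0, 93% germ cells, ~7% somatic split across Sertoli,
  Leydig, smooth muscle, blood, macrophage, lymphocyte); the 27-month
  incomplete sample truncated at t_max = 0.5 with 35% germ and a 40%
  immune fraction (28% macrophage + 12% lymphocyte). The 27-month complete
  sample draws latent times as t_max · Beta(1, 1.4) to thin its
  post-meiotic tail; all other samples use Beta(1, 1) = Uniform(0, t_max).
* **Expression**: each germ cell at latent time t expresses Gaussian-bump
  programs (width 0.15 latent-time units): stage markers ddx4, sycp3,
  ccnb3, tssk6 peaking at 0.05 / 0.35 / 0.65 / 0.95, plus 56 filler genes
  with peaks tiling [0, 1] — the fillers are what makes latent time
  recoverable from expression. Somatic compartments express constant
  programs around their markers; ~120 housekeeping genes give every cell a
  baseline (400 genes total, including 10 mt- genes). In incomplete
  samples the oogenesis/pluripotency genes zp3.2, nanos3, nanog and pou5f3
  gain a constant weight in germ cells, emulating the aberrant
  transcriptional state of aged spermatogonia.
* **Noise**: per-cell library sizes are log-normal (meanlog log 5000,
  sdlog 0.3); counts are negative binomial with a shared dispersion of 0.3
  (variance μ + 0.3 μ²) around the library-size-scaled profile, then
  thinned by 10% Bernoulli dropout. Healthy cells draw their mitochondrial
  fraction from Beta(2, 150) (mean ≈ 1.3%, far below the 5% cutoff); 5% of
  cells are injected as low quality, half with mito fractions in
  (0.10, 0.30) and half with ~100-count libraries that cannot detect 200
  genes, so the QC filter has true positives with known labels.
* **Allocation**: compartment counts use largest-remainder apportionment
  of the design weights rather than a multinomial draw, so realized
  proportions match the design to within one cell at any sample size;
  everything downstream of the allocation is stochastic under the spec
  seed, and a fixed seed reproduces matrices byte-identically.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: doublets, ambient RNA, batch effects
beyond library-size variation, gene–gene correlation beyond the shared
programs, realistic gene counts (400 vs ~25,000), branching lineages, or
the possibility that truncation in real tissue is gradual rather than a
hard cutoff. Recovery results on this generator show the pipeline's logic
is sound, not that it is robust to every artefact of real scRNA-seq.

## Problem sizes and runtime choices

The test-suite and acceptance computations run on deliberately desk-scale
objects: 2,000-cell germ continua for score recovery and root-swap
antisymmetry, a 2,000 + 2,000 complete/incomplete pair for truncation
recovery, 5,000-cell samples for composition and typing recovery, 600–
1,000 cells per sample for full-pipeline determinism runs, and random
graphs of up to 500 nodes for the BFS-equivalence checks. These sizes keep
a full check run in the low minutes on one CPU while leaving every
statistic far from its decision boundary.

## Known limitations

* The flood's visitation quorum (default 2) can strand cells on very
  sparse graphs (tree-like regions), where the quorum can never be met;
  such cells are flagged and pinned, and the kNN graphs the pipeline
  builds (k = √n) are dense enough that this is a non-issue in practice.
* Marker-based typing is only as good as the panel; a cluster of a type
  with no expressed marker is "unknown", and within a germ-only object the
  z-scoring can name a late segment after a marker whose absolute
  expression is low (the alignment uses that call only to pick the matched
  cell set, for which it is adequate).
* The score D is ordinal, not a physical time: equal increments of D do
  not correspond to equal developmental durations, and D's mapping onto
  latent time is monotone but not linear.
* Exchanging the forward and reverse root definitions flips the score
  (D ↦ 1 − D) only approximately; the residual is bounded in the tests but
  nonzero because root clusters differ in size and position.
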