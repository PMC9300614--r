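---
title: "Methods: accessibility scoring, enhancer linking and pseudotime trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accessibility scoring, enhancer linking and pseudotime trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`epilink` re-implements, as a reusable and tested pipeline, the
computational stages of a single-cell multiome (snATAC-seq + scRNA-seq)
analysis of developing forebrain tissue: barcode quality control,
promoter-accessibility (PA) and gene-activity (GAS) scoring, differential
accessibility (DA) with cross-cluster overlap profiling,
co-accessibility-based TSS-to-cis-regulatory-element (cRE) linking,
two-route enhancer prediction with H3K27ac validation, and
pseudotime-binned trend analysis. Upstream processing (read alignment,
peak calling, embedding, batch correction, pseudotime graph learning,
label transfer, motif analysis) is out of scope: the pipeline starts from
cell-by-peak and cell-by-gene count matrices, a gene annotation, cluster
and pseudotime labels, and (optionally) histone peak sets.

Coordinates are 0-based half-open on disk (BED convention) and converted
to `GRanges` at the I/O boundary — that conversion lives in exactly two
functions (`granges0`, `granges_to_bed`). Chromosome names are compared
as exact strings; any cross-input mismatch is reported rather than
silently normalised.

# The synthetic study

Real datasets at atlas scale are not reproducible on a desk, so every
claim the test suite makes is a *recovery* claim against a generator with
planted ground truth (`simulation_design()`, `simulate_multiome()`). The
default design is the study condition for all tests and for
`scripts/acceptance.R`:

* **Populations.** 4 regions (MGE, LGE, CGE, CTX) × 3 maturation states
  (AP → BP → N) × 150 cells = 1800 cells; 200 genes on 5 chromosomes of
  60 Mb; ~1100–1200 peaks (per gene: a promoter peak spanning the 2 kb
  upstream window plus the TSS base, a first-exon peak, 0–3 intergenic
  enhancers within 10–200 kb of the TSS; plus 400 background peaks).
  Genes sit > 1 Mb apart so cross-gene peak pairs always exceed the
  500 kb co-accessibility window — planted links are the only
  promoter–enhancer structure within reach.
* **Programs.** Each gene draws a region scope (one region or all four)
  and a temporal profile over the states. Profile weights plant
  progressively more repression along maturation (genes switching on at
  BP outnumber those switching off ~1.4×; at N they are outnumbered
  ~3.8×), which is what the activation:decommission ratio analysis
  measures. The fully flat profile (all states × all regions) is absent:
  a globally invariant gene is constant under metacell binarisation and
  informs no statistic under test. Activity is *graded*: each active
  (gene, region, state) has a level u ~ U(0.3, 1) scaling both the RNA
  rate and the accessibility rate.
* **Counts.** Per cell, a LogNormal(0, 0.4) depth factor multiplies
  Poisson rates: accessible elements 0.5·u per cell-depth, inaccessible
  0.002, ubiquitous background peaks 0.1; expressed genes 5·u, silent
  0.05. Overdispersion is deliberately omitted (a dispersion hook exists
  but is unimplemented): the statistics under test are ranks, thresholds
  and binarisations, for which Poisson-given-depth suffices; what pure
  Poisson does *not* emulate is the extra variance of real libraries, so
  passing tests bound behaviour under idealised noise, not real-data
  power.
* **Chromatin before RNA.** Promoter and enhancer accessibility follow
  the expression program shifted one state *earlier*
  (`rna_lag = 1`): an element is open wherever its gene is expressed now
  or in the next state. First-exon accessibility is transcription-coupled
  and therefore synchronous with expression. 30% of genes get
  CpG-island-like constitutively accessible promoters (fixed moderate
  rate everywhere). These three mechanisms — graded levels, a
  synchronous gene-body component, and uninformative constitutive
  promoters — are the real-data reasons a multi-element gene activity
  score outperforms a promoter-only score, and they are what makes that
  comparison meaningful on synthetic data.
* **Planted artefacts.** 5% outlier barcodes with 6–12× depth; per-region
  histone sets (H3K4me3 at active promoters, H3K27me3 at silent ones,
  H3K27ac at enhancers of active genes with a 10% false-negative rate);
  a "dense" region (MGE) whose genes carry 3× enhancers, for the
  per-region link-count ordering. Pseudotime is emitted (state rank +
  U(0,1) jitter), not inferred — trajectory inference is out of scope.
* **Ground-truth trend sets.** The planted "early" set holds profiles
  falling in both modalities ({AP}, {AP,BP}); "late" holds only {N}.
  With the one-state lag, a {BP,N} gene is accessible in *all* states, so
  its accessibility trajectory is flat — it is not a coherent late
  program and belongs to neither set.

Everything is a deterministic function of (design, seed); the dataset
writer emits a manifest so a rerun reproduces every file byte for byte.

# Quality control

`tukey_fences()` implements the far-out fence
\[Q1 − k(Q3 − Q1), Q3 + k(Q3 − Q1)\] with k = 3. Quartiles use linear
interpolation (R `quantile` type 7) by default — the underlying
quantile convention is not canonical, so the type is a recorded,
configurable parameter. `filter_barcodes()` computes fences once per
metric on the full input (a single pass, never iterated) and removes a
barcode when *any* screened metric lies strictly outside its fences;
boundary values survive. `range_filter()` is the alternative fixed-range
rule (log10 total counts in \[3, 6\], promoter read fraction in
\[0.05, 0.6\]); its defaults describe genome-wide libraries — a
restricted peak panel like the synthetic study has smaller totals, which
is why the recovery tests exercise the fence filter.

# Scoring

Promoter windows are strand-aware: \[tss − 2000, tss) on "+",
\[tss, tss + 2000) on "−", clamped at the chromosome start. PA sums
counts over peaks overlapping the window by ≥ 1 bp; counts-level data
cannot localise fragments inside a peak, so there is no proportional
splitting, and a peak overlapping two genes' windows contributes to
both. The package's default PA is the 2 kb-upstream definition; a
`gene_body_plus_promoter` mode implements the broader variant. GAS sums
the *union* of peaks overlapping promoter window, first exon and
assigned enhancers — a peak spanning several components counts once per
gene. Union semantics are a pinned choice where conventions differ; the
per-peak-membership oracle in the tests is what the choice is checked
against.

# Differential accessibility

`lr_test_peak()` fits logistic models
`in-cluster ~ 1 + signal + log(total counts)` against
`in-cluster ~ 1 + log(total counts)` and refers twice the log-likelihood
gap to χ²(1). Signal is log1p of median-depth-normalised counts.
Non-convergent or separating fits are refit with an L2 penalty of 1e-4
on the slopes via a deterministic Newton solver and flagged; the
statistic then uses the unpenalised likelihood at the stabilised
estimates, keeping it finite and nonnegative. `find_da_peaks()` screens
peaks at `max(pct_in, pct_out) ≥ 0.2`, adjusts per cluster by
Benjamini–Hochberg (BH matches the stated FDR criterion; the historical
tool default of Bonferroni does not), and calls DA at adjusted p ≤ 0.05
with positive average log fold change.

The overlap matrix counts a DA peak of cluster c as "detectable" in
cluster d when d's *pooled* count at that peak is positive — no minimum
threshold, and pooled-per-cluster semantics are the plain reading of
"reads … in another cluster". Profiles are clustered with correlation
distance and average linkage; a zero-variance profile has no defined
correlation and receives the maximal distance 2, keeping the matrix
complete and the tree deterministic.

# Co-accessibility and gene–peak prediction

The co-accessibility estimator is a declared stand-in for published
graphical-lasso estimators (whose internals are out of scope): cells are
pooled into metacells of 50 by pseudotime order within each
(region, state) group (remainders merge into the last metacell), pooled
counts are binarised, and a peak pair's score is the Pearson correlation
of those binary profiles across metacells, computed for same-chromosome
pairs whose midpoints lie within 500 kb. Peaks constant across metacells
are excluded (no defined correlation). Externally computed link tables
with the same columns can be substituted everywhere a link table is
consumed, so the filtering/classification logic also post-processes real
tool output.

Links are retained at score ≥ 0.25 (inclusive — where sources disagree
between "equal to or greater" and "greater", the inclusive reading is
the default and the threshold is a parameter). A retained link becomes a
TSS–cRE connection when exactly one anchor overlaps a gene TSS (the TSS
point; a slop parameter exists, default 0) and the other anchor overlaps
no promoter window of any gene; an anchor on two TSSs yields two
connections. Per-group link counting downsamples each group to the
smallest group's size (seeded, without replacement) and *recomputes* the
estimator within the group — the conservative reading when it is unclear
whether counting should re-estimate or subset.

The model route (`predict_gene_peak_pairs()`) tests, for every gene
whose TSS-overlapping peak has nonzero total count, each non-promoter
peak within a 500 kb window centred on the TSS (±250 kb): logistic
`P(peak > 0) ~ 1 + normalised expression` vs the intercept-only null,
BH-adjusted genome-wide, retained at FDR ≤ 0.05.

# Enhancer integration

Per-gene percentile ranks use average ties over n; infinite inputs
(−log10 of an adjusted p of zero) are replaced by twice the greatest
finite value of the whole score table before ranking — the global cap is
the default (the singular "greatest value" reads as global), with a
per-gene variant available. Ranks are carried as annotations; no rank
cutoff is applied by default because none is canonical. cRE intervals of
each route are extended ±500 bp and merged (bookended intervals merge:
at that scale adjacency is overlap); `union` mode concatenates and
re-merges with provenance tracking, `intersect` mode keeps the base-pair
intersection (provenance "both"), and the high-confidence list is the
intersection filtered to candidates overlapping (≥ 1 bp) the union of
the supplied H3K27ac sets.

The per-region validation reports three Venn-style comparisons:
promoter ATAC peaks vs promoter H3K4me3; non-promoter ATAC peaks vs
non-promoter H3K27ac; and the TSS-linked subset of non-promoter ATAC
peaks vs the same H3K27ac set. The third A-set is a subset of the
second's by construction, and on data where enhancers carry the mark its
percentage is strictly higher — the directional claim the tests assert.

# Pseudotime trends

Cells are split into 10 equal-width bins over the observed pseudotime
range (left-closed; the last right edge inclusive). Per gene the bin
means are centred and scaled with the *sample* standard deviation
(divisor n − 1, the `scale()` convention, matching the worked z values
in the contract; the population variant is available). An empty bin is
filled by linear interpolation from neighbouring bins and flagged; a
constant trajectory becomes all zeros and is flagged.

Trend grouping concatenates each gene's RNA, GAS and enhancer z-vectors
and clusters them with correlation distance and average linkage — the
joint-concatenation reading, which matches how the matched heatmaps
share one dendrogram; a per-modality mode exists but is unvalidated. The
reference tool's internal cutting heuristics are not replicated: the cut
height k ∈ 2..8 is chosen by maximal mean silhouette with deterministic
ties to the smallest k, groups under 6 genes are discarded to "other",
and each retained group is labeled early / late / transition by whether
its mean z falls or rises by more than 0.5 between the first and last
bin — a documented, deterministic substitute filling the same analytic
role.

State-transition DEGs reuse the same LR test on expression, one-vs-one
between states, with log RNA depth as covariate, BH across genes, and a
fold-change floor of 0.25 (the standard marker-detection default):
per-cell scaling induces small spurious shifts in silent genes when two
states express different numbers of genes, and the floor excludes that
composition artefact before testing. Enhancer tallies count distinct
intervals; an enhancer linked to both an up- and a down-regulated gene
counts in both tallies; a zero decommission count yields an infinite
ratio, flagged rather than dropped.

# Problem sizes and determinism

The default simulation (1800 cells, ~1170 peaks, 200 genes) runs each
full pipeline stage in seconds on one CPU; the test suite and the
acceptance script use 10 replicate seeds for averaged recovery
statistics and 2000 features for the null-calibration check. All
randomness flows from explicit seeds; reruns are byte-identical,
including every file the dataset writer emits.

# Known limitations

* Pure Poisson counts (no overdispersion, no doublets, no batch
  effects) — recovery rates here are upper bounds on real-data
  behaviour.
* The co-accessibility stand-in measures marginal binary correlation,
  not the partial correlations of graphical-lasso estimators; scores
  agree in ranking, not in value, with such tools.
* One transcript model per gene: "first exon" means the supplied
  `exon1`; multi-isoform genes are out of scope.
* Pseudotime is an input; no trajectory inference is performed.
* The enhancer lists carry per-gene ranks but apply no rank threshold;
  downstream users decide.
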