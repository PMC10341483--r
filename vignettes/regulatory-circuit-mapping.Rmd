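---
title: "Mapping regulatory circuits from expression and promoter acetylation counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping regulatory circuits from expression and promoter acetylation counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`regucircuit` implements a desk-scale version of a common integrative design
in neuro-epigenomics: RNA-seq and H3K27ac ChIP-seq counts from a disease
model and its control, at two ages, are reduced to (i) differentially
expressed genes, (ii) differentially acetylated promoter windows and
CRE (cAMP response element) regions, (iii) condition-specific gene regulatory
networks, and (iv) a validated set of master regulators (MRs) sitting atop
the disturbed transcriptional cascade. Every stage is an exported function;
the numbered scripts under `analysis/` chain them on synthetic data with
planted structure, and the same functions accept real count tables, GTF/BED
annotations and edge lists.

### Count model

Read counts for a feature (gene, 2001-bp promoter window, or CRE region) are
modelled as negative binomial,

$$K_{ij} \sim \mathrm{NB}(\mu_{ij},\, \alpha_i), \qquad
  \mu_{ij} = s_j \exp(x_j^\top \beta_i), \qquad
  \mathrm{Var}(K_{ij}) = \mu_{ij} + \alpha_i \mu_{ij}^2,$$

with median-of-ratios size factors $s_j$ (geometric-mean reference over
features with all-positive counts), a log-linear design $x_j$ of condition
(single-factor) or condition + time (two-factor), and a Wald test of the
mutant-vs-control coefficient. Benjamini–Hochberg adjustment is applied
across tested features. Expression analyses call significance on adjusted
p < 0.05 by default; acetylation analyses on raw p < 0.05, the convention
for that assay — both are one switch in `diff_config()`.

### Dispersion estimation

Per-feature dispersions are method-of-moments estimates on normalized
counts pooled within design cells,
$\hat\alpha_i = (s_i^2 - \bar{\xi}\,\bar\mu_i)/\bar\mu_i^2$ with
$\bar\xi = \mathrm{mean}(1/s_j)$, floored at `min_dispersion` ($10^{-8}$).
With three replicates per group a purely per-feature estimate has about four
degrees of freedom, and plugging it into a normal-reference Wald test
inflates the type-I error well above nominal (we measured ≈ 0.12 at a
nominal 0.05 in the 3-vs-3 design), while switching to a $t_4$ reference
restores calibration but costs most of the power against four-fold planted
effects. The package therefore moderates: each feature's dispersion is
additionally floored at the across-feature **median** of the raw moment
estimates (`common_floor = TRUE`). This is a shrinkage toward a single
common dispersion — deliberately *not* a fitted mean–dispersion trend — and
it restores both properties in the regime the tests check (null rejection
≈ 0.05, sensitivity ≈ 0.88 at BH 0.05 on four-fold effects). The cost is
conservatism for features whose true dispersion is far below the data-wide
median; for data with strongly mean-dependent dispersion a trend-based
method (as in the DESeq2/edgeR family) remains the better tool, and the
flag turns the floor off.

Features with all-zero counts are never tested (reported `ns`, p = 1). When
a group mean is zero the reported `log2fc` falls back to a 0.5 pseudo-count
ratio of normalized means; the test itself always uses the GLM.

### Intervals, promoters, CRE assignment

All internal coordinates are 0-based half-open (BED convention); GTF I/O
converts at the boundary (1-based closed). The promoter window spans 1000 bp
on each side of the strand-aware TSS *including* the TSS base, hence 2001 bp,
clipped only at position 0 unless chromosome sizes are supplied. Peak-set
intersection follows `bedtools intersect -u` report-A semantics by default
(each A interval reported once if any B overlap reaches `min_overlap`, default
1 bp); `fragments = TRUE` gives the overlap fragments instead, since the
convention used upstream is rarely recorded.

A motif occurrence is assigned to **every** gene whose TSS lies within
±3 kb of the motif midpoint — regions can plausibly regulate more than one
promoter, and a `nearest_only` switch covers the stricter reading. Distance
is unsigned; the motif's strand is carried but never used. Differentially
acetylated regions are classified by their midpoint with precedence
promoter > gene body > downstream (1 kb past the strand-aware 3' end) >
intergenic, which makes the location categories disjoint even for regions
straddling several features; ties go to the nearest TSS, then lexicographic
gene id.

### Networks and master regulators

The general network is the union of edge-list databases; duplicate edges are
merged (conflicting activation/repression modes collapse to `unknown`).
Contextualization keeps an edge iff its source TF is *expressed*, defined as
mean normalized count ≥ 10 in the relevant condition's samples — the cutoff
is a parameter because published analyses rarely state theirs — and the node
set becomes the endpoints of surviving edges. Targets are kept regardless of
their own expression; only the TF filter is applied.

MR inference walks two steps upstream of the DE genes (reverse edges),
induces the subgraph on the collected nodes, and prunes the largest weakly
connected component: repeatedly delete the node with minimal out-degree
(ties: minimal in-degree, then lexicographic id), stopping *before* any
deletion that would disconnect the remainder or shrink it below
`min_core_size` (default 2, preventing degenerate single-node cores). The
stop test is evaluated before committing, so the disconnecting deletion is
never applied and the trace plus survivors always partition the component.
Weak connectivity is used because direction-blind "connectedness" is the
natural reading of an unconnected regulatory map.

Pruning alone does not isolate a mutually regulating clique: once only the
clique remains, every further deletion keeps the remainder connected, so the
rule would erode it to the guard size. What stops the erosion in practice is
the periphery — the first deletion that would orphan a pendant regulator
halts the process with the dense core intact. The definitive filter is
validation: a surviving candidate (restricted to TFs of the supplied
network) is a master regulator iff it is regulated by another candidate
**and** physically interacts with one (`rule = "both"`). The AND is chosen
because a physically interacting pair that does not regulate each other
should *not* validate; `either` and `regulation_only` are provided. The
control/mutant contrast is set algebra on the validated sets.

## The synthetic study

`sim_config()` defaults are the study conditions, fixed once: 220 genes
(20 TFs) on two 3-Mb chromosomes; a 2 (genotype) × 2 (time) design with
3 replicates per cell, matching the triplicate two-age design such studies
use; lognormal baseline means (log-mean log 100, log-sd 1), NB dispersion
0.1, lognormal(0, 0.2) library-size multipliers; 10% of genes carry a ±2
log2 genotype effect and 10% of promoters/CRE regions a ±1.5 log2
acetylation effect, full-sized at 6 weeks and halved at 4 weeks (the
early/late asymmetry is qualitative, not a fitted value); 20% of genes get a
+1 log2 time effect. The regulatory truth is a six-TF core with all 30
mutual edges (`core_density = 1`), 20 peripheral targets per core TF,
physical interactions between all core pairs, three planted DE targets per
core member so the upstream neighborhood always contains the core, a few
pendant "blocker" regulators wired only into planted DE genes (these
guarantee the pruning stops during the periphery phase, before the core
erodes), and peripheral TFs of out-degree ≤ 3. TF baselines are floored at
40 so regulator expression state is stable across replicates; two peripheral
TFs are silenced to exercise the expression filter, and the
`mutant_only_mr` switch silences one core TF in control samples only,
planting a disease-specific master regulator.

What the generator does *not* emulate: read-level noise and alignment
artifacts, peak shapes, mean-dependent dispersion trends, correlated genes,
GC/length biases, and genome-scale network sparsity. Passing tests therefore
demonstrate the correctness and calibration of the statistical and graph
machinery under the stated model, not performance on real sequencing data.

## Numerical choices and degenerate inputs

Problem sizes were chosen so the whole suite runs in minutes on one core:
2000 features for calibration/power checks, 100 seeded pipeline runs for
planted-core recovery, 100 random instances per brute-force-oracle
comparison. Size factors require at least one feature with positive counts
in every sample and error otherwise rather than silently switching
reference. GLM fits run on explicit model matrices with the dispersion fixed
at its estimate and covariance from the final IRLS decomposition; fits that
fail or lose rank report `NA` effects and p = 1 with the pseudo-count
fold change. Deterministic tie-breaks (lexicographic ids everywhere a choice
is arbitrary) make every pipeline output, including the deletion trace,
byte-identical across reruns of one seed.

## Known limitations

The dispersion model is exchangeable across features (no mean–dispersion
trend, no outlier re-estimation); single-replicate groups are rejected
rather than approximated; promoter windows are per-gene, not per-transcript,
and alternative TSSs are out of scope; the ±3 kb CRE rule is symmetric and
midpoint-based; network contextualization is a hard expression threshold,
not a probabilistic activity model; and MR validation depends on the
completeness of the supplied physical-interaction list — an MR without
curated interactions cannot validate under the default rule.
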