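---
title: "Methods: spatial analysis of plaque-associated microglia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial analysis of plaque-associated microglia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquemap)
```

`plaquemap` analyses imaging-based spatial transcriptomics of microglia
around amyloid plaques: per-cell panel counts with centroids and
segmented volumes, plaque outlines recorded as four perimeter points,
and a manually traced region (cortex) polygon. This vignette documents
the statistical procedures, the choices behind them, and what the
simulation used for validation does and does not emulate.

## QC and normalization

Cells pass four filters and three transforms, in a fixed order that
mirrors how such data are processed in practice:

1. **Transcript/volume filter.** Cells with fewer than 40 total
   molecules or a volume below 100 µm³ are removed. Both thresholds are
   strict (`<`), so a cell at exactly 40 molecules or exactly 100 µm³
   is retained.
2. **Sample depth equalization.** Global differences in molecule counts
   between samples are removed by scaling every cell of sample $s$ by
   $\bar{T} / \bar{T}_s$, the grand mean of per-cell totals over the
   mean total of that sample. The exact form of this step is a design
   choice: equalizing per-sample means against the grand mean is the
   simplest transform that removes between-sample count differences
   while leaving the overall scale intact, and the factors are reported
   in the QC output so any alternative convention can be recovered.
3. **Volume normalization.** Each cell's values are divided by its
   volume, giving counts per µm³ — cell size in imaging data is a
   technical covariate of segmentation, not biology.
4. **Unique-gene filter.** Cells detecting fewer than 11 genes (strict)
   are removed. Positivity is unchanged by steps 2–3, so the outcome is
   identical whichever layer the filter runs on; the tests assert this.
5. **Log normalization.** $x_{cg} = \ln\!\big(1 + 10^4\, v_{cg} /
   \sum_g v_{cg}\big)$. The invariant $\sum_g (e^{x_{cg}}-1) = 10^4$
   holds exactly for every retained cell and is verified to $10^{-6}$
   relative tolerance. Natural log is used, matching the convention of
   the standard single-cell toolchains; the layer tag records it.

Non-finite values anywhere are a hard error — no silent coercion.

## Plaque geometry and proximity

A plaque outline is the closed quadrilateral through its four recorded
perimeter points. Because the points carry no ordering, they are sorted
counter-clockwise by angle about their centroid, which for four points
always yields a simple polygon; collinear or duplicated points are
rejected. The distance from a cell centroid to a plaque is 0 if the
centroid lies on or inside the boundary, otherwise the minimum
Euclidean distance to the four boundary segments — segments, not just
the four vertices, since the recorded points stand for a closed
outline. (Vertex-only distances can be obtained by degenerating the
quadrilateral, but the segment convention is the default and the one
validated against a brute-force boundary-sampling oracle to $10^{-3}$
µm.)

Cells inside the region polygon (boundary inclusive, even–odd rule) are
classified by distance to the *nearest* plaque: `plaque_associated`
when $d \le 15$ µm, `distal` when $d > 15$ µm. The boundary case
$d = 15$ is assigned to the associated class; it has measure zero in
real data but is fixed for determinism. Ties between plaques go to the
smaller plaque id. Cells outside the region are excluded from
classification and from downstream group comparisons. The 15 µm cutoff
reflects nucleus-based distances that allow for the soma and processes
of a microglia; a 5 µm process-contact analogue is available as
`cutoff_um = 5` on the same centroid geometry — true process-surface
geometry is out of scope. Distal density is reported per µm² of region
area minus total plaque area, the areal analogue of normalizing distal
counts to tissue volume minus plaque volume; the output records the
dimension.

## Rank-sum marker detection

For two cell groups on the log-normalized layer, each gene is
summarized by the expressing fraction per group and the fold change
$\log_2\!\big[(\overline{e^{x}-1}_1 + 1)/(\overline{e^{x}-1}_2 +
1)\big]$ — de-logged means with pseudocount 1, consistent with the
$10^4$-scaled layer and the conventional 0.25 threshold scale. Genes
with $\max(\mathrm{pct}_1, \mathrm{pct}_2) \ge 0.01$ and
$|\log_2\mathrm{FC}| \ge 0.25$ are tested with the Wilcoxon rank-sum
test and adjusted over the tested set (Benjamini–Hochberg by default,
Bonferroni on request); the tested-gene count is recorded so the
adjustment denominator is explicit. Filtering before testing matches
the behaviour of the widely used marker-detection functions this
interface mirrors.

The test itself uses midranks for ties. For tie-free samples with
$n_1 + n_2 \le 12$ the two-sided p-value comes from the exact
Mann–Whitney null distribution ($2\min\{P(U \le u), P(U \ge u)\}$,
capped at 1); otherwise a normal approximation with tie-corrected
variance and continuity correction is used. The exact path is verified
against exhaustive enumeration of all assignments; the approximate path
against the reference implementation in base R.

## Module scores and cluster categories

A signature score is the classic control-gene construction: genes are
binned into 24 equal-frequency bins by mean expression across cells;
each signature gene contributes 100 control genes drawn from the
non-signature genes of its bin (without replacement when the bin
suffices, with replacement otherwise — logged); the per-cell score is
the mean expression of signature genes minus the mean over the pooled
control draws. On panel-sized matrices a signature can dominate its own
expression bins; excluding signature genes from control pools, with a
fallback to the nearest non-signature genes by expression rank, keeps
the controls meaningful at panel scale. Scores are seed-reproducible
and invariant to adding a constant to the matrix.

Clusters are categorized DAM when their mean DAM score exceeds their
mean homeostatic score, with exact ties going to homeostatic. The
mean-score *difference* is the decision statistic because module scores
can be negative, making a literal score ratio ill-defined; the ratio is
still reported for inspection. DAM clusters split lymphoid-positive
when the mean lymphoid score exceeds 0 — a threshold choice, since only
"levels of lymphoid-related expression" distinguish the subsets.
Bundled signatures: lymphoid (9 genes), interferon (15 unique genes;
the published list repeats *Isg15*, stored once), DAM (*Cst7*, *Apoe*,
*Lpl*, *Itgax*) and homeostatic (*Cx3cr1*, *Tmem119*, *P2ry12*,
*Csf1r*, *Hexb*, *Sall1*, *Selplg*); all are overridable, and in situ
dot-count positivity uses the presets ≥ 5 dots (*Cd28*) and ≥ 3 dots
(*Mx1*).

## PU.1 intensity states

Nuclei are classified from mean nuclear intensity with cutoffs
$m / f$ and $m \cdot f$: $m$ is the mean intensity over all nuclei of
an experiment (computed per `sample_id` by default, since staining
intensity is batch-scaled and the calibration is per-experiment), and
$f$ is the fold change between reference populations — the mean signal
of PU.1-high reference nuclei over PU.1-low reference nuclei, stored as
the calibration constant 1.25 so classification runs without reference
data; `reference_fold_change()` recomputes it when references exist.
Values strictly below $m/f$ are `low`, strictly above $m f$ are `high`,
and everything between the cutoffs — including values exactly at a
cutoff — is `medium`. Classification is invariant to joint rescaling of
intensities, and widening $f$ only grows the medium class.

## What the simulator emulates

`simulation_config()` defines a seeded scene designed to look like a
cortical field of an aged amyloid-model mouse:

- **Geometry.** A 1,000 × 1,000 µm region with 40 plaques (dense
  plaque load typical of aged 5xFAD cortex), each built from four
  perimeter points at jittered right angles, 10–20 µm from the centre.
  8,000 microglia are placed uniformly.
- **States.** Marginal fractions 0.70 / 0.20 / 0.10 for homeostatic /
  DAM / lymphoid-DAM. Within 15 µm of a plaque edge the odds of both
  disease states are multiplied by `proximity_enrichment` (default 5).
  The logistic-odds form of this enrichment is a modelling choice; the
  true distance dependence of state composition is unknown.
- **Counts.** Gamma–Poisson with a shared dispersion (size 5,
  near-Poisson, reflecting imaging-based molecule counting rather than
  sequencing noise). Per-gene baselines are lognormal across genes
  (`baseline_sdlog = 0.5`, geometric mean 2.5 counts/cell), because
  real panels span expression levels — this is what makes
  expression-matched control binning meaningful. Homeostatic cells
  elevate the homeostatic program 2-fold; DAM cells the DAM program
  8-fold; lymphoid-DAM cells both the DAM and lymphoid programs 8-fold,
  matching the strong induction of disease markers. A panel of
  `n_genes` (default 100, up to the 398-gene scale of real panels)
  always contains the bundled signatures.
- **Samples and QC failures.** Two samples with depth factors 1 and
  1.3 exercise depth equalization. QC-failing cells are injected with
  known ids — totals drawn in 15–39, volumes in 20–99 µm³, or exactly
  10 detected genes — so filter tests have exact expected survivors,
  rather than relying on emergent failures.
- **Intensities.** A trimodal lognormal mixture parameterised by the
  calibration factor $f = 1.25$: component means $m/f^2$, $m$,
  $m f^2$ (64, 100, 156.25), so the classifier cutoffs $m/f$ and
  $m f$ fall at the geometric midpoint between adjacent components,
  each outer component sitting one full fold-change step beyond its own
  cutoff; $\sigma_{\log} = 0.08$ keeps cross-cutoff leakage well below
  sampling noise at the scales tested; weights 0.2 / 0.6 / 0.2. By
  default each nucleus draws from the component of its state
  (lymphoid-DAM → low, echoing the reduced PU.1 of the lymphoid subset;
  homeostatic → medium; DAM → high); `intensity_link = "mixture"`
  instead draws components from the weights, which is the configuration
  used when checking that classified proportions recover known weights.

One master seed derives independent stage seeds (plaques, placement,
states, counts, intensities), so each stage is reproducible in
isolation and identical configurations are byte-identical end to end.

## What passing tests do and do not show

The simulator captures the statistical skeleton the methods rely on —
count overdispersion, volume variation, proximity-dependent
composition, program structure, batch depth and staining scale — but
not segmentation errors, optical crowding, hybrid cells at boundaries,
spatial autocorrelation within states, 3-D geometry, or plaque shapes
more complex than quadrilaterals. Recovery of truth here validates the
implementation, not the biology of any particular dataset.

Validation scales were chosen to finish in minutes on one core: the
geometry oracle uses 1,000 random point–plaque pairs against $10^5$
boundary samples; null calibration pools ten 2,000-cell, 100-gene
datasets; effect recovery uses twenty seeds of 1,000 cells at the full
398-gene panel with a 10-gene program (at a 100-gene panel a 10-gene
4-fold program shifts per-cell totals enough that the compositional
bias of any relative-abundance fold change approaches the assessment
band — a limitation of small panels worth remembering, not of the
estimator); the lymphoid-contrast check uses twenty seeds at the
default scene; intensity recovery uses 5,000 nuclei.

## Numerical conventions

Distances are exact segment projections, no grids. Boundary points
count as inside polygons. Proximity at exactly the cutoff is
plaque-associated; intensity exactly at a cutoff is medium; DAM/
homeostatic score ties are homeostatic. P-values of exactly degenerate
rank-sum comparisons (zero variance) are 1. QC thresholds are strict
inequalities on the failing side. All thresholds are arguments with the
defaults above; the pipeline serializes the resolved configuration into
its report, and timing information is kept out of the report so that
identical runs are byte-identical.
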