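# plaquemap

Spatial analysis of amyloid-plaque-associated microglia from
MERFISH-style imaging data.

In mouse models of amyloid pathology, microglia reorganize around
plaques and shift from a homeostatic program (*Cx3cr1*, *P2ry12*,
*Tmem119*, *Hexb*) to disease-associated (DAM) states (*Cst7*, *Apoe*,
*Lpl*, *Itgax*), including a PU.1-low subset that expresses lymphoid
immunoregulatory genes (*Cd28*, *Cd274*, *Pdcd1*, ...). Imaging-based
spatial transcriptomics yields, per cell, panel transcript counts, a
centroid (µm) and a segmented volume (µm³); plaques are outlined by four
manually recorded perimeter points, and the cortex by a traced polygon.
`plaquemap` implements the analysis cascade this kind of experiment
needs, for R users working at the interface of spatial transcriptomics
and neuroimmunology:

- **QC and normalization** — remove cells with fewer than 40 transcripts
  or volume below 100 µm³, equalize per-sample depth, divide by cell
  volume (counts/µm³), drop cells detecting fewer than 11 unique genes,
  then log-normalize: `x = ln(1 + 10^4 · v_g / Σ_g v_g)` per cell.
- **Proximity classification** — distance from each microglial centroid
  to the nearest plaque *edge* (the quadrilateral through its four
  perimeter points); cells within the cortex polygon are
  `plaque_associated` when `d ≤ 15 µm`, `distal` otherwise. Per-plaque
  cell counts and a distal density normalized to cortex area minus
  total plaque area.
- **Differential expression** — two-sided Wilcoxon rank-sum per gene
  (exact on small tie-free samples, tie-corrected normal approximation
  with continuity correction otherwise), with expressing-fraction
  (`min.pct = 0.01`) and fold-change (`|log2FC| ≥ 0.25`) pre-filters and
  Benjamini–Hochberg (or Bonferroni) adjustment.
- **Module scoring** — per-cell signature scores as mean expression of
  the signature genes minus expression-bin-matched control genes, with
  bundled lymphoid / interferon / DAM / homeostatic sets; cluster
  categorization into homeostatic vs DAM and lymphoid⁺ vs lymphoid⁻.
- **PU.1 intensity states** — nuclei classified low / medium / high
  from mean nuclear intensity with cutoffs `m / f` and `m · f`, where
  `m` is the per-experiment population mean and `f = 1.25` is the
  reference fold change (PU.1-high over PU.1-low reference nuclei).
- **Simulation** — a seeded generator of MERFISH-like datasets
  (negative-binomial program counts, plaque geometry,
  proximity-dependent state composition, lognormal volumes, trimodal
  nuclear intensities) with full ground truth, so the whole cascade is
  testable without imaging data.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` on results, `autoplot()` / `plot_*()` figures, and a
`run_pipeline()` orchestrator plus a thin CLI
(`inst/scripts/plaquemap-cli.R`).

## Worked example

```r
library(plaquemap)

sim <- simulate_dataset(simulation_config(seed = 42, n_cells = 1000,
                                          n_plaques = 12))
qc <- run_qc(sim$counts, sim$cells)
tidy(qc)
#> # A tibble: 2 × 6
#>   stage            n_input n_fail_transcripts n_fail_volume n_fail_genes n_retained
#> 1 filter_cells        1060                 20            21           NA       1019
#> 2 filter_min_genes    1019                 NA            NA           20        999
```

1,060 simulated cells include 60 deliberately QC-failing ones; 999
survive the cascade (a noisy volume draw can fail a regular cell too).
Classify plaque proximity and test for markers of plaque-associated
cells:

```r
prox <- compute_proximity(qc$cells, sim$plaques, sim$region, cutoff_um = 15)
dplyr::count(prox, label)
#>   label                 n
#> 1 distal              983
#> 2 plaque_associated    16

de <- find_markers(qc$lognorm, prox$label, group1 = "plaque_associated")
head(tidy(de), 3)
#>   gene    log2fc  p_value p_adjusted pct_group1 pct_group2
#> 1 Hexb    -1.26  0.000302     0.0190      0.875      0.963
#> 2 Gene034 -1.04  0.00264      0.0736      0.812      0.906
#> 3 Cd72     0.896 0.00350      0.0736      1          0.998
```

With only 16 plaque-associated cells at this small scene size, one gene
clears the 5% FDR: the homeostatic marker *Hexb*, down 2.4-fold in
plaque-associated cells — the expected loss of the homeostatic program
near plaques. PU.1 intensity states, calibrated per sample with the
fold change 1.25:

```r
pu1 <- classify_nuclei(sim$intensities, fold_change = 1.25)
state_proportions(pu1, group_by = "sample_id")
#>   group     n prop_low prop_medium prop_high
#> 1 s1      530    0.132       0.666     0.202
#> 2 s2      530    0.136       0.677     0.187
```

`autoplot(de)` draws the volcano, `autoplot(pu1)` the intensity
histogram with cutoffs, and `plot_proximity_map(qc$cells, sim$plaques,
sim$region, prox)` the tissue map. `run_pipeline(pipeline_config(...),
out_dir)` executes all stages and writes every table plus a
`report.json`.

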