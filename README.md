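# spatialTME

Spatial single-cell analysis of tumor-microenvironment architecture from
multiplexed imaging data.

Multiplexed tissue imaging (imaging mass cytometry and related platforms)
produces, after segmentation, a table of cells: where each cell sits (µm),
which sample/ROI it came from, and the mean intensity of a few dozen protein
markers. `spatialTME` is for analysts who start from that table and want to
answer the questions asked of paired tumor cohorts — here, primary versus
recurrent glioblastoma: *which cell types are present and in what states;
how diverse is each region; which cell types sit next to each other more
often than chance; what recurring local neighborhoods do cells form; and how
are those neighborhoods organized into higher-order tissue contexts?*

## What it computes

- **Phenotyping** — `asinh(raw/cofactor)` transform (cofactor 5), per-marker
  z-scoring (optionally per batch), exclusion of broadly-high artifact
  cells, priority-ordered logical gating into types and four categories
  (immune, cancer, normal brain, vasculature), and binary state calls
  (hypoxia: `z(HIF1A) > 1.2`; EMT: `z(SNAI1) > 1.2`).
- **Diversity** — per-ROI Shannon entropy `H = −Σ pᵢ ln pᵢ` on 1,000
  subsampled cells × 10 iterations; Wilcoxon rank-sum comparisons between
  surgeries (BH-adjusted q per patient); ANOVA-style partition of
  composition variance into patient / surgery / ROI.
- **Spatial graphs** — per-ROI Delaunay triangulation of centroids pruned at
  50 µm.
- **Interaction testing** — for each ordered type pair (A, B), the A→B
  neighbor-link count normalized by the number of A cells with ≥ 1 B
  neighbor (or by all A cells), against a null of 1,000 label shuffles;
  one-sided empirical p-values `(b+1)/(m+1)` (floor `1/1001 ≈ 9.99e−4`),
  calls at P < .01, majority-of-ROIs per patient, and a ≥ 3-patient
  cross-surgery consistency filter (primary-only / recurrent-only / both /
  changed).
- **Cellular neighborhoods** — k-means (k = 12, k-means++, restarts) on
  per-cell neighbor-composition vectors pooled across the cohort; CN
  composition and per-surgery prevalence comparisons.
- **Spatial contexts** — per cell, the minimal CN set reaching 90% of its
  2-hop window; dominant SCs (> 3 patients and > 5% of a surgery's cells,
  strict); the CN co-occurrence network per surgery with degree, closeness
  (component-size corrected) and normalized betweenness.
- **Synthetic cohorts** — a seeded generator emulating the study design
  (5 patients × 2 surgeries × 3 ROIs × ~3,500 cells, 34 markers) as a
  mosaic of cell-type niches, with planted types, states, composition
  shifts and pairwise adjacency enrichment, so every stage is testable
  without external data.

## Worked example

```r
library(spatialTME)

ct <- generateCohort(cohortDesign(n_patients = 5, rois_per_sample = 3,
                                  cells_per_roi = 1000, seed = 1))
ct <- transformIntensities(ct)   # asinh, cofactor 5
ct <- zScoreIntensities(ct)
ct <- excludeBroadlyHigh(ct)
ct <- assignTypes(ct)            # shipped 13-type gating rules
ct <- callStates(ct)

graphs <- buildSpatialGraph(ct, max_dist = 50)
ent    <- subsampledEntropy(ct, entropySpec(1000, 10, seed = 2))
compareEntropy(ent, "cohort")
#>  group n_primary n_recurrent delta_median          p          q
#> cohort       150         150  -0.02431802 0.01980243 0.01980243

res <- testInteractions(ct, graphs, interactionSpec(n_permutations = 1000,
                                                    seed = 3))
agg <- aggregateCalls(res$patient)
agg[agg$typeA == "endothelial", c("typeA", "typeB", "call_primary",
                                  "call_recurrent", "classification")]
#>       typeA       typeB call_primary call_recurrent classification
#> endothelial          AC  interacting             ns    primary-only
#> endothelial   astrocyte  interacting             ns    primary-only
#> endothelial endothelial  interacting    interacting            both
#> endothelial  macrophage  interacting    interacting            both
#> endothelial         MES  interacting    interacting            both
#> endothelial   microglia  interacting             ns    primary-only
#> endothelial      neuron           ns    interacting  recurrent-only
table(agg$classification)
#>           both   primary-only recurrent-only
#>             37             23             21
```

The gating recovers 99.5% of the planted types; the cohort's entropy
median drops at recurrence (p = 0.02 — the generator plants a dominance
gain of normal-brain cells); and the planted endothelial→microglia
coupling surfaces as a primary-only interaction. Because the synthetic
tissue is a mosaic of niches, further focus overlaps produce additional
genuine spatial couplings, as in real tumors — self-interactions
("both" on the diagonal) dominate, exactly as single-cell-resolved
studies report. Continuing into neighborhoods and contexts:

```r
lab <- setNames(cellTypes(ct), colData(ct)$cell_id)
cn  <- fitNeighborhoods(neighborComposition(graphs, lab), k = 12, seed = 4)
cn
#> NeighborhoodModel: k = 12 over 14 types; 30000 labeled cells; inertia 3870.79
#>   dominant types: CN1:oligodendrocyte (52%), CN2:neuron (64%), CN3:AC (68%),
#>   CN4:endothelial (62%), CN5:astrocyte (44%), ..., CN8:astrocyte (82%), ...

ct  <- addCNLabels(ct, cn)
scr <- detectSpatialContexts(ct, graphs, scSpec())
dom <- filterDominantSCs(scr, scSpec())
dom[dom$retained, ]
#>     group      sc n_patients cell_fraction retained
#> recurrent CN5&CN8          5    0.07038655     TRUE

net <- buildCNNetwork(dom, "recurrent", table(colData(ct)$cn))
net@centralities
#>   cn degree closeness betweenness n_cells
#>  CN5      1         1           0    3988
#>  CN8      1         1           0    2712
```

Every CN's dominant type stays below 100% — neighborhoods are admixtures
even when one type predominates — and the one dominant spatial context of
this small cohort pairs the two astrocyte-driven CNs at recurrence, where
the generator inflates astrocytes. `runPipeline(ct, pipelineConfig(seed =
1))` chains all stages and returns a manifest whose hashes are identical
across reruns with the same config and input.

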