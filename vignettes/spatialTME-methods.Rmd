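---
title: "spatialTME: methods and design notes"
author: "spatialTME authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spatialTME: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`spatialTME` implements the post-segmentation half of a spatial single-cell
proteomics study of the tumor microenvironment (TME): it starts from a
per-cell table (identity keys, centroid coordinates in micrometers, raw mean
marker intensities) such as one produced by imaging-mass-cytometry (IMC)
segmentation, and ends with cell phenotypes, diversity statistics,
interaction calls, cellular neighborhoods (CNs), spatial contexts (SCs) and
CN-network centralities. Everything upstream of the cell table — ablation,
image conversion, segmentation — is out of scope, as are transcriptomic
analyses.

Because real cohorts of this kind are small and access-controlled, the
package carries a first-class synthetic-cohort generator with planted ground
truth. All statistical guarantees quoted below are verified by the test
suite on that generator; the section on the generator spells out which
features of real tissue it does and does not emulate, and therefore what a
passing suite does and does not certify about real data.

# Phenotyping

Raw intensities are transformed as `asinh(raw / cofactor)` with cofactor 5,
the standard variance-stabilizing choice for mass-cytometry counts, then
z-scored per marker. Z-scoring can be computed globally or within a batch
column; per-patient standardization (`batch_key = "patient"`) is the
package's lightweight stand-in for cross-patient alignment and is off by
default, since the synthetic generator has no batch structure. The order
"transform, then z-score, then gate" is fixed; both global and per-batch
scaling orders are exposed because published pipelines differ on this
point.

**Artifact exclusion.** Segmentation artifacts (debris, doublets) show
uniformly elevated signal across the panel. A cell is excluded when its
z-score exceeds the 99th-percentile normal quantile in at least 75% of
markers; both numbers are configuration, not estimates, and survivors are
re-z-scored because artifact cells inflate the original scale. The
operationalization is deliberately simple — no published formula exists for
this filter — and both knobs are in `transformSpec()`.

**Gating.** Cell types are assigned by a priority-ordered rule engine: a
rule lists markers that must be high (z strictly above the high gate,
default 0.5) and low (strictly below the low gate, default 0.5). The first
matching rule wins; unmatched cells are `"unassigned"`. The shipped default
rules cover thirteen TME cell types in four categories (immune / cancer /
normal brain / vasculature), with cancer rules placed before normal-brain
rules so that e.g. EGFR+/SOX2+ astrocytic cancer cells are not swallowed by
the astrocyte rule. The gate of 0.5 z is a replaceable default chosen to
sit well inside the separation of the generator's signatures; it makes no
claim about any particular antibody panel. Strictness of all inequalities
is a determinism decision: boundary cells behave identically on every
platform.

**States.** Hypoxia is `z(HIF1A) > 1.2`, EMT is `z(SNAI1) > 1.2`, both
strict; the cutoff 1.2 is the conventional z-score gate for these state
calls. TGFBeta can be AND-ed into the EMT call; the default uses SNAI1
alone because the marker pair is redundant in the generator and a
conjunctive call only lowers sensitivity.

# Diversity

Per ROI, Shannon entropy `H = -sum(p ln p)` (natural log, so the upper
bound is `ln K`) is computed on 1,000 cells sampled without replacement, 10
times; ROIs smaller than the subsample contribute all their cells each
iteration, avoiding with-replacement bias. Surgeries are compared by
two-sided Wilcoxon rank-sum. The default observation unit is the per-ROI ×
iteration value (pooled at cohort level); per-ROI means are exposed as an
alternative because the iteration-level unit overstates the effective n
when the subsample nearly exhausts the ROI. Per-patient tests are
Benjamini–Hochberg adjusted and reported as q-values.

`compositionVariance()` fits `proportion ~ patient + surgery` per cell
category over per-ROI proportions; the residual is ROI-to-ROI (intra-tumor)
variation. Zero-variance responses are reported degenerate rather than
tested.

# Spatial graphs

Adjacency is the Delaunay triangulation of centroids (via `deldir`) pruned
at 50 µm — the convention for ~10 µm cells, where longer Delaunay edges
span empty space rather than touching membranes. Coordinates are a local
ROI frame with origin at the lower-left; border cells get no edge-effect
correction, matching the pruned-triangulation method as commonly stated.
Pruning uses Euclidean centroid distance. Degenerate inputs: collinear
point sets fall back to a radius graph (all pairs within 50 µm), exact
duplicates are re-attached to their retained representative by a
zero-length edge, fewer than two points give an empty graph with a warning,
all-coincident input is an error. The test suite certifies equivalence with
a brute-force empty-circumcircle oracle on random 12-point sets.

# Interaction testing

For an ordered type pair (A, B) on one ROI graph the statistic is the
number of directed A→B neighbor links, divided either by the number of A
cells (`classic`) or by the number of A cells with at least one B neighbor
(`at_least_one_normalized`, the default). The null is obtained by
shuffling the type labels across the ROI's cells 1,000 times, preserving
the type multiset and the graph. One-sided p-values use the add-one
estimator `(b + 1) / (m + 1)`, which never returns zero and has floor
`1/1001 ≈ 9.99e-4` at 1,000 shuffles — the value `scripts/acceptance.R`
recomputes. Permutations for which a statistic is undefined (no qualifying
A cell) enter the null as zero intensity; an undefined *observed* statistic
excludes the pair with a reason.

Pairs are tested directionally, at fixed `alpha = 0.01`, with no
multiplicity correction across pairs: instead, evidence is filtered for
consistency — a per-patient call requires the same significant direction in
a majority of that patient's ROIs (2 of 3 by default), and a cohort-level
call requires at least 3 patients to agree within a surgery. Retained
pairs are classified primary-only / recurrent-only / both / changed.
Shuffling within ROI first and pooling afterwards (rather than pooling
graphs before the null) was chosen because it respects per-ROI composition
differences; both pooling orders are reasonable and the per-ROI table is
returned so users can re-pool.

# Cellular neighborhoods

Each cell's neighbor composition is the fraction of each type among its
graph neighbors, excluding the cell itself (a neighborhood is its
neighbors; self-inclusion is a flag). Unweighted counts are used — no
distance weighting within a 50 µm-pruned graph is worth the extra
parameter. Vectors are pooled across all patients and surgeries and
clustered jointly so CN labels are comparable between timepoints, with
k-means: k-means++ seeding, Lloyd iterations, 10 restarts keeping the best
inertia, fully deterministic under the seed. `k = 12` is the default
granularity for this tissue; it is a modeling choice, not an estimate, and
the composition-vector simplex makes an elbow diagnostic easy to run if
wanted. Isolated cells (no neighbors) are labeled `"isolated"` and never
clustered. Composition vectors are type-level by default (category-level
works by passing category labels).

# Spatial contexts and the CN network

A cell's spatial context is the minimal set of CNs whose cumulative
fraction in its wider window reaches 0.9: window CN fractions are sorted
decreasing (ties broken by CN name for determinism) and the shortest
qualifying prefix, sorted and joined with `"&"`, is the SC label. The
window is the 2-hop graph neighborhood by default (a radius in µm is
exposed), a scale of roughly 50–100 µm that matches "where neighborhoods
border". Dominant SCs must appear in **strictly more than** 3 patients and
cover **strictly more than** 5% of a surgery's cells — the inequalities are
strict by contract and the boundary cases are pinned in tests.

The CN network of a surgery joins two CNs whenever some retained SC
contains both. Centralities: degree; closeness with the Wasserman–Faust
component-size correction `(r/(n-1)) · (r/sum d)` so disconnected networks
remain comparable (singletons get 0); betweenness normalized by
`(n-1)(n-2)/2`. A static CN→metaprogram→layer annotation table
(`defaultCNAnnotation()`, with one dual-mapped CN) is shipped purely as a
labeling aid for network figures. All three measures are certified against
a hand-written all-pairs shortest-path oracle on networks of up to 12
nodes.

# The synthetic generator

`generateCohort()` emulates the study design this pipeline was built
around: 5 patients × paired primary/recurrent surgeries × 3 ROIs of
1,000 µm side and ~3,500 cells (about 105,000 cells per cohort). Marker
intensities are lognormal per type — location on the natural scale,
dispersion on the log scale — because asinh-transformed IMC intensities are
approximately unimodal per population and right-skewed raw; the shipped
signatures put characteristic markers at location 25 versus background 1.5
with dispersion 0.35, i.e. well-separated (≥ 2 z) populations. Default
type proportions shift from primary to recurrence the way treated cohorts
do (vascular loss, normal-brain and especially astrocyte gain), a
per-patient lognormal proportion jitter (`patient_effect_sd = 0.25`,
shared across a patient's surgeries) makes inter-patient heterogeneity
dominate intra-patient heterogeneity, and per-type state rates raise EMT in
all cancer types at recurrence while moving hypoxia up in AC and down in
MES/NPC cells.

Spatial structure: every default type is clustered — the tissue being
emulated is a mosaic of niches (hypoxic tumor cores, vascular niches,
immune hubs, infiltrative brain), and a generator with uniformly scattered
types produces no niche-pure regions, which starves the spatial-context
stage of dominant contexts. Each type draws its foci uniformly in the ROI
and its cells at isotropic Gaussian offsets, reflected at the ROI borders
(clipping would stack cells onto the exact boundary, a degenerate input
for the triangulation). Per-type focus counts (3–8) and spreads
(40–100 µm) set the niche grain. Pairwise adjacency enrichment is planted
by letting an enriched pair share a fraction `1 - 1/multiplier` of foci
(multiplier 1 = complete spatial randomness between the pair; < 1 pushes
foci apart by rejection); the shared subset is drawn at random from the
partner's foci, and several partners of one hub type take distinct foci
while any remain, so planted pairs spread over the hub's territory
instead of piling onto one spot. Shared foci were preferred over pairwise
interaction point processes because they are controllable, cheap, and
sufficient to exercise the permutation test. The layering-recovery
property test composes these pieces into a core–periphery tissue: a core
type with several tight foci and peripheral types each ringing a distinct
core focus with a wider spread, which yields a star-shaped CN network
whose core has the highest closeness.

Reproducibility: one master seed is expanded into per-ROI substreams by a
counter (`seed + position in the patient × surgery × ROI grid`; patient
jitter uses `seed + 500000 + patient`), so identical seeds give
bit-identical cohorts, single ROIs are reproducible in isolation, and
`shiftComposition()` — which edits one surgery's proportions and
regenerates — leaves the other surgery's ROIs bit-identical. A
consequence worth knowing: two cohorts whose master seeds differ by less
than the number of ROIs share substreams, so replicate studies should space
their seeds (the test suite spaces them by 100–1000).

What the generator does **not** emulate: batch/acquisition effects and
spillover, segmentation errors, cell-size and shape variation, density
gradients within a focus, marker-marker correlation beyond the type means,
and anisotropic tissue architecture (vessel trees, necrotic rims). Passing
tests therefore certify the *statistics* — calibration of the permutation
null on CSR tissue, recovery of planted effects, determinism, oracle
equivalence — not robustness to those real-data nuisances.

# Problem sizes and numerical choices

The validation suite runs, by design, at desk scale: null calibration uses
200 single-ROI cohorts of 500 cells and two types at 1,000 permutations;
planted-interaction recovery uses 20 replicate 5-patient cohorts of 400
cells/ROI with enrichment multiplier 5 at recurrence only; the entropy
direction check uses 20 replicate 5-patient cohorts of 1,200 cells/ROI
with a 40%→70% dominance shift; CN recovery clusters 20,000 planted
vectors. These sizes give tight binomial error bars while keeping the
whole suite in minutes. Numerical conventions collected in one place:
strict inequalities at every gate and filter boundary; add-one permutation
p-values; ties in SC fractions broken by CN name; k-means ties resolved by
the first-best restart; zero-variance markers get z = 0; entropy of an
empty ROI is an error, never 0; proportions validated to 1e-9; centroid
simplex tolerance 1e-6.

# Limitations

The gating defaults describe the synthetic signatures, not any particular
antibody panel — real panels need their own rule table. The permutation
test conditions on the graph and type multiset; it detects label-graph
association, not mechanism. CN number is fixed rather than selected.
Closeness on very small networks (3–4 CNs) is dominated by the component
correction and should be compared, not interpreted absolutely. The
dominant-SC filter's strict "> 3 patients" reading drops SCs seen in
exactly 3 of 5 patients; relax `min_patients` if that is too conservative
for a smaller cohort.
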