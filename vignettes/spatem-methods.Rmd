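---
title: "Methods: integrating spatial transcriptomics with EM ultrastructure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating spatial transcriptomics with EM ultrastructure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spatem)
```

## The problem

Imaging-based spatial transcriptomics (MERFISH-style panels) records the
positions and expression of hundreds of genes in thousands of single cells in
a tissue section. Volume electron microscopy of an *adjacent* section records
the ultrastructure — nuclei, lysosomes, lipid droplets, mitochondria, ER — of
the same tissue at nanometre resolution, but carries no molecular identity.
`spatem` implements the computational chain that joins the two: per-cell
quality control and annotation of the transcriptomic section, registration of
the EM section into the same coordinate frame, statistical comparison of
spatial patterns across modalities, and kernel-based transfer of values
between modalities so that gene expression can be correlated with
ultrastructural features cell by cell. The motivating application is a focal
demyelinated brain lesion populated by homeostatic microglia,
disease-associated (DAM-like) microglia, lipid-laden "foamy" microglia,
interferon-responsive glia and infiltrating T-cells.

Because the raw study data (tissue images, micrographs) are not shipped with
a package, every stage is validated on a coupled synthetic-data generator
that plants known spatial, transcriptional and ultrastructural structure, and
on small brute-force oracles (exact enumeration, linear programming,
pair counting) where an estimator has a checkable ground truth.

## The synthetic tissue

`synth_config()` fixes the emulated study conditions; `simulate_bundle()` is
a deterministic function of it.

* **Geometry.** A circular lesion of radius 400 µm centered in a
  2200 × 2200 µm frame (the scale of the imaged block face). Homeostatic
  cells are uniform outside the lesion disk, DAM-like cells uniform inside.
* **Niches.** Foamy cells follow a Thomas cluster process (Poisson parents,
  Gaussian daughters) whose parents sit near the lesion center; the Thomas
  process is used because it has analytic intensity and trivial simulation,
  and it reproduces "niches of a few tens of microns" with `niche_sd`
  (default 30 µm) controlling their spread. IFN-responsive cells and T-cells
  share niche parents — that is the planted co-clustering the neighborhood
  and Ripley statistics must detect — but T-cells occupy only ~60% of the
  shared niches, so the two classes remain globally distinguishable (without
  this, their long-range density maps would be statistically identical and
  cross-modal class matching would be ill-posed, which is also what one would
  expect of real T-cell infiltrates that do not fill every IFN niche).
* **Counts.** Negative-binomial counts (dispersion `nb_dispersion = 2`) over
  a 150-gene panel: 12 markers per class at `marker_logfc = 2` (log2) over a
  lognormal baseline, lognormal cell size factors, and 10 appended `Blank-`
  pseudo-genes with Poisson noise totalling `blank_rate = 0.3` counts/cell,
  mirroring the MERFISH blank-probe convention. The foamy program scales
  smoothly with a per-cell latent (class effect + unit Gaussian), which makes
  the program a graded, not binary, signal.
* **QC violators.** 2% of cells are planted as violators, one unambiguous
  criterion each (too few/too many transcripts, too few genes, volume out of
  the 40–2500 µm³ window, blank mean above 1); honest cells are kept safely
  inside all bounds. The truth record lists the violators, so QC exactness is
  scored by bookkeeping, not re-derivation.
* **EM section.** EM cells are a subsample of ST cells jittered by
  `em_jitter_sd = 5` µm (adjacent 10 µm sections), mapped into the EM frame
  by a similarity transform (10°, 1.05×, (30, −20) µm) plus a smooth
  deformation: 3 Gaussian bumps of 20 µm amplitude and 250 µm spread. The
  configuration refuses amplitude/spread combinations whose displacement
  gradient could reach 1 (fold-over), keeping the true map invertible.
  16 landmark pairs on a grid across the frame map exactly under the true
  transform. Organelle features are drawn per class (foamy: large lipid
  droplet areas; T-cells: high nucleus/cell ratio and near-zero organelles;
  IFN-like: high mitochondria and empty cytoplasm). The lipid-droplet area is
  a *linear* function of `rho * z + sqrt(1 - rho^2) * noise`, with `z` the
  standardized foamy latent, so the planted gene-program/feature correlation
  is exactly `latent_gene_feature_rho` (default 0.6) in expectation.
* **scRNA-seq.** A 2000-gene full transcriptome with the same class programs
  plus 8 extra (non-panel) markers per class for imputation tests, and a
  strictly positive lipid-stain intensity `100 * exp(0.5 * latent + noise)`
  (noise sd `bodipy_noise_sd = 0.3` on the log scale).

What the generator does **not** emulate: segmentation errors and doublets,
spatial expression gradients within a class, batch effects between
replicates, anisotropic section compression, or irregular lesion shapes.
Passing tests therefore demonstrate correctness of the estimators under the
stated model, not robustness to every artefact of real tissue.

## Quality control and normalization

Cells are excluded when the total (non-blank) transcript count is below 30 or
above 2500, fewer than 5 genes are detected, the segmented volume is outside
40–2500 µm³, or the mean blank-probe count exceeds 1. All exclusions are
strict inequalities, so a cell exactly at a bound is retained — the literal
reading of "<30 or >2500". Blank probes never enter totals, normalization,
PCA or marker tests. Normalization is `ln(1 + 10^4 * x / total)` per cell.
The filter report counts removals per criterion non-exclusively.

Module scores use the binned-control procedure (24 average-expression bins,
100 controls per signature gene, drawn without replacement within the bin,
seed-deterministic). Contamination-signature regression replaces the working
layer by per-gene OLS residuals on the score covariates; constant covariates
are dropped with a warning, and with no informative covariate the operation
is the identity — a deliberate no-op contract so that "regress nothing"
cannot silently center the data. Markers use the two-sided Wilcoxon rank-sum
test with BH adjustment; a constant gene returns p = 1 by convention rather
than NaN.

Graph clustering is PCA (20 PCs by default) → exact k-nearest-neighbor graph
→ Jaccard-weighted shared-nearest-neighbor edges → Louvain communities
(igraph), seeded for determinism. Label transfer projects the query into a
PCA basis fitted on the scaled reference over shared genes and lets the k
nearest reference cells vote with inverse-distance weights (an exact-match
neighbor takes the whole vote, so a query identical to the reference
reproduces it with confidence 1). This joint-PCA + weighted-vote scheme is a
deliberate simplification of anchor-based integration; it is validated by
recovery on synthetic truth (≥90% class accuracy), not by equality with any
external toolkit. Imputation uses the same neighbor structure to average
reference expression of genes that pass the expression filter (≥10 total
counts in ≥20 cells, reading the filter as total-counts-and-detection since
the two thresholds otherwise conflict); measured panel genes pass through
unchanged.

## Lesion geometry

The expert-drawn lesion core of the original workflow is formalized as a
density-difference rule: Gaussian KDE (bandwidth 50 µm) of a core-enriched
class minus KDE of a core-depleted class, thresholded at the 0.90 grid
quantile, largest connected component, contour polygonized. This is a
documented stand-in validated only against synthetic truth (centroid within
50 µm, area within 25%). Rings are *distance bands*: a point is in ring k
when its Euclidean distance to the core polygon lies in ((k−1)·50, k·50] µm.
Membership therefore uses exact point-to-polygon distances
(boundary-inclusive containment), while ring outlines and areas for
reporting are contoured from the distance field on a fine raster (1–2 µm
pixels; the circular closed form is reproduced within 1%). Region priority
is core > inner edge > outer edge > controls > none.

## Spatial statistics

**Neighborhood enrichment.** Each cell's 5 nearest neighbors (Euclidean,
self excluded) are pooled per query class; the fraction of each target label
is compared to 10,000 label permutations with positions fixed. Fold
enrichment is observed over permutation mean; the p-value uses the add-one
convention `(1 + #{perm ≥ obs}) / (1 + n_perm)`, so it can never be zero.

**Cross-type Ripley's L.** The cross-type K function is estimated by pair
counting inside a polygonal window with an isotropic edge correction: the
weight of a pair is the inverse fraction of the circle (centered at one
point, through the other) lying inside the window, averaged over both
orderings so the estimator is exactly symmetric in the two classes. The arc
fraction is evaluated numerically (64 arc samples against a 256×256 raster
of the window; weights capped at 16). L = sqrt(K/π) (Besag's transform).
Envelopes come from 200 random relabellings of the pooled two-class points;
the centered curve is `L_obs − mean(L_perm)`, so positive values indicate
attraction — the sign convention is chosen to honor the stated
interpretation of such plots. The estimator is validated against an O(n²)
pair-count oracle (no correction, exact equality) and by CSR calibration
(≥90% of radii inside the 0.05 envelopes on average).

## Registration

The alignment chain is rigid → similarity → thin-plate spline, each stage
fitted on the source points as mapped by the previous stages. With trusted
landmark pairings the rigid/similarity stages are closed-form orthogonal
Procrustes (Umeyama scale, det(R) = +1 enforced); without pairings an ICP
loop alternates nearest-neighbor correspondence and Procrustes, rejecting
the worst decile of residuals per iteration for robustness, until the rmse
change falls below 1e-10. The TPS uses the standard U(r) = r² log r kernel
with affine part and no smoothing, so it interpolates landmarks exactly;
source coordinates are normalized to unit scale before solving because the
kernel matrix is badly conditioned at millimetre coordinate magnitudes
(observed reciprocal condition numbers near machine epsilon). TPS
invertibility is not guaranteed; `diagnose_foldover()` reports negative
numeric Jacobians on a grid. Fitted rmse is non-increasing along the chain.

## Multiscale Earth Mover's Distance

Class patterns are compared as normalized density maps: Gaussian KDE of each
class at σ = 25, 50, 75, 100 µm on a common 50×50 grid (clip-to-window then
renormalize; grid resolution is a configuration choice — the matching
analyses in tests use 24×24, where the EMD has converged to within ~1% of
finer grids while each exact solve stays below a second). The EMD between
two maps is the exact optimal-transport cost with Euclidean ground distance
between bin centers, solved by a dense transportation (network) simplex
written for this package: row-greedy minimum-cost starting basis (a spanning
tree under a ~1e-13 supply perturbation that also prevents degenerate
cycling), blocked Dantzig pricing, cycles found via the rooted tree's lowest
common ancestor, and potentials updated only on the smaller cut component
(valid because duals have a global gauge freedom). Bins below 1e-12 mass are
pruned. The solver is validated against a linear-programming oracle
(`boot::simplex`) to 1e-6 and satisfies the metric axioms on random
histograms; above 64×64 grids a log-domain Sinkhorn approximation is used
with a warning. The multiscale EMD is the arithmetic mean over the four
scales, and class-by-class matrices can be row/column z-scored for display.

## Cross-modal transfer and correlation

With both modalities in the common frame, every cell receives, for every
column, the bisquare-kernel weighted average `w(d) = (1 − (d/d_max)²)²`
(zero at and beyond `d_max = 75` µm) over the donors of that column's source
modality. Gene columns use measured panel values plus imputed values for the
rest; structural columns come from EM cells. `include_self = TRUE` is the
default for same-modality smoothing (w(0) = 1 makes self-inclusion the
continuity-respecting choice); cross-modality transfer has no self by
construction. ST cells are restricted to the area surrounding the available
EM data, operationalized as "within d_max of the nearest EM cell" — the rule
has no numeric definition in the original description, and this choice keeps
exactly the cells that can receive a structural value. Smoothing is a convex
combination, so smoothed values stay inside the donor range; cells with no
donor in range are reported missing.

Gene-feature association is Spearman's ρ with average ranks and
pairwise-complete observations. Over-representation of gene sets among the
top-200 correlates is a one-sided hypergeometric test against the analyzed
universe with BH adjustment. Note that smoothing attenuates a planted
program-feature correlation of 0.6 to roughly 0.45–0.55 at the default
settings (count noise within markers, neighborhood mixing across classes);
recovery is asserted within ±0.2 with calibrated nulls, which is the
resolution this design actually supports.

## Ultrastructural morphometrics

Features come from binary label masks per cell (invariants: organelles
inside the whole cell, heterochromatin inside the nucleus). Connected
components under 5 pixels are removed as stray pixels (8-connectivity, so
thin diagonal structures survive). Areas are pixel counts (reported in px
and µm²); empty cytoplasm is the whole cell minus the union of all other
segmentations, which makes pixel conservation exact for disjoint
compartments; ER length is the arc length of the Zhang–Suen skeleton,
measured as the weight of the minimum spanning tree over 8-neighbor steps
(1 or √2 px) — a 50-pixel straight segment measures 49 pixels. The "32
structural metrics" of the motivating study are not enumerated anywhere, so
the ratio list is an explicit manifest (`structural_ratio_manifest()`):
organelle shares of the whole cell, intra-nuclear and intra-cytoplasmic
shares; it is configurable and recorded with the output. Structural
clustering z-scales features (missing ratios → 0 plus a missingness
indicator) and reuses the expression clustering machinery. Expert labels are
matched to featured cells by nearest position (many-to-one allowed but
flagged), and label agreement is tested per class pair with a one-sided
Fisher exact test, validated against direct hypergeometric enumeration to
1e-12.

## Metacells, lipid-stain correlation and GSEA

Metacells are seed cells plus their k−1 = 19 nearest neighbors in a 15-PC
space of the normalized counts; candidates sharing more than k/2 members
with an accepted metacell are rejected. Defaults left open by the source
description: number of seeds n/5, permutations 1000. The stain is
log10-transformed before averaging; per-gene Pearson correlations against
the metacell stain means define the ranking. At k = 1 the construction is
the identity, and the correlation equals the single-cell correlation exactly
— a useful invariant test. Preranked GSEA is the weighted Kolmogorov–Smirnov
running sum (hit increments ∝ |stat|^weight, uniform miss decrements; ES =
signed maximal deviation) with a gene-permutation null, NES = ES divided by
the mean same-sign permutation magnitude, and deterministic tie-breaking by
gene name. The score matches both a brute-force oracle and `fgsea`'s
statistic to numerical precision.

## Numerical choices and degenerate inputs

* Add-one convention for all permutation p-values (never zero).
* Constant genes: p = 1 in rank-sum tests, `NA` in correlations, zeros with
  a warning in z-scored matrices.
* `n_pcs` clamps (with a warning) to what the data support.
* Resolution → 0 yields a single Louvain community on a connected SNN graph
  (well-separated data can still split into graph components).
* EMD refuses mass mismatches above 1e-6 and mismatched grid geometry.
* Boundary containment is inclusive everywhere (a cell on the core outline
  is in the core; a donor exactly at d_max has weight zero).
* All randomized steps (generator, permutations, control sampling, Louvain,
  metacell seeds) take explicit integer seeds.

## Problem sizes

The default synthetic conditions are 2000 ST cells, 800 EM cells, 1000
scRNA-seq cells, a 150-gene panel and a 2000-gene transcriptome. The test
suite runs the permutation statistics at their full settings (10,000
neighborhood permutations; 200 relabellings for envelopes over 50 CSR seeds;
10-seed recovery loops for matching and correlation), with EMD matching on
24×24 grids; these are the package's validation conditions, chosen so the
whole chain remains reproducible on a laptop.

## Known limitations

* The lesion-core rule is a stand-in for expert segmentation; on real data
  the threshold quantile and bandwidth need tuning, and expression-guided
  refinement (e.g. myelin genes) is out of scope.
* The isotropic edge correction is numeric (arc sampling on a raster), exact
  only in the limit of fine sampling; the `"none"` option exists for exact
  oracle comparisons.
* Label transfer/imputation is a simplified neighbor-vote scheme, not an
  anchor-based integration; systematic cross-platform shifts beyond
  per-gene scaling are not modeled.
* TPS extrapolates poorly outside the landmark hull; landmarks should cover
  the analyzed region.
* The exact EMD solver is dense (O(m·n) memory); beyond 64×64 grids the
  entropic approximation takes over.
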