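# spatem

Integration of single-cell spatial transcriptomics with adjacent-section
electron-microscopy (EM) morphometrics.

Imaging-based spatial transcriptomics (e.g. a MERFISH panel) gives each cell
in a tissue section a position and an expression profile over a few hundred
genes; volume EM of the adjacent section gives cells their ultrastructure —
nucleus, lysosomes, lipid droplets, mitochondria, ER — but no molecular
identity. `spatem` implements the computational chain that anchors the two
modalities to each other, with a demyelinated brain lesion (homeostatic,
DAM-like, foamy and interferon-responsive glia plus infiltrating T-cells) as
the motivating system:

* **Expression**: per-cell QC (transcript/gene/volume/blank-probe bounds),
  `ln(1 + 10⁴·x/total)` normalization, binned-control module scores,
  contamination-signature regression, Wilcoxon markers, SNN-Louvain
  clustering, reference label transfer and panel→transcriptome gene
  imputation.
* **Lesion geometry**: density-difference estimation of the lesion core and
  exact 50 µm ring expansion (`lesion_core`, `lesion_inner_edge`,
  `lesion_outer_edge`), boundary-inclusive region assignment.
* **Spatial statistics**: k-nearest-neighbor composition enrichment with
  permutation p-values, and cross-type Ripley's L — Besag's transform
  `L(r) = sqrt(K_ab(r)/π)` of the cross-type K function with isotropic edge
  correction in a polygonal window, centered as `L_obs − mean(L_perm)` with
  0.05-level permutation envelopes (values above 0 indicate attraction).
* **Registration**: landmark chain rigid → similarity (closed-form
  orthogonal Procrustes, optional ICP with trimmed correspondences) →
  interpolating thin-plate spline (`U(r) = r² log r`).
* **Pattern similarity**: multiscale Earth Mover's Distance — exact
  optimal-transport cost between per-class Gaussian density maps, averaged
  over σ = 25/50/75/100 µm, computed by a transportation-simplex solver
  validated against a linear-programming oracle.
* **Cross-modal transfer**: bisquare-kernel distance-weighted averaging
  (`w(d) = (1 − (d/75 µm)²)²`) carrying gene expression and structural
  features to every cell of both modalities, Spearman gene×feature
  correlation, and hypergeometric over-representation of the top correlates.
* **Ultrastructure**: organelle label-mask morphometrics (pixel areas, ER
  skeleton arc length, empty-cytoplasm subtraction, ratio manifest),
  structural clustering, nearest-position expert-label matching with
  one-sided Fisher overlap tests.
* **Metacells**: k-NN metacell aggregation, per-gene Pearson correlation
  with a log10 lipid-stain (BODIPY-like) readout, and preranked GSEA
  (weighted Kolmogorov–Smirnov running sum, gene-permutation null).

A coupled synthetic-data generator (`synth_config()`, `simulate_bundle()`)
plants known class layouts, niches, marker programs, a known
similarity+deformation between frames, and a known gene-program/feature
correlation, so every stage is tested against ground truth. All functions
take data frames first and return tibbles; fitted objects have
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

```r
library(spatem)

b <- simulate_bundle(synth_config(seed = 1))
#> <synth_bundle> 2000 ST cells, 800 EM cells, 1000 scRNA-seq cells (seed 1)

qc <- qc_filter(b$st_cells, b$st_counts)
qc$report
#> # A tibble: 7 × 2
#>   criterion   n_removed
#>   <chr>           <dbl>
#> 1 low_counts          7
#> 2 high_counts         7
#> 3 low_genes           7
#> 4 low_volume          7
#> 5 high_volume         6
#> 6 high_blank          6
#> 7 total              40
```

Exactly the 40 planted QC violators are removed (the per-criterion rows are
non-exclusive counts). Registration of the EM frame onto the ST frame from
the landmark pairs:

```r
lm <- landmark_set(b$landmarks[, c("x_src", "y_src")],
                   b$landmarks[, c("x_dst", "y_dst")])
chain <- fit_transform_chain(lm)
chain
#> <transform_chain> rigid -> similarity -> tps; rmse: 50.29 -> 5.332 -> 3.11e-13 µm
```

The rigid stage leaves the 1.05× scale unexplained (rmse 50 µm), the
similarity stage removes it (5.3 µm, the residual smooth deformation), and
the thin-plate spline interpolates the landmarks exactly. Neighborhood
enrichment inside the lesion then recovers the planted T-cell/IFN niches:

```r
core  <- estimate_lesion_core(b$st_cells, "dam", "homeostatic")
cells <- assign_regions(b$st_cells, expand_rings(core))
lesion <- dplyr::filter(cells, region_label %in%
                        c("lesion_core", "lesion_inner_edge", "lesion_outer_edge"))
knn_enrichment(lesion, k = 5, n_perm = 10000, seed = 1) |>
  dplyr::filter(query_class == "tcell")
#>   query_class target_class observed_fraction fold_enrichment empirical_p
#> 1 tcell       dam                    0.135            0.344    1
#> 2 tcell       foamy                  0                0        1
#> 3 tcell       homeostatic            0.00125          0.0216   1
#> 4 tcell       ifn                    0.462            2.45     0.0001
#> 5 tcell       tcell                  0.401            3.21     0.0001
```

46% of T-cell neighbors are IFN-responsive cells — a 2.45-fold enrichment
over the permutation null (p = 1e-4, the add-one minimum at 10,000
permutations), while homeostatic cells are strongly depleted around T-cells.

The full chain (QC → lesion → neighborhood → Ripley → registration →
multiscale EMD → kernel transfer → correlation → metacells) runs as
`run_pipeline(synth_config(seed = 1), "out/")` and writes deterministic
TSV/JSON outputs; `inst/scripts/spatem.R` is a thin command-line wrapper
over it.

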