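# nucbin

Single-nucleus reconstruction from subcellular spatial transcriptomics.

Probe-based spatial platforms now measure UMI counts on a continuous grid of
2 × 2 µm capture spots — well below the size of a cell. The standard way to
make these data tractable is to aggregate spots into fixed 8 × 8 µm
(64 µm²) squares approximating a "typical" cell, but squares ignore where
cells actually are: one bin can straddle two cells, and most bins straddle a
cell and its surroundings. `nucbin` implements the alternative used for
archival (FFPE) kidney biopsies: segment nuclei on the registered image,
assign every spot to the nucleus covering it, and sum spot profiles per
nucleus, yielding a *single-nucleus* expression matrix

```
y_k = Σ_{s : label(s) = k} x_s
```

for nucleus *k* over spots *s*, with per-nucleus area, spot count, detected
features and mitochondrial fraction carried as metadata. The package is
aimed at computational biologists analysing subcellular spatial data of
structured tissue (the built-in simulator and signatures are modelled on
kidney, with glomerulus-like niches and a rare podocyte-like type).

Around that core it provides the full downstream workflow:

- **Synthetic tissue** (`sim_config()`, `generate_tissue()`,
  `generate_cohort()`, `perturb_segmentation()`): ground-truth nuclei
  (log-normal areas centred at 20 µm² ≈ five 2 µm spots), marker-driven
  multinomial expression, negative-binomial libraries, ambient spill,
  multi-patient batch effects and transcript-degradation artifacts — so
  every stage is testable without external data.
- **Segmentation evaluation** (`match_instances()`, `precision_recall()`,
  `roi_report()`): optimal one-to-one IoU matching of predicted vs truth
  nuclei, precision/recall per region of interest.
- **Quality control** (`filter_genes()`, `filter_nuclei()`, `apply_qc()`):
  genes kept at total counts ≥ 3; nuclei kept at counts > 10 and
  mitochondrial percentage < 5 (both strict).
- **Clustering and annotation** (`cluster_graph()`, `rank_markers()`,
  `signature_score()`, `assign_types()`): PCA → shared-nearest-neighbor
  graph → Leiden communities; Wilcoxon one-vs-rest markers; rank-based
  (UCell-style) signature scores with a rank ceiling; per-cluster cell-type
  calls with an explicit `"unknown"` when no signature dominates.
- **Integration** (`cca_project()`, `find_anchors()`,
  `integrate_datasets()`): diagonal canonical correlation analysis,
  mutual-nearest-neighbor anchors, Gaussian-weighted correction toward the
  largest dataset.
- **Binning comparison** (`run_both()`, `run_both_cohort()`,
  `comparison_report()`): nucleus binning vs 64 µm² square binning on the
  same input with provably identical parameters, reporting shared/unique
  cell types, unknown-assignment fractions, and the focal-type
  signature-score test.

All tabular results are tibbles; fitted containers have `tidy()`,
`glance()` and `autoplot()`/`plot_*()` methods.

## Worked example

Simulate one tissue, reconstruct nuclei, and annotate:

```r
library(nucbin)

sim <- generate_tissue(sim_config(n_nuclei = 600L, canvas_px = c(208L, 208L),
                                  n_glomeruli = 3L), seed = 7)
nm <- bin_by_nuclei(sim$spots, sim$truth$label_image)
nm
#> <nucleus_matrix> 600 observations x 500 genes, 63,457 total counts

area_stats(nm)$summary
#> # A tibble: 1 × 5
#>   n_nuclei mean_area_um2 median_area_um2 mean_spots median_spots
#>      <int>         <dbl>           <dbl>      <dbl>        <dbl>
#> 1      600          19.8              20       4.94            5

counts_area_regression(nm)
#> # A tibble: 1 × 5
#>   slope intercept r_squared  p_value     n
#>   <dbl>     <dbl>     <dbl>    <dbl> <int>
#> 1  2.66      53.2     0.196 4.14e-30   600

ad <- annotate_dataset(nm, signatures = sim_signatures(sim$truth))
ad$assignment$calls
#> # A tibble: 6 × 6
#>   cluster call             best_signature  best_median runner_up_median tie_flag
#>   <chr>   <chr>            <chr>                 <dbl>            <dbl> <lgl>
#> 1 1       proximal_tubule  proximal_tubule       0.537           0.0100 FALSE
#> 2 2       distal_tubule    distal_tubule         0.58            0.0100 FALSE
#> 3 3       immune           immune                0.619           0.0292 FALSE
#> 4 4       glom_endothelial glom_endotheli…       0.587           0.0100 FALSE
#> 5 5       mesangial        mesangial             0.61            0.0100 FALSE
#> 6 6       podocyte         podocyte              0.672           0.0583 FALSE
```

Reading the output: the reconstructed nuclei average 4.94 spots at a mean
area of 19.8 µm² (five 4 µm² spots per ~20 µm² nucleus); nuclear area is
moderately, positively associated with per-nucleus counts (R² ≈ 0.2);
graph clustering recovers the six simulated cell types, and each cluster is
confidently called because its winning signature's median score dwarfs the
runner-up (`runner_up_median`), including the rare glomerular podocyte-like
type.

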