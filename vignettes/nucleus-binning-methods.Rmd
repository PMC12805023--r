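---
title: "Methods: nucleus binning for subcellular spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleus binning for subcellular spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `nucbin`, in the spirit of a methods section: what each
stage assumes, which knobs matter, and what the synthetic data can and
cannot tell you about real tissue.

## The reconstruction model

The input is a UMI count matrix on a regular grid of 2 × 2 µm capture
spots, together with a nucleus instance segmentation registered one pixel
per spot (an integer row/column offset handles cropped regions; see
`label_image()`). Nucleus binning assigns a spot to nucleus $k$ exactly
when the spot's center pixel carries label $k$, and sums the assigned spot
vectors:

$$y_{kg} = \sum_{s\,:\,\mathrm{label}(s)=k} x_{sg}.$$

Two properties follow by construction and are enforced by tests: counts
are never invented or lost (assigned + background = total), and each spot
contributes to at most one nucleus. The *center rule* — whole spots are
assigned, no area-overlap weighting — is the simplest interpretation
consistent with binning entire capture areas; spots straddling a nucleus
boundary are therefore attributed wholly to the nucleus covering their
center. The alternative, apportioning a spot between neighbours, would
create fractional counts and break downstream count models.

Fixed square binning (`bin_by_square()`, default 8 µm = 16 spots = 64 µm²,
the conventional approximation of a typical cell's area) partitions the
grid by `floor(index / k)`. Ragged edge bins are kept and flagged rather
than dropped: dropping them would silently lose counts at region borders.

At ~20 µm² per nucleus and 4 µm² per spot, a nucleus collects about five
spots; per-nucleus totals are consequently shallow, which shapes several
choices below (rank ceilings, confidence rules).

## The synthetic tissue generator

`generate_tissue()` draws ground truth first and observations second, so
every downstream claim can be checked against a known answer.

* **Geometry.** Nuclei are non-overlapping ellipses with log-normal areas
  (mean `mean_area_um2 = 20` µm², CV 0.35) rasterised on the 2 µm pixel
  grid; placement is rejection-sampled. Star-convex segmentation masks are
  well approximated by ellipses, and ellipse areas are directly
  controllable. Six cell types are simulated; the three glomerular types
  (podocyte-like, endothelial-like, mesangial-like) are confined to
  circular glomerulus-like disks. Within a disk the types are radially
  zoned — podocytes toward the periphery, endothelium and mesangium in the
  core, with an overlap band — matching glomerular micro-anatomy, where
  podocytes line the outside of the capillary tuft. Zoning matters for the
  binning comparison: with fully interleaved types, no 64 µm² bin is ever
  podocyte-dominated and square binning cannot produce a podocyte cluster
  at all, which is not what is observed on real tissue.
* **Expression.** Each type has a relative-rate profile: `n_markers_per_type
  = 10` markers at `marker_fold_change = 8`, all other non-mitochondrial
  genes at 1, over a 500-gene panel. Canonical kidney markers (NPHS2,
  PODXL, PECAM1, PLVAP, EHD3, CLIC4, PDGFRB, GPX3, DPEP1, ANPEP) lead their
  type's marker block so that curated signatures work on synthetic data.
  Per-nucleus library sizes are negative binomial (`library_mean = 120`,
  size 8) with the mean scaled by relative nuclear area to the power
  `area_coupling = 0.5`; this coupling reproduces a moderate positive
  counts–area association (R² near 0.2) rather than the R² ≈ 0.5 that
  proportional coupling would give. The mitochondrial share per nucleus is
  Beta-distributed with mean 2.5%, so a realistic minority of nuclei fails
  the 5% QC cut. Genes are allocated multinomially; the generator is
  therefore a standard UMI count model, not a model of any particular
  chemistry.
* **Spatial placement.** Each transcript lands uniformly inside its
  nucleus, or — with probability `ambient_fraction` (default 0.1) —
  uniformly in a dilation ring of radius `ambient_dilation_px = 3` pixels
  around it, standing in for cytoplasmic and ambient material. Count
  conservation is exact: every transcript lands somewhere on the canvas.
* **Cohorts.** `generate_cohort()` multiplies profiles by per-gene
  log-normal factors (sd `batch_effect`) per patient, and can zero a chosen
  fraction of one type's markers in one batch to emulate transcript
  degradation in old archival tissue — the artifact that makes one cell
  type split into batch-specific clusters before integration.

What the generator does **not** emulate: diffusion-shaped spill (the ring
is uniform), segmentation errors from image artifacts
(`perturb_segmentation()` applies stylised drops/merges/splits/jitter
instead), realistic transcript-level dropout structure, spatial gradients
within a cell type, or whole-transcriptome panel sizes. Passing tests on
synthetic data therefore demonstrate the *bookkeeping and inference
machinery* under a known truth, not performance on any particular
platform's noise.

## Quality control

Thresholds follow the filtering rules exactly as stated for this kind of
data: genes kept at summed counts **≥ 3** (inclusive), nuclei kept at
total counts **> 10** and mitochondrial percentage **< 5** (both strict, so
boundary values are removed). The gene filter runs first — gene detection
is assessed across all nuclei — and the mitochondrial percentage is
recomputed on the reduced panel before the nucleus filter. Summary
"mean ± sd" statistics use the sample (n − 1) standard deviation; a
single-observation input reports sd 0 with a flag rather than `NA`.

## Clustering, markers, signatures, calls

Normalisation is median-total scaling followed by `log1p`. The signature
score depends only on within-observation ranks, so it is invariant to any
monotone per-observation transform; the normalisation choice affects only
clustering geometry.

Clustering is PCA (`n_pcs = 30`, capped at dimensions − 1; genes centred
and unit-scaled), a shared-nearest-neighbor graph (`n_neighbors = 15`,
Jaccard weights, pruned below 1/15) and Leiden modularity communities at
`resolution = 1`, relabelled by decreasing size for determinism. Marker
detection is one-vs-rest Wilcoxon on normalised expression with
Benjamini–Hochberg adjustment per cluster; pooled sizes of at most 20 use
an exact null (complete enumeration under ties), larger ones the
tie-corrected normal approximation with continuity correction.

The **signature score** is the rank-based (UCell-style) statistic: ranks by
decreasing expression, capped at `rmax + 1`, and
$1 - U'/(n\,r_{max})$ clipped to $[0,1]$. Two choices deserve comment.

* *Tie handling.* Tied expression values (mostly the zero block) receive
  average ranks. Giving ties the minimum rank would let a nucleus's many
  undetected genes all inherit the rank of the first zero, which collapses
  the contrast between observations that do and do not express a signature
  on shallow panels; average ranks, the published convention for this
  score, preserve it.
* *Rank ceiling.* `rmax` must exceed the typical number of expressed genes
  per observation but sit well below the panel size, so that absent
  signature genes saturate at the cap. 1500 is the whole-transcriptome
  convention; for the simulator's 500-gene panel the pipeline default is
  `ucell_rmax = 100`, on the order of the median detected-feature count.

**Cell-type calls** are made per cluster from median signature scores. A
call is confident only when the winning median clears an absolute floor
(`unknown_score_threshold = 0.2`) *and* is at least `dominance_ratio = 2`
times every competing signature's median; otherwise the cluster is
`"unknown"`. The dominance clause encodes the curation logic used in
practice — a podocyte call stands because endothelial and mesangial
signatures are absent — and is robust to sequencing depth, which an
absolute threshold alone is not: the absolute magnitude of a rank score
falls as profiles get shallower even when the winning signature towers
over all competitors. Mixed bins, whose two lineage signatures score
comparably, fail dominance and go unknown; this is the mechanism behind
the higher unknown fraction of square binning. Exact ties resolve to the
lexicographically first signature, are flagged, and fail dominance.

Signatures themselves are short curated lists (`default_signatures()`,
`sim_signatures()` with 3 genes per type): cell types are called on a
handful of specific genes, not a full differential-expression programme.

The **assignment score** reported per nucleus is the fraction of its
`k = 15` nearest neighbours in PC space sharing its cluster label — a
k-NN label-consistency surrogate, defined here because no standard
definition exists for this quantity; per-cluster medians near 1 indicate
well-resolved clusters. **Hedges' g** (with the small-sample correction
$J = 1 - 3/(4n - 9)$) quantifies pairwise differences in counts and
features across clusters; zero pooled variance returns 0 for equal means
and a flagged signed infinity otherwise, rather than `NaN`.

## Segmentation evaluation

Predicted and truth instances are matched one-to-one by maximising total
IoU over candidate pairs at or above `iou_threshold = 0.5` (the standard
instance-segmentation convention), using an in-package Hungarian
(shortest-augmenting-path) solver; ties prefer lower truth labels via an
infinitesimal bonus, making results deterministic. Precision is TP over
predictions (0, flagged, when there are no predictions), recall TP over
truth. Per-ROI metrics subset instances by the ROI containing their
centroid and match within the ROI; a pooled row reports across-ROI means.
Note that at ~5 pixels per nucleus an IoU of 0.5 is a severe criterion:
±1 pixel of boundary jitter can dissolve a match, which is why the
evaluation exposes the threshold rather than hard-coding it.

## Integration

The integration is a deliberately reduced anchoring workflow. Datasets are
log-normalised, restricted to the shared panel, and the top 2000 variable
genes enter a diagonal CCA: per-gene standardisation, SVD of the
cross-product, L2-normalised per-observation embeddings. The reported
canonical correlations are the cosines of the paired gene-space variates
(components reordered so they are non-increasing); this definition gives 1
when a dataset is projected with itself and decays for unrelated data.
For problems above 400 observations per side the SVD is a randomized
truncated decomposition (two power iterations, oversampling 10) with an
internal fixed seed that preserves the caller's RNG state.

Anchors are mutual nearest neighbours (`k_anchor = 5`) in CC space, scored
by shared-neighbor overlap in the joint embedding. Each query observation
is corrected by a Gaussian-kernel weighted mean of its `k_weight = 50`
nearest anchors' (reference − query) differences. Anchors are located at
the *midpoint* of their two embeddings and boundary ties are kept in the
k-nearest selection (with a floating-point tolerance); this makes the
symmetric anchor pairs that arise when integrating a dataset with a copy
of itself receive equal weights, so their opposite differences cancel and
self-integration is exactly a no-op — a property an asymmetric weighting
scheme does not have. The reference is the largest dataset
(deterministic); a pair with zero anchors passes through uncorrected with
a warning. Anchor averaging does shrink observations toward local
reference means, so even a no-batch-effect cohort sees a small nonzero
correction; the tests bound it and check that truth recovery is not
degraded.

## The binning comparison

`run_both()` (single sample) and `run_both_cohort()` (integrated
multi-patient) process the identical spot grid through nucleus binning and
64 µm² square binning with one shared `run_config()`; the two run
manifests differ only in their binning stanza, which the tests verify.
"Observations" are post-QC nuclei or bins. The comparison report contains
the shared/unique called-type sets, the unknown-assignment fraction per
strategy (computed over post-QC observations), and the focal-type
(podocyte) comparison: a two-sided Wilcoxon rank-sum on per-observation
signature scores plus the observation-count ratio.

On the synthetic cohorts, square binning shows a strictly higher unknown
fraction (mixed and spill-dominated bins fail dominance) and more
podocyte observations (a ~20 µm² nucleus plus its spill ring spans
several 16-spot bins). The score comparison deserves a caveat: synthetic
nucleus profiles are information-rich, so their score distributions are
tight, and the small genuine dilution of boundary-straddling square bins
is statistically detectable at these sample sizes even though the medians
are close. On shallow real data the same comparison is far noisier; the
package reports the test rather than asserting its outcome.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on simulated data at
desk scale: 150-nucleus tissues (112² pixels) for unit tests, the
1,000-nucleus default (256² pixels) for geometry and parameter-recovery
checks, 250-nucleus two-patient cohorts for integration properties, and
three-patient glomerulus-rich cohorts (1,000 nuclei per patient) for the
binning comparison. Every stochastic step is reproducible from a single
integer seed: the simulator consumes one seeded RNG stream, clustering
seeds Leiden explicitly, and internal randomized algorithms use fixed
seeds while restoring the caller's RNG state.

## Known limitations

* The center rule ignores partial spot–nucleus overlap; at 2 µm pitch the
  resulting misassignment is at most one spot ring per nucleus, but it is
  not modelled.
* Cell bodies extend beyond nuclei; nucleus binning deliberately trades
  transcript recovery for purity, and no cell-boundary expansion is
  provided.
* The anchoring integration is a reduced scheme: no reciprocal PCA, no
  label transfer, no per-anchor filtering beyond the shared-neighbor
  score.
* The unknown-call rule (floor + dominance) is a package definition;
  reported unknown fractions are comparable between strategies within a
  run, not across tools.
* Brute-force neighbour searches (`dist()`-based) bound practical problem
  sizes to a few thousand observations per dataset.
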