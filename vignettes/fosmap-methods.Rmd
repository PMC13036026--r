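---
title: "fosmap: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fosmap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What fosmap computes

fosmap is a desk-scale implementation of a whole-brain c-Fos mapping
workflow. The immediate early gene *c-Fos* accumulates in recently active
neurons, so counting immunolabeled c-Fos puncta per brain region, across a
cohort of animals, turns cleared-brain fluorescence volumes into a
region-by-animal table of activation densities that can be modeled
statistically. The package covers the computational chain downstream of
image acquisition and registration:

1. **Puncta detection** in 3D volumes with two complementary detectors,
   both deliberately biased towards over-detection;
2. **Consolidation** of duplicate detections with DBSCAN;
3. **Cell/non-cell classification** of each consolidated spot;
4. **Mapping** of cell coordinates through a deformation field onto a
   hierarchical atlas, and region-wise density aggregation;
5. **Inference**: random-forest region pre-selection, per-region factorial
   linear models with a mouse random intercept, variance-standardized
   effect sizes (Cohen's d) with confidence intervals, Benjamini-Hochberg
   FDR, and classification of regions as treatment-responsive with time
   and sex interactions.

A synthetic-data module generates every input the chain needs — toy
atlases, fluorescence phantoms with ground truth, deformation fields, and
cohorts with injected effects — so the whole pipeline is testable without
any imaging download.

# The detection model

Puncta are modeled as anisotropic Gaussian blobs: a c-Fos-positive nucleus
is roughly 5–10 um across, and the axial elongation of a confocal PSF at
high NA stretches it in z. The default blob scale is `c(4, 1.5, 1.5)` um
(z, y, x) at the acquisition spacing `c(5.33, 0.361, 0.361)` um.

`detectConventional()` computes a scale-normalized negated
Laplacian-of-Gaussian response and takes 26-connected local maxima above
`median + threshold_sd * robust SD` of the response, where the robust SD is
the median absolute deviation scaled by 1.4826. The default
`threshold_sd = 2` is intentionally low: the workflow's philosophy is that
missed cells are unrecoverable while false detections are cheap, because
the classifier stage removes them. `detectMatched()` computes normalized
cross-correlation with a Gaussian template and thresholds at a correlation
(default 0.5), which makes it independent of the intensity scale — it
recovers locally clear but globally dim puncta that a global threshold
loses, e.g. under spatially varying background. Both detectors return
sub-voxel, world-micrometre centroids (intensity-weighted means over a
1-sigma neighbourhood); all geometry is computed in micrometres, never in
voxels, because the grid is anisotropic.

`consolidateSpots()` merges the union of both detectors' outputs with
DBSCAN at `eps = 5` um and `min_samples = 1`. The 5-um radius matches the
validation criterion for deciding that two spots are the same cell; with
`min_samples = 1` every point is a core point, so consolidation is exactly
connected-component merging of the 5-um reachability graph and singleton
detections survive. Each cluster becomes one spot at the unweighted member
centroid with the maximum member intensity. No DBSCAN implementation for
point sets is available among the installed packages, so the package
carries a small grid-hashed implementation; it is exercised directly by
the idempotence and hand-centroid tests.

`matchSpots()` scores detections against ground truth by one-to-one
matching within a radius: among all matchings it maximizes cardinality and
then minimizes total distance (min-cost max-cardinality assignment, solved
by successive shortest augmenting paths on the sparse feasible-pair graph
after connected-component decomposition). Optimal rather than greedy
matching makes precision/recall/F1 well defined and independent of spot
order. F1 is computed as `2m / (n_pred + n_truth)`, which is algebraically
`2PR/(P+R)` but exact at boundary values such as 0.8.

# The classifier

Large-scale runs of this kind of workflow classify raw patches with a deep
network; at desk scale fosmap uses a random forest over seven deterministic
patch features with the identical contract (train / fine-tune / predict,
binary cell vs non-cell, probability threshold 0.5). The features are
designed against the three artifact classes the phantom generator renders:

* bright planes at volume edges — high `planarity` (fraction of patch
  energy in its brightest plane along any axis);
* autofluorescent vessel-like tubes — high `anisotropy` (ratio of extreme
  eigenvalues of the intensity second-moment matrix, in micrometre
  coordinates);
* single-voxel noise spikes — anomalous `contrast_ratio` and `local_sd`.

`fineTune()` refits on the original training set plus new examples
weighted x5 (by replication). The weighting is a design choice: a 50–200
example local sample must be able to move the decision boundary of a model
trained on thousands of examples without erasing it. The decision
threshold stays fixed at 0.5 rather than being tuned per brain, which
would leak the validation patch. Border-flagged spots are classified like
any other; the features carry the border distance.

`validateBrain()` applies the acceptance protocol: F1 within an annotated
ground-truth patch, at the 5-um matching radius, must strictly exceed 0.80;
otherwise the run is flagged for fine-tuning.

# Mapping and aggregation

`transformSpots()` adds a trilinearly interpolated displacement to each
sample-space coordinate (field direction is sample-to-atlas; the inverse is
deliberately unsupported). Spots outside the grid are clamped to the
border and flagged rather than dropped — registration edges are imperfect
and silent dropping would bias border regions. `assignRegions()` is
nearest-voxel label lookup; labels are categorical so no interpolation is
meaningful. Label 0 and out-of-volume spots stay unassigned: they count in
whole-brain totals but never in region statistics.

`aggregateRegions()` produces direct counts (exact label), cumulative
counts (plus all descendants), and density = cumulative count / annotated
region volume (cells/mm^3). The atlas is mirror-labeled, so left and right
counterparts of a structure are pooled automatically.
`buildDensityMatrix()` assembles per-animal results into a
`SummarizedExperiment` subclass with regions as rows (depth-first ontology
order, so column order is deterministic) and animals as columns; a region
with no spots is density 0, never missing.

`coronalHeatmaps()` splits the anterior-posterior axis into 1-mm slabs,
histograms cell positions at atlas voxel resolution, divides by the number
of animals, and smooths with a Gaussian kernel. The 100-um kernel width is
a visualization choice with no inferential role. Pre-smoothing slab mass
is exactly (spots in slab)/n_animals, and the renormalized kernel
conserves mass for content at least two kernel radii from the map borders.

# The inference stack

**Region pre-selection.** `selectRegions()` trains a random forest (300
trees) to discriminate treatment from the wide density table, reports
stratified k-fold cross-validated F1 (folds capped at the smaller class
size — a 27-animal cohort cannot always fill 10 stratified folds), refits
on all animals, and keeps regions with nonzero impurity importance.
Because parent and child structures have correlated densities, ancestors
of selected regions are then removed with `excludeParents()`. "Child on
the list" is read as *any* strict descendant, not only direct children;
this prevents a grandparent from surviving pruning when only its
grandchild carries signal, which is the multicollinearity rationale for
the rule. The result is an antichain in the ontology.

**Per-region model.** For each selected region, density is modeled with
full-factorial fixed effects treatment x time x sex (reference cell:
saline, 1 h, male, making the treatment main effect the morphine effect in
1-h males) and a random intercept per mouse. When every mouse contributes
exactly one row — the usual layout, since each animal yields one density
per region — the split between the intercept variance and the residual
variance is not identifiable; fosmap then fits by ordinary least squares
and reports the intercept variance as zero. This is safe because every
downstream quantity uses only the *sum* of the two components, which is
identifiable either way. When mice do repeat (e.g. stacked technical
replicates), the model is fit by REML via `lme4`.

**Effect sizes.** For a contrast vector c, `effectSizes()` computes
beta_c = c'beta, its Wald SE, and Cohen's d = beta_c / sqrt(sigma2_resid +
sigma2_intercept) — the fixed-effect contrast standardized by the combined
residual and random-intercept SD. The 95% CI on d is the Wald CI of beta_c
scaled by the same SD; the SD is treated as known, with no small-sample
correction, and p-values are two-sided normal tests. These are
deliberate, documented choices where t-based alternatives would also be
defensible; the parameter-recovery suite verifies that at the default
cohort design the CIs cover the truth at between 90% and 99%.

The eight reported contrasts are the four group morphine effects
(male/female x 1 h/4 h) and the treatment:time and treatment:sex
interactions at each level of the remaining factor; e.g. the female-4h
morphine effect is the sum of the treatment main effect and its three
interaction terms.

**Multiplicity and classification.** `bhFdr()` applies Benjamini-Hochberg
step-up adjustment (via `stats::p.adjust`), validated against the textbook
definition in the tests. FDR is controlled within each contrast family
across regions — not pooled across families — which is the conservative
reading of per-figure starring. A region is *responsive* when any group
contrast has |d| > 0.8 with a CI excluding 0; time and sex difference sets
apply the same rule to the interaction contrasts; stars mark q < 0.05 /
0.01 / 0.001. Effect-size reporting is deliberately primary and
significance secondary: with hundreds of regions and N = 27, FDR
correction is stringent, so large-effect regions are reported with their
CIs and the stars annotate which survive q < 0.05.

# The synthetic-data generator

`makeToyAtlas()` builds a mirror-labeled label volume (left and right
hemispheres share structure ids) partitioned into leaf slabs under a
3-level ontology, with volumes computed exactly from voxel counts.
`simulateVolume()` draws per-region Poisson counts (`rate x region volume`)
of Gaussian puncta with multiplicative size and intensity jitter, renders
the three artifact classes, and adds tissue background and Gaussian noise;
the truth table records every punctum and never an artifact.
`simulateCohort()` mirrors the inference model exactly: density = baseline
+ (injected d x total SD x design indicator) + mouse intercept + residual
noise. Because the injected effects are scaled by
`sqrt(sigma_mouse^2 + sigma_resid^2)`, the injected numbers *are* the
Cohen's d values the stats module should recover, which makes
parameter-recovery tests well posed. Negative densities are clipped at
zero with a warning.

The default cohort design is the 8-group factorial with group sizes
5/3/4/3 (morphine male-1h, female-1h, male-4h, female-4h) and 3/2/3/4
(saline), N = 27 (15 male, 12 female). Default variance components are
20% (between-mouse) and 30% (residual) of the mean baseline — fixture
choices, since per-group variance components are not published. Note that
with these proportional defaults an injected |d| of 2 moves a group mean
by ~0.72 baselines, so recovery simulations instead fix absolute SDs at
10%/15% of a 5000 cells/mm^3 baseline, keeping the baseline above five
total SDs and clipping negligible.

What the phantoms do *not* emulate: depth-dependent attenuation and
scattering, stitching seams, striped illumination, and real registration
error beyond synthetic warps. Passing the detection gate on phantoms
therefore demonstrates the pipeline's mechanics and its artifact
rejection, not performance on degraded real acquisitions.

# Numerical and design choices

* **Separable filtering.** All smoothing, box sums and template
  correlations are separable 1D passes implemented as sparse band-matrix
  products; truncated kernel rows are renormalized so a constant volume is
  exactly invariant under smoothing.
* **Foreground masking.** Otsu on a Gaussian-smoothed, 90th-percentile
  winsorized copy (winsorizing stops sparse bright puncta from dominating
  the histogram), then largest 6-connected component, then one-voxel
  dilation to recover the smoothing-eroded boundary. On volumes above ~2M
  voxels the connected-component step runs on an any-pooled downsampled
  grid; this only affects cleanup at the few-voxel scale. A degenerate
  volume yields an all-true mask with a warning.
* **Thresholds at machine precision.** The LoG threshold has an absolute
  floor of `1e-8 x max(smoothed)` so numerically flat volumes produce no
  maxima; an OLS residual variance below a relative tolerance is snapped
  to zero so degenerate inputs fail loudly in `effectSizes()` instead of
  standardizing by rounding noise.
* **World coordinates.** Voxel centers sit at `(index - 1) x spacing`;
  the origin is the first voxel center. Every file format documents axis
  order (z, y, x with z anterior-posterior).
* **Determinism.** Every stochastic stage takes a seed; fixing the seed
  fixes every output bit-for-bit, and the pipeline asserts this by
  checksum. Pipeline stages write JSON manifests with input checksums and
  are skipped when inputs are unchanged (resumability without a workflow
  engine).
* **Problem sizes.** The reference detection phantom is 100 x 512 x 512
  voxels at the anisotropic acquisition spacing with ~230 puncta at SNR 8;
  the classifier trains on a disjoint 60 x 256 x 256 phantom. Statistical
  suites use 200 replicates of the 27-animal design over 20 regions, plus
  200 global-null replicates. Unit tests run on smaller phantoms
  (~40 x 96 x 96) with the same parameters.

# Known limitations

* The per-region model treats regions independently; a joint model with
  region terms (with regions as repeated measures within mouse) is a
  plausible alternative reading and is not implemented.
* Wald/normal inference at N = 27 is mildly anti-conservative relative to
  t-based inference; the recovery suite bounds the practical effect
  (CI coverage stays within [0.90, 0.99]).
* The matched filter assumes the template scale; strongly size-variant
  puncta rely on the LoG detector and the classifier.
* Whole-brain density denominators use total annotated volume; whether
  white matter should be excluded from the denominator is left to the
  gray-matter flag.
* The generator's artifacts are stylized; the classifier's measured F1 on
  phantoms is an upper bound on what identical settings would achieve on
  real data.
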