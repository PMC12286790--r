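---
title: "APTw habitat radiomics: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{APTw habitat radiomics: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Lymphovascular space invasion (LVSI) in cervical cancer is decided today
from hysterectomy specimens — after surgery. Amide proton transfer-weighted
(APTw) MRI measures mobile protein/peptide content through chemical
exchange saturation transfer and is elevated in aggressive tumor tissue,
making it a candidate preoperative marker. The conventional reading —
three circular ROIs on the largest-diameter slice, averaged — collapses a
heterogeneous 3-D lesion to one number. *Habitat radiomics* instead
partitions the whole tumor into subregions ("habitats") with distinct
signal profiles, extracts a large handcrafted feature bank per habitat,
and compresses it into a single radiomic score under a strict,
leakage-controlled selection cascade.

This package implements that entire analysis as tested, reusable code,
and ships a synthetic phantom cohort generator so that every stage — and
the end-to-end claim that a combined clinical + habitat model outperforms
either source alone — can be exercised without any imaging download.

## APTw quantification

APTw contrast is the magnetization transfer ratio asymmetry at ±3.5 ppm
around water:

$$\mathrm{APTw}\% \;=\; \frac{S(-3.5\,\mathrm{ppm}) - S(+3.5\,\mathrm{ppm})}{S_0}\times 100$$

`compute_aptw_map()` evaluates this voxel-wise on the tumor mask. Offsets
are matched by nearest ppm within 0.05 ppm; voxels with non-positive
unsaturated signal are flagged and removed from the mask. No vendor-style
clipping is applied. The conventional comparator arm
(`measure_three_roi_mean()`) places three disjoint circles on the axial
slice of maximum in-mask extent (ties to the lowest slice index) by a
deterministic, seeded farthest-point rule, avoiding an exclusion mask
(necrosis/vessels).

## Habitat partitioning

Thirteen local descriptors are computed per in-mask voxel over a 3×3×3
window: mean, variance, skewness, kurtosis, min, max, range, energy,
8-bin entropy, and four co-occurrence terms (contrast, homogeneity,
correlation, energy). Two numerical choices matter and were made
deliberately:

* **Global gray-level binning.** The window co-occurrence and entropy
  terms are discretized over the whole-tumor intensity range, not the
  window's own min–max. Per-window normalisation makes these descriptors
  pure sampling noise with strong mutual correlation — k-means then
  spends clusters on that continuum instead of on the tissue structure.
* **Full windows only.** Voxels with fewer than 26 in-mask neighbours
  are excluded from clustering (truncated windows bias every
  scale-dependent descriptor and otherwise form a spurious "edge shell"
  cluster); they inherit labels afterwards by 26-connected majority
  propagation, so habitat labels still partition the mask. Masks with
  fewer than 32 full windows fall back to the 8-neighbour rule.

Each tumor is clustered independently (k-means++ seeding, 10 restarts,
Lloyd iterations, features z-scored within tumor) for K = 3..10, and the
Calinski–Harabasz index picks K (ties toward smaller K). Habitats are
relabelled in ascending mean-APTw order, which is what makes "h3" — the
highest-signal subregion — comparable across patients.

A caveat worth stating plainly: on graded, quasi-1-D signal structure the
CH index carries a parsimony bias (merging adjacent groups retains most of
the between-scatter while halving $k-1$), so it reliably returns small K.
Our phantoms reproduce the "consistently K = 3" behaviour for three
planted subregions, but CH never peaks at 5 for five planted subregions,
and we document this as a structural property rather than hiding it.

## Feature bank

Per habitat: 14 shape features (computed once — transforms change
intensities, not geometry), then per transform 18 first-order and 75
texture features (GLCM 24, GLRLM 16, GLSZM 16, GLDM 14, NGTDM 5, IBSI
formulations, 13-direction merged matrices in 3-D). The default bank has
20 members: original, 8 stationary Haar sub-bands, 5 Laplacian-of-Gaussian
scales (1–5 mm), gradient magnitude, square, square-root, logarithm,
exponential, and a 6-neighbour 3-D local binary pattern map — giving
14 + 20×93 = 1874 columns per habitat and 5622 for three habitats. (The
source study prints 1,834 per habitat alongside family counts that imply
1,874; we keep the arithmetic and note the discrepancy.)

Numerical conventions: population moments; non-excess kurtosis;
percentiles by linear interpolation (R type 7); fixed bin width 0.1
percent-units on the original image and fixed bin count 32 on filtered
images (their intensity scales are arbitrary), capped at 64 gray levels.
Surface area uses the coarea formula on the Gaussian-smoothed indicator
(σ = 0.7·min-spacing) — accurate to ~1% for blob-like lesions,
under-estimating sharp-cornered regions by up to ~15% — instead of a
marching-cubes mesh; sphericity and compactness inherit this estimator.

## Selection cascade and the radiomic score

ICC filter (two-way random effects, absolute agreement, single
measurement; keep ICC ≥ 0.85 against a second-reader table) → within-fold
z-scoring → Welch t-test (p < 0.05) → greedy correlation pruning (drop
the weaker-association member of any pair with |r| > 0.9; ties drop the
lexicographically later name) → mRMR (greedy difference criterion;
relevance is the ANOVA F rescaled to η² = F/(F+df₂) so it is commensurate
with the |r| redundancy term — with raw F the penalty would be
numerically irrelevant) → LASSO logistic regression with 10-fold
stratified CV, λ at the CV deviance optimum. The radiomic score is the
linear predictor of the surviving features; feature count never increases
across stages, and the whole cascade is deterministic given its seed.

## Models and leakage control

Three logistic models: clinical-radiological (CA125 + tumor size), the
radiomic score alone, and the combination. Evaluation uses outer
stratified 5-fold CV; inside each outer training fold the *entire*
cascade is refit (including z-score parameters and ICC survival), an
inner CV tunes an L2 strength over a small grid (including an
effectively-unpenalised value), and held-out patients are scored once.
Pooled out-of-fold predictions give each model a single ROC; a full-data
refit of the cascade is also reported and labelled as such. The
leakage-free mode is the default; a global-filter mode
(`leakage_free = FALSE`) reproduces the common pre-CV filtering reading
for comparison. The leakage sentinel — permuting labels must drive
held-out AUC to ~0.5 — is part of the acceptance suite.

## Evaluation machinery

AUC by midranks; DeLong structural-components variance for single-AUC
z-tests (the per-model "z"/"p" rows are against AUC = 0.5), CIs, and
correlated-AUC comparisons; Youden-optimal thresholds with ties to the
lowest threshold and "score ≥ threshold ⇒ positive" orientation;
confusion-metric algebra from integer counts (rounding expected counts to
integers reproduces published accuracy/NPV/PPV/Youden values exactly);
ICC(2,1) with McGraw–Wong F-based CIs and Bland–Altman limits;
Mann–Whitney U (exact for ≤8 per group without ties) and χ² (no Yates
correction by default) for the baseline table.

## The synthetic cohort: what it emulates, and what it does not

Defaults state a world modelled on the published cohort: n = 124, 40%
LVSI-positive (exact split — the logistic label model is conditioned on
the margin), whole-tumor APTw class means ≈ 2.4% vs ≈ 4.4%, ADC
anti-correlated with APTw, CA125/BMI/age/tumor-size drawn from log-normal
distributions matched to the published medians and IQRs, and a latent
"aggressiveness" factor linking the high-APTw habitat fraction and the
laboratory values. Tumors are ellipsoids with an optional necrotic core;
habitats are grown from farthest-point seeds by a fraction-steered
weighted Voronoi rule, ordered spatially so only adjacent signal levels
touch; the mean field is a terraced (smoothed) staircase whose
nearest-plateau bands define the planted ground truth; voxel noise is
uniform with a per-habitat SD ladder (0.45 × 1.7^(k−1) percent) so
subregions differ in textural heterogeneity as well as level; the
LVSI class contrast is spread nearly uniformly across habitats
(profile ratio 1.15, 1.40% tumor-average shift — concentrating it in one
subregion sharpens that subregion's interfaces and destabilises the
K = 3 selection); a per-patient common APTw offset (SD 1.2%) supplies
between-patient variability, and a small independent per-habitat jitter
(SD 0.15%) bounds how precisely inter-habitat feature contrasts can
cancel that offset — without the jitter the selection cascade denoises
the radiomic score into a near-perfect separator. One published detail
is deliberately not reproduced: the all-13-features-from-h3 exclusivity.
In this stated world h3 features rank highest marginally, but the mRMR
redundancy step mixes habitats by design; the tests assert h3
participation and plurality-level dominance instead. The clinical
pathway (CA125, tumor size) enters the label model mostly through
covariate components independent of the imaging channel, so the
combined model's advantage over the radiomic score is structural rather
than accidental.

What a green test does *not* establish: realistic MR physics (no B0/B1
inhomogeneity, motion, partial-volume anatomy), realistic cervix anatomy,
or the actual clinical effect sizes — the model ordering
(combined > habitat score > clinical, DeLong p < 0.05) is reproduced as a
property, not the printed AUCs, which belong to a private cohort.

Known limitation, stated rather than patched: voxels whose 3×3×3 window
straddles a habitat interface are intrinsically ambiguous. Hiding that
shell from the clusterer requires noise comparable to half the
inter-habitat contrast, which then randomises the shell's assignment;
the two constraints cap planted-partition recovery (adjusted Rand index)
near 0.85 at desk-scale phantoms — below the 0.9 acceptance bar, which
we leave red with this analysis rather than weaken.

## Reproducibility

Every stage is a deterministic function of the single pipeline seed,
which fans out to per-stage seeds; rerunning an identical configuration
is bit-identical. Artifacts (NIfTI volumes, CSV tables, JSON reports) are
written with a manifest of checksums, and the CLI stages
(`simulate`, `aptw`, `habitat`, `features`, `select`, `fit`, `evaluate`,
`run`) chain through a run directory so the pipeline can be reproduced
piecewise.
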