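# aptwhabitat

Habitat radiomics on amide proton transfer-weighted (APTw) MRI, built
around the preoperative prediction of lymphovascular space invasion
(LVSI) in cervical cancer — as a tested, reusable, leakage-controlled R
package.

## Who this is for

Imaging scientists who want the full habitat-radiomics analysis chain as
auditable code: APTw quantification from z-spectra, whole-tumor habitat
partitioning, IBSI-style feature extraction over an image-transform
bank, a strict feature-selection cascade producing a linear radiomic
score, nested cross-validated logistic models, and the ROC/DeLong/Youden
reporting surface of a clinical imaging paper. A synthetic phantom
cohort generator with planted ground truth makes the whole pipeline
testable end to end — no imaging download, no PHI.

## The core quantities

APTw contrast is the magnetization transfer ratio asymmetry at
±3.5 ppm:

    APTw% = (S(−3.5 ppm) − S(+3.5 ppm)) / S0 × 100

Each tumor is partitioned into habitats by k-means on 13 voxel-level
window descriptors, with the cluster count chosen by the
Calinski–Harabasz index CH = [tr(B)/(k−1)] / [tr(W)/(n−k)] over
K = 3..10, and habitats ordered by mean APTw (so "h3" is the
highest-signal subregion). Per habitat, 14 shape + 20×(18 first-order +
75 texture) = 1874 features feed the cascade

    ICC ≥ 0.85 → z-score → Welch t-test (p < 0.05)
      → correlation pruning (|r| > 0.9) → mRMR → LASSO (10-fold CV)

whose surviving coefficients define the radiomic score
score = β₀ + Σ βᵢ·zᵢ. Three logistic models (CA125 + tumor size; the
score; both) are compared under stratified 5-fold nested CV with the
DeLong test, with the entire cascade refit inside every training fold.

## Worked example

```r
library(aptwhabitat)

# a 12-patient phantom cohort with planted habitats and clinical records
coh <- generate_cohort(cohort_config(n_patients = 12, seed = 7))
coh
#> <phantom_cohort: 12 patients, 5 LVSI+ / 7 LVSI->

p <- coh[[1]]
fmap <- extract_voxel_features(p$volume_aptw, p$mask)
hm <- select_habitats(fmap, p$volume_aptw, seed = 1)
hm
#> <habitat_map: K = 3 (CH-selected), sizes 61/157/293, mean APTw 3.95 < 4.58 < 5.01>

# conventional three-ROI reading, two readers
rr <- simulate_two_readers(p, seed = 3)
rr$reader1
#> three-ROI measurement on slice 11: 4.854, 3.174, 5.244 -> mean 4.424

# end-to-end pipeline (simulate -> habitats -> features -> cascade ->
# nested CV -> evaluation); n = 124 takes ~9 minutes on one CPU
res <- run_pipeline(pipeline_config(seed = 42))
res$comparison
#> model comparison (pooled out-of-fold):
#>                  model   auc threshold sensitivity specificity accuracy youden
#>  clinical_radiological 0.726     0.422        0.72       0.730    0.726  0.450
#>                aptw_h3 0.922     0.448        0.88       0.851    0.863  0.731
#>               combined 0.930     0.308        0.92       0.784    0.839  0.704
#> DeLong pairwise:
#>                 model1   model2     diff      z        p
#>  clinical_radiological  aptw_h3 -0.19676 -3.926 8.63e-05
#>  clinical_radiological combined -0.20432 -4.533 5.83e-06
#>                aptw_h3 combined -0.00757 -0.807 4.20e-01
```

The combined model's pooled out-of-fold AUC exceeds the radiomic-score
model, which exceeds the clinical model — the published ordering,
reproduced as a property of the calibrated synthetic world — and the
combined-vs-clinical DeLong comparison is significant. The per-patient
radiomic score is dominated by features from the highest-APTw habitat
(h3), mirroring the published selection.

## Command line

```sh
Rscript inst/cli/aptwhabitat simulate --seed 3 --out runs/demo
Rscript inst/cli/aptwhabitat habitat  --seed 3 --out runs/demo
Rscript inst/cli/aptwhabitat features --seed 3 --out runs/demo
Rscript inst/cli/aptwhabitat select   --seed 3 --out runs/demo
Rscript inst/cli/aptwhabitat fit      --seed 3 --out runs/demo
Rscript inst/cli/aptwhabitat evaluate --seed 3 --out runs/demo
# or everything at once:
Rscript inst/cli/aptwhabitat run --seed 3 --out runs/demo
```

## Acceptance

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch: the exact confusion-metric algebra implied by
the published operating points (50 LVSI+ / 74 LVSI−), the DeLong
type-I-error calibration, planted-habitat recovery summaries, and the
n = 124 pipeline model-ordering AUCs (runtime ≈ 12 minutes, dominated by
the pipeline stage).

Two acceptance tests are intentionally red, with the analysis in the
methods vignette: planted-partition ARI > 0.9 (window-support interface
ambiguity caps ARI near 0.85 at desk-scale phantoms) and planted K = 5
recovery (the Calinski–Harabasz index structurally prefers small K on
graded signal ladders — which is also a plausible reading of why real
cohorts report "consistently K = 3").

## Layout

- `R/` — volume + NIfTI-1 I/O, APTw quantification, habitat
  segmentation, feature bank, selection cascade, modeling, evaluation,
  pipeline, CLI
- `src/` — Rcpp kernels: sliding-window voxel descriptors and
  GLCM/GLRLM/GLSZM/GLDM/NGTDM count matrices
- `vignettes/habitat-radiomics-methods.Rmd` — models, assumptions,
  numerical choices, limitations
- `tests/testthat/` — unit, property and acceptance suites (oracle-based)
- `scripts/acceptance.R` — the acceptance report
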