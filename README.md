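# voxdose

Voxel-based modeling of radiotherapy dose and nutritional toxicity in head
and neck cancer.

Radiotherapy for head and neck cancer irradiates the swallowing apparatus —
the pharyngeal constrictor muscles (PC) and the larynx — and many patients
end up needing nutritional support: a feeding tube, or >10% weight loss
from baseline within 90 days of completing treatment (the composite
**FT/WL** endpoint). Conventional plan evaluation relies on dose-volume
histogram (DVH) metrics, which assume every part of an organ is equally
radiosensitive. `voxdose` asks the spatial question instead: *which
subregions of these organs drive the outcome?*

The package implements the full analysis as a reusable, tested pipeline:

1. **Synthetic cohort generator** — reference organ anatomy, per-patient
   smooth anatomical deformations, analytic dose distributions
   (prescriptions 30–81.6 Gy, lateralization coupled to the `bilateral`
   covariate), clinical covariates with study-like marginals, and FT/WL
   outcomes drawn from a known logistic truth model driven by the mean dose
   to a **planted subregion** (default: the superior third of the PC):

   p = logistic( b₀ + b_dose·(D̄_planted − 18 Gy) + Σⱼ bⱼ·(xⱼ − x̄ⱼ) )

   Real cohorts of this kind are protected health information; the planted
   truth makes every downstream claim testable — the pipeline must
   rediscover the subregion from images and outcomes alone.
2. **Spatial normalization** — contour-driven rigid + affine +
   demons-style deformable registration on signed distance transforms,
   Dice QC (> 0.7 gate), pull-back dose warping into the reference frame,
   left-right flip augmentation (the organs are midline structures).
3. **Dosimetry** — proton RBE scaling (×1.1, applied exactly once),
   cumulative DVHs, VxGy metrics (inclusive threshold), mean and regional
   doses.
4. **Voxel models** — ridge logistic regression on per-voxel dose
   (standardized on the training set only), stratified 80/20 split, 5-fold
   cross-validated penalty tuning, coefficient maps as spatial feature
   importance.
5. **Aggregate models** — univariate logistic screen (ORs, Wald CIs,
   p-values), clinical-only / DVH-metrics / regional-dose ridge models,
   repeated trials, permutation feature importance, two-tailed Wilcoxon
   model comparison.
6. **Pipeline + CLI** — one JSON config, derived seeds everywhere,
   manifest with checksums; reruns are byte-identical.

## Worked example

Generate a 120-patient cohort with the default planted superior-PC signal,
screen the covariates, fit the PC voxel model with flip augmentation, and
ask both methodologies where the signal lives:

```r
library(voxdose)

co   <- generate_cohort(120, cohort_config(shape = c(64, 64, 80),
                                           volumes = FALSE), seed = 42)
clin <- clinical_table(co)
y    <- setNames(clin$outcome, clin$id)

univariate_screen(clin, y, c("treatment_setting", "bilateral",
                             "chemotherapy", "baseline_weight", "adi",
                             "dysphagia_grade0", "gender",
                             "modality_proton", "smoker", "age"))
#           variable   or       p
#          bilateral 5.46 2.1e-05
#   dysphagia_grade0 0.30 3.6e-03
#  treatment_setting 2.68 1.2e-02
#             gender 3.55 1.4e-02
#       chemotherapy 1.94 9.5e-02
#                adi 1.01 9.8e-02

fm  <- truth_feature_matrix(co, "pc")              # cohort x PC-voxel dose
fmf <- truth_feature_matrix(co, "pc", flip = TRUE) # mirrored copies
vm  <- fit_voxel_model(fm, y, fm_flipped = fmf, seed = 7)
# voxel model: lambda 1526.4, CV AUC 0.78 +/- 0.10, test AUC 0.76

importance_summary(vm$coefficient_map, co$partition)
# pc_superior_midline pc_superior_lateral pc_middle_midline ... (8 regions)
#                   0                   1                 0 ...
```

Every one of the top-5% |coefficient| voxels lands in the planted superior
third. The validation methodology agrees — permuting each of the 8
regional mean doses in turn, the largest AUC drop belongs to a superior PC
region:

```r
fml <- truth_feature_matrix(co, "larynx")
reg <- features_regional_table(fm, fml, co$partition)
permutation_importance(reg, y, n_reps = 25, seed = 3)
#              feature mean_auc_loss  p_value
#  pc_superior_lateral       -0.3741 1.33e-09
#    pc_middle_lateral       -0.1108 1.33e-09
#    pc_middle_midline       -0.0589 2.15e-09
```

The univariate odds ratios recover the planted directions (bilateral
treatment and primary setting increase risk, baseline dysphagia grade 0
is protective), the voxel map localizes the planted subregion, and the
permutation ranking confirms it with 14 features instead of thousands.

The full pipeline — cohort NIfTI/CSV export, registration with QC,
DVH metrics, both organ voxel models, the three aggregate models, the
importance tables and a markdown report — runs from one config:

```r
cfg <- run_config(seed = 1, n = 60, out = "run1")
run_pipeline(cfg)
report("run1")           # run1/report.md + ROC and coefficient-map PDFs
```

or from the command line (`inst/cli/voxdose`):

```sh
voxdose synth --n 60 --seed 1 --out cohort/
voxdose register --cohort cohort/ --organ pc --out norm/
voxdose dvh --cohort cohort/ --out metrics.csv
voxdose run --config run.json
```

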