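---
title: "voxdose: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voxdose: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Radiotherapy for head and neck cancer inevitably irradiates the swallowing
apparatus — the pharyngeal constrictor muscles (PC) and the larynx — and a
large fraction of patients end up needing nutritional support: a feeding
tube, or they lose more than 10% of their baseline weight within 90 days of
finishing treatment (the composite FT/WL endpoint). Treatment plans are
conventionally evaluated through dose-volume histograms (DVHs), which
collapse the 3D dose distribution inside an organ into a curve and
implicitly assume every part of the organ is equally radiosensitive.

`voxdose` implements a voxel-based alternative: map every patient's organs
into a common reference frame with deformable registration, carry the dose
along, and let an L2-penalized (ridge) logistic regression on the per-voxel
doses reveal *which subregions* of the organ drive the outcome. A second,
low-dimensional methodology — ridge models on aggregated regional mean
doses and on clinical DVH metrics, with permutation feature importance —
validates the subregions found by the voxel models with far fewer degrees
of freedom.

Real cohorts of this kind are protected health information, so the package
ships a synthetic cohort generator with a *planted* radiosensitive
subregion. Every stage of the analysis is therefore testable end to end:
the pipeline must rediscover, from generated images and outcomes alone, the
subregion the generator used to produce those outcomes.

## The synthetic world

`make_reference()` builds a reference anatomy on a regular grid (default
96×96×120 voxels at 1.27×1.27×1 mm; tests use the 64×64×80 smoke grid): the
PC stand-in is a curved posterior half-annular shell about 3.6 mm thick,
48 mm tall, widening superiorly; the larynx stand-in is an ellipsoid
(semi-axes 13×10×17 mm) sitting anterior-inferior, overlapping the caudal
PC z-range. Both are exactly midline-symmetric, which is what justifies
left-right flip augmentation downstream.

`sample_patient()` draws, per patient:

* **Anatomy** — a global affine jitter (rotation up to ±4° about z,
  per-axis scale 0.95–1.05, translation ±3 mm) plus a band-limited random
  displacement field: white noise smoothed with a Gaussian of σ = 12 mm and
  scaled to a per-patient maximum amplitude of up to 8 mm. The field is
  generated on a 4× coarser grid and trilinearly upsampled, which is
  equivalent for a field this smooth and much cheaper. The forward field w
  maps reference voxels into patient space; patient masks are materialized
  through its fixed-point-inverted map, and w itself is stored compactly
  (affine parameters + coarse noise grid) on the case so an *exact*
  normalization is always recoverable.
* **Dose** — one Gaussian-falloff high-dose target (two mirrored ones when
  the `bilateral` covariate is 1, combined by voxelwise max so the peak
  equals the prescription), centered anywhere along the pharyngeal column
  (as in a cohort spanning oropharynx to larynx primaries), lateralized by
  8–20 mm, with σ of 14–24 mm in-plane and 8–16 mm axially. Prescriptions
  are uniform on 30–81.6 Gy.
* **Covariates** — marginals anchored to the emulated study population
  (e.g. 37% primary treatment setting, 68% chemotherapy, 43% proton, ADI
  mean 45, age mean 61); joint dependence is not modeled except that
  `bilateral` deliberately couples to dose laterality, reproducing the
  confounding that makes flip augmentation meaningful.

`assign_outcome()` draws the FT/WL outcome from the logistic truth model

  p = logistic( b0 + b_dose (D̄ − 18 Gy) + Σ_j b_j (x_j − x̄_j) )

where D̄ is the mean RBE-scaled dose to the *planted subregion* (default:
the superior third of the PC), b_dose = 0.15 per Gy, and the covariate
log-odds are the log odds ratios of the emulated population (bilateral
log 6.72, treatment setting log 4.62, chemotherapy log 2.54, dysphagia
grade 0 log 0.51, weight and ADI log 1.014 per unit, and so on). Centering
at the sampling means (18 Gy is the pilot-cohort mean planted dose, a
one-off calibration) makes the intercept (0.1) control prevalence directly:
cohorts land near the study-like prevalence of ~0.5. Feeding-tube events
and longitudinal weight records are then constructed to be *consistent*
with the drawn outcome under the endpoint rule, so the endpoint extractor
is exercised honestly end to end.

What the generator does **not** emulate: CT intensities (registration is
contour-driven by design), realistic fractionation or beam physics (dose is
a smooth analytic field), organ-specific motion, or dependence between
clinical covariates. A green recovery test therefore establishes that the
*analysis machinery* localizes a planted signal under smooth anatomical
variability and realistic confounding — not that the method would perform
identically on clinical images.

## Spatial normalization

Masks are registered to the reference on **signed distance transforms**
(binary images give vanishing gradients), clamped at ±20 mm: a
moments-based rigid stage (centroid alignment), a principal-axes affine
stage (symmetric square-root covariance matching), then a multi-resolution
demons-style stage (40 iterations at half resolution, 10 at full;
per-iteration step cap 3 mm; Gaussian regularization σ = 2 mm of the
*increment only*, so smoothing cannot corrupt the affine base). After every
stage the Dice of the warped mask is evaluated and the stage kept only if
it improves — the final field can never be worse than the initial overlap,
which makes the "registration never degrades" contract structural rather
than statistical. QC applies the Dice > 0.7 gate; failing cases are flagged
and excluded from modeling with a logged count, never silently dropped.

Displacement fields use one fixed **pull-back convention** — for each
reference voxel, where to sample the moving volume — so "apply the same
deformation to the dose" is a single, well-defined operation (`warp()`,
trilinear for dose, nearest for masks, out-of-bounds filled with 0 and
counted). The two organs are registered independently, and flip-augmented
copies are registered to the (unflipped) reference in the same manner as
the originals.

For synthetic cohorts a `"truth"` normalization mode uses the generator's
own forward field instead of estimating one. The model-recovery tests use
it deliberately: they test the *models*, registration accuracy has its own
contract (and on default-amplitude cohorts the estimated registrations
reach mean Dice ≈ 0.94).

## Dosimetry

Proton doses are scaled by exactly 1.1 (RBE), enforced to happen once via a
`"rbe_scaled"` flag. VxGy uses the inclusive convention (percent of organ
volume with dose ≥ x). The DVH feature set is the seven-metric clinical
set: mean PC and larynx dose, PC V50/V55/V60, larynx V50/V60 (PC V65
available behind `include_v65` — the source material is internally
inconsistent about it, and the methods text wins). DVH metrics are computed
in the patient frame on the RBE-scaled dose; default DVH bin width is
0.1 Gy, finer than any metric threshold gap.

## Ridge modeling

All models are ridge logistic regressions solved by `glmnet`
(`alpha = 0`, `standardize = FALSE`, convergence threshold 1e-8). Features
are standardized to training-set mean 0 / sd 1 (population denominator)
with parameters estimated *inside each CV fold's training part*; held-out
rows always use training parameters; zero-variance columns map to 0 and
are retained so voxel-column alignment never shifts.

* **Splits** — 80/20, stratified by outcome (plain random splits produce
  single-class test sets at desk scale); the same split serves both organ
  models. Flip-augmented rows inherit their source patient's assignment and
  appear in training (and within-CV training parts) only — never in
  validation or test rows — so a patient and its mirror can never leak
  across a boundary.
* **Penalty tuning** — 50 penalties, log-uniform on [1e-4, 1e4], chosen by
  stratified 5-fold cross-validated AUC. The aggregate models take the AUC
  maximizer. The voxel models use the **one-standard-error rule** (largest
  penalty within one SE of the best mean AUC): across that range the CV AUC
  is nearly flat, but the coefficient map changes character completely —
  near the AUC maximizer ridge begins to decorrelate the spatially
  correlated voxel columns and the map fragments, while the 1-SE penalty
  yields the spatially coherent importance maps the method exists to
  produce (the same motivation that led to ridge over L1 in the first
  place). This is the package's one deliberate deviation from "take the
  argmax".
* **Wide-data reduction** — for p ≫ n (voxel matrices), the fit is
  performed on the thin-SVD scores Z = UD with β = Vγ. With an unpenalized
  intercept and a pure L2 penalty this is *exactly* equivalent (the
  solution lies in the row space of X; the orthogonal complement is
  penalized but does not affect the likelihood), verified in tests against
  the direct fit, and orders of magnitude faster.
* **Evaluation** — AUC is the rank-based (Mann-Whitney) statistic, ties
  counting 1/2, so a constant predictor scores exactly 0.5; accuracy and F1
  use the positive class FT/WL = 1 at threshold 0.5.

Coefficient maps place the standardized-scale coefficients back at their
reference-grid voxels (zeros outside the organ). `importance_summary()`
reports, for the top q% (default 5%) of voxels by |coefficient|, the share
falling in each of the 8 subregions.

## Aggregate models and inference

The univariate screen fits one logistic regression per covariate and
reports odds ratios with Wald 95% intervals and p-values (complete
separation is flagged and the interval reported unbounded). Selection is
strict p < 0.05; ties at the boundary are excluded. On degenerate small
cohorts where nothing passes, the pipeline falls back to the six smallest
p-values (logged) so downstream stages remain defined — at the default
cohort sizes the screen selects the six planted-signal covariates.

The subregion partition splits the PC into equal-extent cranio-caudal
thirds of its spanned z-slices, crossed with midline vs lateral
(|x − x_mid| ≤ 10 mm, configurable — the boundary is not derivable from
the source figures), and the larynx into a superior (top third of its
z-extent, configurable) vs inferior region: 8 regional mean doses. Feature
tables are 6 (clinical) / 6+7 (DVH) / 6+8 (regional).

`repeated_trials()` reruns split → tune → fit → test-AUC/F1 under fresh
stratified splits (50 by default). `permutation_importance()` draws, per
repetition, a stratified 5-fold partition, fits on intact training parts at
a penalty tuned once, and permutes one feature at a time *within the
validation part* — measuring reliance without retraining; by default every
repetition resamples its folds. Signed mean ΔAUC (permuted − intact;
negative = drop) ranks the features; a two-tailed Wilcoxon rank-sum test
compares the permuted and intact AUC samples. Model comparisons use the
same Wilcoxon convention with the normal approximation and no continuity
correction, so identical samples give p exactly 1 and fully separated
n = 50 samples give p < 1e-10.

## Reproducibility

Every source of randomness flows from one master seed through named
substreams (`derive_seed()`, a multiplicative string hash modulo 2³¹−1), so
any stage can be re-run in isolation and two runs of `run_pipeline()` with
the same config produce byte-identical CSV/JSON tables and voxel-identical
NIfTI outputs; the manifest records md5 checksums of every artifact and is
itself path-independent. Configs serialize to JSON (no YAML parser is
assumed in the environment). NIfTI-1 I/O is a minimal self-contained
reader/writer (float64, diagonal sform; the package's fixed axis
convention makes reorientation unnecessary).

## Limitations

* The generator's dose model is a smooth blob; real dose gradients near
  targets are sharper, and registration of contour surrogates cannot see
  intensity detail. The QC floor (Dice > 0.7), not voxel-accurate warping,
  is the contract.
* Outcome truth is a single logistic index of one subregion's mean dose;
  real toxicity is plausibly multi-regional and nonlinear.
* The study-scale headline numbers (AUCs near 0.85, Dice 0.80/0.84, the
  odds-ratio table) belong to a protected cohort and are not reproduction
  targets; all acceptance checks are property-based on the synthetic world.
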