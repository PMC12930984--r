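---
title: "Quantifying and classifying brain-MRI defacing quality"
author: "defacingQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and classifying brain-MRI defacing quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defacingQC)
```

## The problem

A head MRI contains a face. Rendered in 3D, that face can be matched to a
photograph, so shared neuroimaging data is routinely *defaced*: the nose,
eyes, mouth and surrounding superficial tissue are removed from the volume.
Defacing tools fail in characteristic ways — residual eyelids or nasal
tips, near-global low-amplitude intensity perturbations, or accidental
clipping of brain tissue — and checking thousands of defaced scans by eye
does not scale. defacingQC turns the check into a supervised
classification problem: given an original/defaced scan pair, extract
features that quantify what defacing changed, and predict whether the
result still carries an identifiable face.

## Feature model

**Preprocessing.** Both scans are reoriented to a fixed RAS
(right/anterior/superior) axis order so "the direction the face points" is
well defined, and intensities are min–max normalized to $[0,1]$. The head
mask is the set of voxels with normalized intensity above a threshold
$\tau$ (default 0.03), which removes background noise. A constant volume
normalizes to all zeros (and hence an empty head mask) rather than
erroring, so degenerate inputs flow through the pipeline.

**Volumetric measures.** With head mask $M_h$ (from the original scan, so
the denominator is not itself perturbed by defacing) and a supplied brain
mask $M_b$:

* *impacted voxels*: $100\,|\{x \in M : |I_o(x) - I_d(x)| > \varepsilon\}| / |M|$,
* *removed voxels*: $100\,|\{x \in M : I_o(x) \neq 0 \wedge I_d(x) = 0\}| / |M|$,

each computed for $M_h$ ("head loss") and $M_b$ ("brain loss"), plus the
brain-to-head ratio $|M_b|/|M_h|$ as a mask-quality indicator. The
difference and zero tests run on the **raw**, orientation-aligned
intensities rather than the normalized ones: per-volume min–max
normalization exactly cancels a global additive perturbation (the minimum
shifts with the data), and a defacer that nudges every voxel by a constant
must register as 100% impacted, not 0%. The tolerance $\varepsilon$
defaults to 0 — any change counts — and exists because floating-point
round-trips through files can introduce spurious differences.

**Surface views.** Each scan is rendered from five standardized
perspectives — frontal, left/right profile, left/right 45° — by
orthographic first-hit ray casting: rays parallel to the view direction
(the anterior axis rotated about the superior axis by the view azimuth)
march through the grid at half-voxel steps, and each pixel takes the
intensity of the first head-mask voxel hit, 0 if none. The image plane is
scaled to the volume bounding box with square pixels, so original and
defaced views align. There is no lighting model: the pixel value is
strictly a function of the data, the renderer is deterministic, and
left/right view pairs of a symmetric head are exact mirror images (a test
asserts this bit-for-bit). Default resolution is 256×256; the test suite
renders at 64×64, which is sufficient for the metrics and much faster.

**Similarity metrics.** For each of the five view pairs we compute RMSE,
PSNR, SSIM and FSIM, and average each metric over the views (the package
also offers worst-view aggregation). All metrics operate on the float
renders with dynamic range $L = 1$:

* PSNR $= 20\log_{10}(L/\mathrm{RMSE})$, capped at 100 dB so identical
  images produce a finite feature.
* SSIM uses Gaussian-windowed local statistics ($\sigma = 1.5$, width 11,
  $C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$, population covariance), evaluated
  on the valid interior and averaged. This matches the reference
  configuration of scikit-image's `structural_similarity`, which the test
  suite uses as an independent oracle at $10^{-6}$.
* FSIM combines phase congruency (log-Gabor bank, 4 scales × 4
  orientations, minimum wavelength 6, multiplier 2, $\sigma_{onf}=0.55$,
  with the conventional noise-energy compensation) with Scharr gradient
  magnitudes; per-pixel similarities are pooled weighted by
  $\max(PC_1, PC_2)$. The contrast constants $T_1 = 0.85$, $T_2 = 160$
  follow the conventional 8-bit parameterization; inputs are rescaled
  internally. Only the luminance channel exists here, so the chrominance
  extension is omitted. A second, independently written NumPy
  implementation of the same published algorithm serves as the test
  oracle at $10^{-3}$ (observed agreement is ~$10^{-15}$). Constant
  images carry no phase congruency; identical constants define FSIM = 1,
  otherwise the unweighted mean of the similarity map is used.

## Classification

The feature table couples the four similarity metrics, three volumetric
measures (head loss, brain loss, BHR — the removal-centric subset; all
five volumetric quantities are computed and emitted), and four one-hot
defacing-method indicators: 11 features. Four model families are
supported: ridge logistic regression (glmnet), a single-hidden-layer
perceptron (nnet), random forest (ranger) and gradient boosting
(xgboost). Linear and neural models are standardized with statistics from
their own training data; tree models use raw features.

Evaluation uses **nested stratified group k-fold cross-validation**
(default 5 outer × 3 inner folds). Subjects contribute several scans, and
scans of one subject resemble each other, so all scans of a subject are
confined to one fold — otherwise the outer estimate leaks. Folds are
built greedily: subjects, largest first, are assigned to the fold that
minimizes the class-balance deviation with a mild size penalty. The inner
loop tunes each model's small hyperparameter grid by mean inner AUROC;
the winner is refitted on the full outer-training set and evaluated on
the held-out fold; metrics (accuracy, sensitivity, specificity,
precision, AUROC — positive class = *insufficiently defaced*, because the
privacy failure is the event of interest) are averaged with sd over outer
folds. AUROC is the tie-corrected rank statistic; a single-class outer
fold leaves it undefined, which is recorded as missing and excluded from
the mean with a warning. The grids are deliberately small (regularization
strength, hidden width/decay, mtry, tree depth): they exist to exercise
the nested protocol, not to squeeze out performance.

**Feature selection.** Permutation importance (mean AUROC drop on the
outer test fold over seeded shuffles, averaged across folds, computed for
the tree ensembles) is combined with average-linkage hierarchical
clustering of Spearman correlations at distance $1 - |\rho|$ (cluster
threshold 0.2, i.e. $|\rho| > 0.8$). Each iteration drops features for
one reason at a time, redundancy first: clusters keep only their
highest-importance member; once no cluster remains, features below the
importance floor (0.005 AUROC drop) go. A reduction is kept if the mean
outer AUROC does not decrease; because the fold-mean AUROC of a
stochastic learner is itself noisy, "does not decrease" is judged with a
tie tolerance (default 0.01) on identical outer folds across iterations.
Otherwise the reduction is reverted and the loop stops — which is a valid
outcome: on cohorts where similarity and volumetric features carry
complementary signal, the optimal subset *is* the full set.

**Rater agreement.** `raterAgreement()` reports percent agreement and
Cohen's $\kappa = (p_o - p_e)/(1 - p_e)$ with $p_e$ from the product of
marginal label frequencies, per group if requested. When $p_e = 1$ (both
raters constant on the same label) $\kappa$ is defined as 1 for perfect
agreement and 0 otherwise, with a warning.

## The synthetic phantom cohort

Clinical registries cannot ship with a package, so the test substrate is
generated: an ellipsoidal head (~30/36/38% of the grid per semi-axis)
with an interior brain ellipsoid (BHR ≈ 0.35) and four facial features —
nose, two eyes, mouth — as parameterized protrusions on the anterior
surface. Tissue intensities are piecewise constant (head 0.55, features
0.70, brain 0.85) plus Gaussian noise (default $\sigma = 0.02$) inside
the head; the background is exactly zero so the τ = 0.03 head mask is
stable. Per-subject shape jitter (2% relative sd) is shared across a
subject's scans — this within-subject correlation is what makes the
group-fold constraint worth testing — while acquisition noise is
redrawn per scan.

Simulated defacing mirrors the observed failure modes: a removal extent
$r_f \in [0,1]$ per feature, applied **surface-inward** (outermost voxels
first, so partial removal leaves a realistic residual shell rather than
speckle); an optional global additive perturbation $\delta$ emulating
defacers that alter nearly every voxel (applied before feature zeroing,
so "removed" voxels stay exactly zero and the voxel accounting remains
consistent when both effects are combined); and a brain-clip fraction
emulating accidental brain damage. Ground truth is a pure function of the
removal extents: a feature is *residual* if $r_f < 0.95$; the **strict**
criterion demands zero residual features, the **lenient** criterion
tolerates one residual provided $r_f \ge 0.5$ (a "minimal trace" — the
qualitative notion is operationalized by this explicit, configurable
threshold, with no claim that it reproduces any particular human rater).

Cohorts draw 1–7 scans per subject, deface each scan with each method (or
a per-scan sample of methods), and sample per-entry outcomes from
scenario mixes ("full", "clean", "single_minimal", "single_severe",
"multi") so the realized share of insufficient labels matches the
requested class balance exactly up to rounding; the method tag modulates
nuisance effects (the `mrideface` tag adds a small global perturbation,
`fsldeface` occasionally clips brain voxels). Everything — volumes,
labels, manifest — reproduces bit-for-bit from one master seed.

What the phantoms deliberately do **not** model: bias fields, k-space
physics, anatomical detail, modality contrast (T1 vs FLAIR), or
registration error between the pair. Tests passing on phantoms therefore
show that the *pipeline* measures and classifies what it claims to
measure under controlled failure modes; they do not certify performance
on clinical data, whose labels come from human raters and whose feature
distributions are broader.

## Numerical choices and degenerate inputs

* Identical pairs score exactly (RMSE 0, PSNR = cap, SSIM 1, FSIM 1, all
  volumetric percentages 0); the test suite asserts this over 50 seeded
  phantoms.
* Original and defaced scans must share a grid; shape mismatch is an
  error, never a silent resample — the pairs come from one acquisition.
* Empty head or brain masks make the percentage denominators undefined
  and raise errors; an empty mask in rendering yields an all-background
  image, which is a legitimate render.
* Constant feature columns have undefined rank correlations; these are
  recorded as 0 with a warning so clustering can proceed.
* Fold assignment, model fits, permutations and phantom noise all derive
  from one master seed via a fixed linear-congruential child-seed scheme,
  keeping every derived seed in 32-bit range.
* Ties in hyperparameter tuning resolve to the first grid row; ties in
  cluster importance to the first feature.

## Problem sizes used by the test suite

The generator defaults are 96³ voxel grids and 256 px views. The test
suite and the acceptance script run the same code paths at 48³ voxels and
64 px views with 10–90 pair cohorts, 100–200 oracle cases, and 10–20
selection/fold-audit replicates — sizes chosen so the full battery runs
in a few minutes on one CPU while every property remains sharply
distinguishable from its failure mode.
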