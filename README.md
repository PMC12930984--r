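# defacingQC

Automated quality assessment of brain-MRI defacing.

Head MRI scans carry a reconstructible face, so shared neuroimaging data
is *defaced*: nose, eyes, mouth and surrounding superficial tissue are
removed from the volume before release. Defacing tools fail quietly —
residual eyelids or nasal tips, near-global low-amplitude intensity
changes, clipped brain tissue — and auditing thousands of defaced scans
by eye does not scale. defacingQC is for data managers and neuroimaging
researchers who need that audit automated: it compares each defaced scan
with its original and classifies whether the defacing succeeded.

## What it computes

For an original/defaced NIfTI pair (plus a brain mask), the package
extracts:

* **Volumetric impact** — with head mask `M_h` (normalized original
  intensity > 0.03) and brain mask `M_b`:
  impacted voxels `100·|{x ∈ M : |I_o(x) − I_d(x)| > ε}| / |M|` and
  removed voxels `100·|{x ∈ M : I_o(x) ≠ 0 ∧ I_d(x) = 0}| / |M|`,
  for head and brain, plus the brain-to-head ratio `|M_b|/|M_h|`.
* **Surface similarity** — the head surface is rendered from five
  standardized perspectives (frontal, left/right profile, left/right 45°)
  by deterministic orthographic first-hit ray casting, and RMSE, PSNR,
  SSIM and FSIM are computed per view pair and averaged. FSIM couples
  log-Gabor phase congruency with Scharr gradient magnitude,
  `S = S_PC · S_G`, pooled with weights `max(PC_1, PC_2)`.

These features — plus one-hot defacing-method indicators — feed four
classifiers (ridge logistic regression, MLP, random forest, XGBoost)
evaluated under **nested stratified group k-fold cross-validation**: all
scans of one subject stay in one fold, class balance is preserved per
fold, and an inner loop tunes hyperparameters without ever touching the
outer test folds. Permutation feature importance plus hierarchical
clustering of Spearman correlations drives an iterative feature-selection
loop; percent agreement and Cohen's κ quantify rater reliability.

A synthetic head-phantom generator (ellipsoidal head, interior brain,
parameterized facial protrusions, seeded defacing simulations with
strict/lenient ground-truth rules) replaces private clinical data for
testing and benchmarking; see the methods vignette
(`vignettes/defacing-quality-assessment.Rmd`) for the model and its
limits.

## Worked example

```r
library(defacingQC)

# a synthetic head with masks and facial-feature geometry
ph <- generatePhantom(phantomSpec(gridSize = 64, subjectId = "subj001",
                                  scanId = "subj001_s1",
                                  subjectSeed = 7, seed = 7))
ph
#> HeadPhantom subj001_s1 (subject subj001): head 45470, brain 16370 voxels, BHR 0.360

# simulate a defacing run that leaves 30% of the left eye behind
defaced <- simulateDefacing(ph, defaceSimSpec(
  removal = c(nose = 1, left_eye = 0.7, right_eye = 1, mouth = 1),
  method = "pydeface"))

pairFeatures(ph@scan, defaced, ph@brainMask, qaConfig(resolution = 128L))
#>      scan_id subject_id  fsim  ssim   rmse psnr head_impacted_pct
#> 1 subj001_s1    subj001 0.965 0.955 0.0578 25.8              1.89
#>   head_removed_pct brain_impacted_pct brain_removed_pct  bhr
#> 1             1.89                  0                 0 0.36
```

Reading the row: defacing zeroed 1.89% of head voxels and altered exactly
those (impacted = removed, so nothing else was perturbed), brain tissue is
untouched, and the five-view similarity dropped from its identity values
(FSIM 1 → 0.965) because the face changed. The residual left eye makes
this pair *insufficiently defaced* under the strict criterion but
acceptable under the lenient one:

```r
sim <- defaceSimSpec(removal = c(nose = 1, left_eye = 0.7,
                                 right_eye = 1, mouth = 1))
labelDefacing(sim, groundTruthRule("strict"))   # 1 (insufficient)
labelDefacing(sim, groundTruthRule("lenient"))  # 0 (acceptable)
```

Cohort-scale training runs through `generateCohortManifest()` /
`cohortFeatureTable()` → `nestedCV()` → `trainDefacingClassifier()` /
`predictDefacing()`, or from the shell via the thin CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","defacingQC.R",package="defacingQC"))')" \
  simulate --out cohort/ --subjects 20 --seed 1
```

with subcommands `simulate`, `features`, `train`, `predict`, `agreement`.

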