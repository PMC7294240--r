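---
title: "Predicting the evolution of white-matter hyperintensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the evolution of white-matter hyperintensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depwmh)
```

## The problem

White-matter hyperintensities (WMH) — bright lesions on T2-FLAIR MRI and a
hallmark of cerebral small vessel disease — do not only accumulate: over a
one-year interval individual lesion regions may grow, stay stable, or
shrink. `depwmh` implements a voxel-wise *disease evolution predictor*: given
only a baseline scan (plus, optionally, clinical covariates or a stochastic
auxiliary input), it estimates where lesions will progress and regress by
the next time point.

Three map modalities represent lesions on a common `[0, 1]` scale:

* **IM** (irregularity map): an unsupervised per-voxel irregularity score
  that retains lesion texture, with intensity gradients throughout lesions;
* **PM** (probability map): a supervised segmentation probability, saturated
  at 1 inside lesion cores and graded only at the borders;
* **LBL**: a binary expert lesion label.

The **Disease Evolution Map (DEM)** is the signed voxel-wise difference
`followup - baseline` of two IM or PM volumes; it lies in `[-1, 1]`, with
positive values marking progression. From two binary masks the analogous
object is the **three-class evolution label map**: per voxel, *stable*
(lesion at both time points), *shrink* (baseline only), *grow* (follow-up
only), or background. WMH masks are obtained from IM/PM by inclusive
thresholds: a voxel is lesion when its irregularity is at least 0.178 or its
probability at least 0.5. Stroke-lesion voxels, when a stroke mask is
available, are removed from all lesion bookkeeping before labelling and
volumetry.

## The two predictors

**DEP-UResNet** is the supervised variant: a residual U-Net reads one
baseline FLAIR-like axial slice and emits four class probabilities per voxel
(softmax head). It is trained on expert three-class label maps with
class-weighted categorical cross-entropy. Because changed regions are far
smaller than stable ones, weights are inverse class frequencies (normalised,
capped at 20) so grow/shrink voxels are not drowned out.

**DEP-GAN** is the adversarial variant for settings without longitudinal
labels. The same U-Net backbone with a tanh head maps a baseline IM/PM
slice to a *generated* DEM `y'`; the implied follow-up is `x1' = x0 + y'`.
Up to two convolutional critics score realism: **D** scores follow-up
images, **C** scores DEMs. Training uses the Wasserstein objective with a
gradient penalty of factor 10 on per-sample interpolates between real and
fake inputs. The generator additionally minimises a regularisation term

`lambda1 * MAE(x1', x1) + lambda2 * (1 - softDSC(x1', x1)) + lambda3 * MSE(vol(x1'), vol(x1))`

with weights 100, 1, 100. Four variants span the ablation space:
`wgan_gp` (C only, no image regularisation), `vagan` (D plus the intensity
term), `depgan_1c` (D plus the full regularisation), and `depgan_2c`
(C and D plus the full regularisation). Setting a weight to zero removes
its term exactly, so the variants form an algebraic family: `depgan_1c`
with `lambda2 = lambda3 = 0` *is* the `vagan` objective.

Each critic is updated 5 times per generator update, and 100 times during
the first 25 generator iterations and on every 100th one (the heavy
phases). For GAN variants the schedule's `epochs` counts generator updates;
for the supervised variant it counts data epochs.

### Auxiliary input and FiLM

Non-image information enters through feature-wise linear modulation (FiLM):
an auxiliary vector (default length 32) passes through a small dense branch
that emits one `(gamma_m, beta_m)` pair per modulated feature map, applied
as `gamma_m * F_m + beta_m` after the first convolution of every residual
block. The branch's final layer is zero-initialised and gamma is
parameterised as `1 + delta`, so conditioning starts exactly at the
identity; "no auxiliary" is the same network with FiLM frozen there, which
makes ablations bit-comparable. Auxiliary modes:

* `none`;
* `wmh_load` / `wmh_sl_loads`: per-subject baseline lesion loads (ml),
  z-scored over the training cohort with the population (1/n) variance and
  broadcast to all of a subject's slices; test-time data reuse the training
  scaler;
* `gaussian`: a standard-normal vector, which makes the model
  non-deterministic. During training the *Min-of-N* rule draws several
  candidate vectors and backpropagates only the lowest-loss one; at test
  time several draws are scored and both the average and the best-by-Dice
  draw are reported.

## The synthetic cohort

The clinical cohort behind this line of work is not public, so the package
ships a generator of longitudinal phantoms that reproduces the *structure*
of the task. Each subject is an elliptical intracranial volume on a
48x48x8 grid at 0.9375 x 0.9375 x 4 mm (the acquisition geometry,
downsampled in-plane; a 256x256x42 full-scale grid is one configuration
change away) containing 2-4 smooth ellipsoidal lesion clusters. Between
time points each cluster's boundary advances or retreats by 1.5 mm
according to a per-subject logistic growth probability; covariates
(hypertension, diabetes, smoking, lacunar stroke subtype, basal-ganglia
perivascular-space score, baseline load) shift its log-odds, centred at
their population prevalences — taken from a mild-stroke cohort profile
(hypertension 75%, smoking 64%, diabetes 12%, lacunar 46%) — so the
configured marginal rates (grow 0.6, shrink 0.3 per cluster) are preserved.

Intensities are constructed *from* the masks, never the reverse, with a
guard band of two noise standard deviations around each threshold and
additive noise clipped to that band. Hence thresholding a generated IM at
0.178 or PM at 0.5 recovers the generating mask exactly — a property the
test suite asserts bit-wise. The modality contrast is reproduced: IM values
are graded throughout the lesion (cores below 1), PM cores are exactly 1
with gradients only at borders.

Baseline images also carry a *rim signature* tied to each cluster's sampled
fate: growing clusters show a faint exterior halo — a stylisation of the
"WMH penumbra", the zone of subtly abnormal tissue around lesions that is
known to be at elevated risk of conversion — while shrinking clusters show
a faded interior rim. This is what makes single-time-point prediction
learnable in the phantom. It is a deliberate idealisation: real penumbras
are weaker, anisotropic and confounded; real cohorts contain
periventricular topography, registration error, artefacts and atrophy that
the phantom does not attempt. Passing the end-to-end test therefore shows
that the architecture, losses and training loop can extract a
baseline-image signal of evolution — not that this signal is as accessible
in clinical MRI.

```{r, eval = FALSE}
cohort <- generate_cohort(cohort_config(n_subjects = 40, seed = 1234))
model <- dep_uresnet(cohort$subjects[1:30], epochs = 30, aux_mode = "gaussian",
                     seed = 1234)
labels <- predict(model, cohort$subjects[31:40])
```

## Evaluation battery

* **Direction accuracy**: per subject, predicted follow-up volume (from the
  predicted label map: baseline minus shrink plus grow) is compared against
  baseline; G and S are the percentages of truly growing / shrinking
  subjects called correctly, reported with their average (G+S)/2. Subjects
  with exactly zero true change carry no direction and are excluded with a
  warning.
* **Bland-Altman agreement**: differences are ground truth minus predicted
  (positive bias = under-prediction); limits of agreement are the bias
  plus/minus 1.96 sample standard deviations.
* **Volumetric correlation**: OLS trend of predicted on true volumes with
  the squared Pearson correlation.
* **Per-class spatial agreement**: Dice `2TP / (FP + 2TP + FN)` one-vs-rest
  for stable, shrink and grow; *change* is shrink-or-grow; *entire WMH* is
  the implied follow-up extent (stable-or-grow). Two empty masks score 1
  (perfect agreement on absence). These two compound columns are package
  definitions, stated here because the field reports them without defining
  them.
* **ANCOVA plausibility**: a linear model of follow-up lesion burden (% of
  intracranial volume) on baseline burden plus seven clinical covariates,
  reporting each coefficient as B(p) with two-sided Wald p-values; aliased
  columns raise an error and high variance inflation warns.
* **Cross-validation**: subject-level k-fold partitions (both scans of a
  subject stay together), near-equal fold sizes.

## Numerical choices

* The network engine is written in-package: activations are
  `(H*W*N) x channels` matrices, convolutions are im2col gathers plus BLAS
  matrix products with the gather/scatter kernels compiled from C
  (single-precision GEMM inside the kernels, the deep-learning convention;
  parameters and everything user-visible stay double). Gradients come from
  a reverse-mode tape; the test suite checks them against double-precision
  references and directional finite differences.
* The gradient penalty's *value* uses the exact reverse-mode input gradient.
  Its gradient with respect to critic weights is a second-order quantity;
  it is computed as a central-difference Hessian-vector product along the
  frozen normalised input-gradient direction (two extra first-order passes,
  step 1e-3). This avoids double backprop while keeping the penalty's
  training effect; the unit-gradient-critic zero case is exact.
* The soft segmentation inside the Dice and volume loss terms uses a
  logistic step at the modality threshold with sharpness 50 and smoothing
  constant 1; hard masks are used only at evaluation time. The volume term
  is computed per slice (in ml-equivalents) during 2D training.
* `apply_dem()` clips the implied follow-up to `[0, 1]` so downstream
  thresholding stays meaningful; training uses the unclipped sum for
  gradient flow.
* Optimisers: Adam with learning rate 1e-3 (supervised) and 1e-4 with
  betas (0, 0.9) (adversarial, the gradient-penalty convention).
* Calibrated decoding: cost-weighted cross-entropy tilts the fitted class
  probabilities towards the up-weighted rare classes, which over-segments
  the change rims and inflates predicted volumes. `predict()` therefore
  divides the probabilities by the training class weights before the
  argmax (the standard prior correction for cost-weighted training;
  `prior_correction = FALSE` restores the raw decode). Averaging predicted
  volumes over repeated noise draws was evaluated as an alternative decode
  and found grow-biased on held-out phantoms, so the reported protocol uses
  a single draw per subject.
* Desk-scale economy, chosen once from CPU profiling and stated as the
  package's problem size: trainers default to one residual block per level
  (the `generator_spec()` default remains two), a 1x1 skip-merge
  projection, batch 16, and Min-of-N with 3 candidates ranked on a 6-slice
  subsample of the minibatch (`noise_config()` itself defaults to the full
  10/10 protocol, and `select_noise()` implements the contract for any
  count). The end-to-end demonstration trains 30 subjects on the 48x48x8
  grid for 30 epochs.
* Degenerate inputs: thresholding is inclusive at the boundary; three-class
  labelling is defined on integer masks so no floating-point zero test is
  involved; zero-variance loads and rank-deficient ANCOVA designs raise
  errors rather than silently proceeding; slices without brain tissue are
  omitted from training, and prediction labels them background.
* Reproducibility: cohort generation, training and noise-based evaluation
  are pure functions of their seeds; RNG state is saved and restored around
  every seeded computation.

## Known limitations

The phantom's rim cue makes the task easier and cleaner than clinical data;
per-class Dice on thin change rims remains much lower than on stable
regions, mirroring the ordering seen in practice. Subject-level direction
calls are least reliable for subjects that mix growing and shrinking
clusters with a small net volume change, where a one-voxel-scale
segmentation bias can flip the sign. The adversarial trainer
is functional and tested for its mechanics (schedule, losses, penalty,
determinism) but at desk scale it is not trained long enough to claim
image-quality results. 3D architectures, registration preprocessing and the
upstream IM/PM segmenters are out of scope; the package consumes their
outputs.
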