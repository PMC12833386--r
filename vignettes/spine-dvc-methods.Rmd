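---
title: "Methods: digital volume correlation and clinical metric prediction for the lumbar spine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital volume correlation and clinical metric prediction for the lumbar spine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spinedvc)
```

## The analysis chain

`spinedvc` implements the full measurement chain that turns a pair of 3D
spine image volumes — a reference ("neutral") scan and an extension-loaded
scan of the same lumbar spine — into biomechanical and clinical quantities,
and then relates the two statistically:

1. **Digital volume correlation (DVC).** Cubic image subsets from the
   reference volume are matched into the deformed volume, giving an
   internal displacement field `u(x)` on a regular node lattice.
2. **Rigid-body removal.** The common repositioning motion between the two
   scans (translation plus rotation about the centroid, via polar
   decomposition) is estimated from the field and removed by exact
   composition with the inverse rigid motion.
3. **Strain mapping.** The Green–Lagrange tensor
   `E = (G + G^T + G^T G)/2` is computed from the field gradient `G`,
   eigen-decomposed into principal strains `eps1 >= eps2 >= eps3` and the
   maximum shear `gamma_max = (eps1 - eps3)/2`, and summarised per
   intervertebral disc as unweighted node means and signed
   maximum-magnitude peaks (reported in percent).
4. **Kinematics.** Per-vertebra translations are mask averages of the
   field (Vx anterior–posterior, positive posterior; Vy cranial–caudal,
   positive cranial; Vz lateral, positive right), `Vtot` is the norm of
   the averaged components, and segmental anterolisthesis is the
   anterior-positive difference `(-Vx_sup) - (-Vx_inf)`.
5. **Clinical geometry.** Disc heights (anterior/central/posterior,
   orthogonal to the mid-disc plane), the anterior:posterior height ratio,
   Cobb segmental lordosis, lumbar lordosis, lumbar height, sacral angle,
   and the Pfirrmann consensus grade are measured on explicit mid-sagittal
   landmarks.
6. **Statistics.** Per disc level, predictors are screened for
   multicollinearity (VIF below 10), outcomes are fitted by backward
   elimination of ordinary least-squares models, residuals are checked for
   normality and homoscedasticity, and the family of model p-values at
   each level is corrected with Hommel's procedure. Inter-rater agreement
   of the geometric measures uses ICC(2,1), the two-way random-effects
   absolute-agreement single-measurement form.

Because no imaging data ship with the package, a phantom module generates
every input with analytic ground truth; all accuracy statements below are
demonstrated on phantoms by the test suite and `scripts/acceptance.R`.

## The correlation engine

**Schedule.** The default multipass pyramid uses subsets of 48, 32, 24 and
16 voxels with 1, 1, 2 and 2 passes, 50% subset overlap and a 50% minimum
valid-voxel fraction. With 50% overlap the node spacing of the final
16-voxel stage is 8 voxels; at the working resolution of 0.58 mm isotropic
that is 4.64 mm — the displacement-field resolution of the chain. Each
stage seeds the next from its trilinearly interpolated field
(predictor–corrector).

**Matching.** Coarse stages use zero-mean, Hann-windowed FFT
cross-correlation of reference and (seed-shifted) deformed subsets, with
peaks restricted to a quarter subset to avoid wrap-around aliasing. The
final stage uses zero-normalised cross-correlation (ZNCC) over a bounded
integer search window (default ±2 voxels around the seed). Sub-voxel
refinement is a separable three-point Gaussian fit on the correlation
peak. Two safeguards matter in practice:

* *Exact-match shortcut.* When the correlation peak is numerically
  perfect, the sub-voxel step is skipped; integer-voxel motions of
  noise-free data are therefore recovered exactly rather than to fitting
  tolerance.
* *Affine corrector.* A zeroth-order subset (pure translation model)
  carries a bias wherever the true motion varies within the subset — even
  a 1° rigid rotation moves opposite subset corners ±0.14 voxel apart,
  which the texture converts to ~0.02–0.04 voxel of node-to-node error
  and, after differentiation, to spurious strain of a few tenths of a
  percent. Corrector passes therefore counter-warp the deformed subset by
  the seed field's local affine motion (its fractional shift plus its
  displacement gradient, estimated from neighbouring nodes and clamped to
  ±0.08) using separable Catmull-Rom cubic resampling, then redo the
  integer ZNCC search and Gaussian fit on the counter-warped target. The
  corrected solution is kept only when its correlation peak is at least
  as high as the uncorrected one. This first-order scheme reduces the
  node error on smooth fields to ~0.015 voxel RMS and keeps per-disc mean
  strains of rigid-only scan pairs below the 0.18% strain precision of
  the chain.

**Validity.** A node is invalid when its subset holds less than the
minimum valid-voxel fraction of foreground, has no intensity variance, or
when any candidate of its (seed-shifted) search window — including the
corrector's interpolation support — leaves the volume. Invalid nodes carry
no displacement and are excluded from every aggregate. Ties on the
correlation peak are broken toward the smallest displacement magnitude,
biasing degenerate cases toward null motion.

## Rigid-body estimation and removal

The translation is the mean displacement over valid nodes; the rotation is
the orthogonal polar factor (via SVD, determinant forced positive) of the
least-squares linear map from centred node positions to centred deformed
positions. Removal composes the measured mapping with the inverse rigid
motion — `u'(x) = R^T (x + u(x) - c - t) + c - x` — rather than
subtracting the rigid displacement field, so the operation is exact at
finite angles; subtraction is only first-order correct. Green–Lagrange
strain is invariant under this composition (`F -> R^T F` leaves `F^T F`
unchanged), which the tests assert both analytically and through the
pipeline.

## Strain conventions

Gradients are central differences on the node lattice (one-sided at
lattice boundaries) over the node spacing in mm. The maximum shear uses
the tensorial convention `(eps1 - eps3)/2`; the engineering convention
(`eps1 - eps3`) is available via the `shear` argument. Peaks keep their
sign: the peak minimum principal strain is the most negative value, "peak"
meaning highest magnitude. A subset belongs to a disc when its centre
voxel lies inside the disc mask (endplate voxels are part of the disc
masks); the mean is unweighted over qualifying valid nodes — weighting by
valid-voxel counts was considered and rejected as the original summaries
are defined per subset, not per voxel.

## The phantom module

**Speckle texture.** Volumes are sums of random Gaussian blobs over a
constant background, evaluable at any continuous coordinate. A deformed
volume is the texture *exactly resampled* at inverse-mapped voxel centres,
so correlation error is never confounded with image-interpolation error;
pure-translation specs invert exactly and identity warps are bit-identical
to the reference sampling. Blob standard deviations default to 0.9–1.6
voxels — wide enough to be band-limited above the voxel Nyquist rate, the
requirement for the analytic-resampling argument to carry over to the
sampled grid — and the spine phantom defaults to 0.05 blobs/voxel, about
200 features per final 16-voxel subset, the kind of feature density DVC
speckle is designed to have. Sparser or narrower textures degrade the
correlation exactly as poorly speckled specimens do; the defaults document
what "well-textured" means for this engine.

**Deformations.** A `deformation_spec` composes a rigid motion about a
centre, a small affine gradient, and a mild quadratic displacement; the
displacement, deformation gradient and Green–Lagrange strain are all
closed-form. The quadratic part is inverted by fixed-point iteration to
1e-12 mm; rigid and affine parts invert exactly.

**Spine geometry.** The spine phantom stacks `levels + 1` vertebral bodies
(convex quadrilaterals with parallel endplates, extruded laterally) and
`levels` disc slabs in the sagittal plane. Prescribing per-disc anterior
and posterior heights together with the body depth fixes the disc wedge
exactly — `sin(wedge/2) = (anterior - posterior)/(2 * depth)` — and with
parallel endplates the Cobb angles telescope, so the lumbar lordosis of
the emitted landmarks equals the sum of the prescribed wedges and the
sacral angle is the prescribed tilt of the most caudal superior endplate.
Geometry can equivalently be prescribed as central height plus wedge. The
phantom favours this exactness over anatomical realism: bodies are not
anatomically shaped, there is no cortical/trabecular contrast, no MRI
noise or bias field, and endplates are flat. Passing tests therefore
demonstrate the correctness of the measurement chain, not robustness to
scanner artefacts.

**Synthetic cohorts.** Cohort tables draw the predictor vocabulary of the
regression layer (age 23–67, gender, BMI ~ N(23.8, 2.6), average disc
height ~ N(9.6, 1.2) mm, A:P ratio 1–2, Pfirrmann grades binned ND/D/SD,
segmental lordosis ~ N(8, 3)°, lumbar height ~ N(185, 12) mm, sacral angle
~ N(38, 6)°) and build the outcome from a known linear model plus Gaussian
noise. The regression-recovery simulations plant effects on age (0.1 per
year) and the A:P ratio (5 per unit) with noise SD 0.9, putting the full
eight-predictor model's adjusted R² at n = 15 in the high-signal regime
of the significant models this analysis is designed to produce (the tests
assert the median over replicates lies in 0.5-0.9, and require the
planted support to be retained in the majority of 200 replicates).

## Kinematic screening and error propagation

The chain's displacement precision constants default to 0.165 mm (Vx),
0.129 mm (Vy), 0.138 mm (Vz); combining the three in quadrature gives the
0.251 mm total-translation precision, and the worst-case linear
propagation of two Vx readings through the anterolisthesis difference
gives 0.330 mm. Strain accuracy and precision default to 0.34% and 0.18%.
A set of measurements is kept ("resolved") when its mean magnitude or its
range reaches ten times the relevant precision (boundary inclusive);
`Vtot` is deliberately the norm of the averaged components, the definition
consistent with the quadrature propagation.

Anterolisthesis is returned anterior-positive, `(-Vx_sup) - (-Vx_inf)`,
so that larger positive values mean larger forward slip of the superior
vertebra under the posterior-positive Vx convention. A raw
`Vx_sup - Vx_inf` difference would invert that reading; the anterior-
positive form is the one under which "greater positive = greater
anterolisthesis" is coherent.

## Statistical layer choices

* Backward elimination drops the predictor with the largest partial
  p-value at or above `p_out` and refits; `p_out` defaults to 0.10, the
  conventional removal threshold of backward procedures in the major
  statistics packages. Elimination by p-value and by F-change coincide
  for single-predictor removals.
* Gender and degeneration enter as indicators with female and
  non-degenerated as reference categories; bins absent at a level drop
  out as constant columns and are ledgered.
* The VIF screen removes iteratively above a threshold of 10, largest
  first, later column on ties; exact collinearity is removed with an
  infinite-VIF entry.
* The "visual" assumption checks are automated: Shapiro–Wilk on the
  residuals and the studentised Breusch–Pagan test against the fitted
  values at alpha 0.05; violating models are flagged excluded, and
  `model_diagnostics(..., plot = TRUE)` still draws the two panels for
  eyeballing. Zero-variance residuals (noise-free fits) pass by
  definition.
* The Hommel family at a level is the set of model p-values fitted at
  that level (all outcomes, and both vertebra-matching variants when
  vertebral translations are modelled, since each segment borders two
  vertebrae); `hommel_adjust()` wraps the closed-testing step-up
  adjustment and is validated against exhaustive closed testing with
  Simes local tests.
* ICC(2,1) is computed from the two-way ANOVA mean squares with the
  Satterthwaite-based 95% interval; absolute agreement penalises constant
  rater offsets, which the consistency form would hide.

## Problem sizes and numerical tolerances

The shipped tests and the acceptance script run phantoms sized for a
single-CPU workstation: 64³ speckle volumes for shift/warp recovery, a
two-level spine phantom (~127 x 150 x 63 voxels at 0.58 mm) for the
rigid-pair strain budget, 48³ volumes for the unit tests, 200 cohort
replicates at n = 15 for the elimination study and 1,000 draws for the
Hommel oracle battery. Key tolerances: deformation inversion 1e-12 mm;
rigid rotation orthonormality 1e-6; strain symmetry check 1e-8 relative;
correlation "perfect match" threshold 1 - 1e-9; seed-gradient clamp
±0.08. Larger cohorts or finer phantoms only change runtime, not any
constant above.

## Known limitations

* Translations are resolved in the global image frame, not in
  vertebra-local anatomical frames.
* Whole-disc summaries only; no regional (anterior/posterior annulus)
  strain maps.
* The phantom does not emulate MRI noise, bias fields, or anatomically
  realistic vertebral shapes, so tests bound algorithmic error only.
* The statistics layer fits each level independently; no hierarchical
  pooling across levels and no missing-data handling.
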