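# spinedvc

Digital volume correlation (DVC) and clinical metric prediction for the
lumbar spine, in R.

## The problem

Excessive intervertebral disc (IVD) strain and vertebral motion are
implicated in low back pain, but neither can be read off a routine scan.
When a spine is imaged twice — once neutral, once under extension loading —
subset-based DVC can recover the internal 3D displacement field between
the two volumes, and from it the disc strains and vertebral translations.
Clinicians, meanwhile, routinely measure disc heights, sagittal alignment
angles and Pfirrmann degeneration grades on the same images. This package
implements the full chain connecting the two worlds, for researchers in
spine biomechanics and medical image analysis:

* **`dvc`** — multipass FFT + direct-correlation subset matching
  (48–32–24–16 voxel pyramid, 50% overlap, sub-voxel Gaussian peak
  fitting with a first-order corrector), producing a displacement field
  `u(x)` on a node lattice with validity flags;
* **`rigid`** — estimation (polar decomposition of the best-fit linear
  map) and exact removal of the inter-scan rigid-body motion;
* **`strain`** — the Green–Lagrange tensor `E = (G + Gᵀ + GᵀG)/2`,
  principal strains `ε₁ ≥ ε₂ ≥ ε₃`, maximum shear
  `γmax = (ε₁ − ε₃)/2`, and per-disc mean/peak summaries in percent;
* **`kinematics`** — mask-averaged vertebral translations (Vx, Vy, Vz,
  Vtot), anterior-positive anterolisthesis, order-of-magnitude precision
  screening, and quadrature/linear error propagation;
* **`spine metrics`** — landmark-based disc heights, anterior:posterior
  height ratio, Cobb segmental lordosis, lumbar lordosis/height, sacral
  angle, Pfirrmann consensus grading;
* **`stats`** — VIF-screened backward multivariate regression with
  residual diagnostics, Hommel family-wise correction, and ICC(2,1)
  inter-rater agreement;
* **`phantom`** — analytic speckle and spine phantoms with closed-form
  displacement/strain ground truth, so the whole chain is testable
  without any imaging data.

## Worked example

A two-level spine phantom is scanned "twice": the second volume is the
first one moved by a known rigid repositioning (1.0, −0.6, 0.3) mm plus a
1° rotation — the kind of motion you must remove before interpreting
strain. The pipeline recovers the field, strips the rigid motion, and
reports every downstream quantity:

```r
library(spinedvc)
cfg <- pipeline_config(seed = 42, spacing = 1.16)
rep <- run_pipeline(cfg)

rep$rigid
#> <rigid_transform> t = (1.01, -0.6082, 0.316) mm, rotation 1.011 deg
```

The imposed translation and rotation are recovered to hundredths of a
millimetre/degree. After removal, the residual per-disc strains are small
(this pair is rigid-only, so they are pure measurement noise):

```r
rep$strain_summary[, c("level", "n_nodes", "mean_eps1", "mean_eps3", "mean_gamma")]
#>   level n_nodes mean_eps1 mean_eps3 mean_gamma
#> 1 V1-V2       2     0.313    -0.090      0.202
#> 2 V2-S1       3     0.323    -0.204      0.264
```

(percent strain; at the full 0.58 mm working resolution the rigid-pair
means stay below the 0.18% strain precision of the chain — this coarse
1.16 mm demo trades accuracy for a few seconds of runtime). The raw
kinematics show the imposed motion and are screened against the cited
precision constants:

```r
rep$kinematics$vertebrae[, c("vertebra", "vx", "vy", "vz", "vtot", "screen")]
#>   vertebra    vx     vy    vz vtot          screen
#> 1       V1 0.633 -0.810 0.312 1.07 below-precision
#> 2       V2 0.981 -0.627 0.311 1.21 below-precision
#> 3       S1 1.393 -0.357 0.324 1.47 below-precision

rep$kinematics$segments
#>   segment anterolisthesis resolved
#> 1   V1-V2           0.348     TRUE
#> 2   V2-S1           0.412     TRUE
```

`below-precision` flags translations smaller than ten times the 0.251 mm
Vtot precision — correctly so for a ~1 mm repositioning. Anterolisthesis
is anterior-positive: the rotation slides each superior vertebra ~0.4 mm
forward relative to its inferior neighbour. The clinical geometry comes
straight from the phantom's landmarks:

```r
rep$metrics$levels[, c("level", "anterior", "posterior", "ratio", "segmental_lordosis")]
#>   level anterior posterior ratio segmental_lordosis
#> 1 V1-V2       11       8.5 1.294              5.117
#> 2 V2-S1       11       8.5 1.294              5.117

rep$metrics$global
#> $lumbar_lordosis
#> [1] 10.23479
#> $lumbar_height
#> [1] 57.92857
#> $sacral_angle
#> [1] 38
```

— exactly the prescribed 11/8.5 mm wedges, their implied 5.12° Cobb
angles summing to the 10.2° lordosis, and the prescribed 38° sacral
angle. Adding `cohort = list(n = 15, true_betas = c(age = 0.1,
ap_ratio = 5), noise_sd = 0.9)` to the config appends a synthetic-cohort
regression stage (VIF screen → backward elimination → diagnostics →
Hommel correction) that recovers the planted associations.

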