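# morphfit

Single-image 3D face-shape reconstruction with a PCA morphable model, and
quantitative validation of reconstructed surfaces — for researchers who
need the *geometry* side of image-based face reconstruction (e.g. clinical
shape assessment in facial palsy, where 3D acquisition is not always
available) as tested, reusable R components.

The package covers the full loop:

* **Statistical shape model.** From a corpus of corresponded triangle
  meshes, `build_morphable_model()` computes the linear model
  `S(α) = S₀ + Σⱼ Bⱼ σⱼ αⱼ` by thin SVD (orthonormal modes `Bⱼ`, per-mode
  SDs `σⱼ` in mm, coefficients `α` in SD units).
* **Landmark fitting.** `fit_landmarks()` recovers shape coefficients and
  a scaled orthographic camera pose `(R, t, s)` from 68 2D facial
  landmarks by minimising
  `E(α,R,t,s) = (1/L) Σᵢ ‖xᵢ − SOP(vᵢ(α))‖² + λ‖α‖²`,
  alternating an exact pose solve (pose-from-orthography + Gauss–Newton)
  with an exact linear ridge shape solve, followed by a joint
  Gauss–Newton refinement. Returns a classed fit object with `print`,
  `summary`, `coef`, `predict`, `fitted`, `residuals` and `plot` methods.
* **Analytic components of deep reconstruction pipelines.** Articulated
  blend-skinned head models (`articulated_deform()`), identity/expression/
  texture 3DMMs (`dual_3dmm()`), 9-term spherical-harmonics shading
  (`sh_radiosity()`), and the standard losses — photometric, landmark,
  perception, coefficient regularisation, texture flattening, eye
  closure, soft symmetry — as evaluable scoring functions with
  `coarse_loss()` / `detail_loss()` aggregators.
* **Validation.** Exact point-to-surface distances
  (`point_to_surface_distances()`), mean ± SD / max surface-error reports
  (`distance_report()`), and trimmed similarity-ICP registration
  (`rigid_register()`, Umeyama updates, scale allowed by default because
  monocular reconstruction has no absolute scale).
* **Synthetic data.** `make_truth_model()` / `make_scenario()` generate
  ground-truth models, subjects, noisy landmark observations and
  sensor-like degraded references (1 mm-class depth-camera noise, smooth
  MRI-segmentation-like bias), all pure functions of a seed, so the whole
  pipeline is testable without subject data. `run_experiment()`
  orchestrates simulate → fit → register → validate into a per-subject
  error table.

## Worked example

Reconstruct a synthetic subject from noisy landmarks and score the result
against a depth-sensor-like reference:

```r
library(morphfit)

model   <- make_truth_model(seed = 1, m_vertices = 300, k_modes = 10)
subject <- sample_subject(model, seed = 2)
pose    <- sop_pose(rotation_exp(c(0.10, -0.05, 0.08)), t = c(150, 160), s = 3)
obs     <- observe_landmarks(subject$mesh, model, pose, noise_sd_px = 1, seed = 3)

fit <- fit_landmarks(model, obs)
summary(fit)
#> Morphable-model landmark fit
#>   68 landmarks, 10 shape modes, lambda = 0.001
#>   objective: 1.434 after 100 alternation iterations (converged)
#> sop_pose: scale 2.986 px/mm, rotation 8.18 deg, t = (150.93, 161.00)
#>   reprojection error [px]: mean 1.081, sd 0.5125, max 2.3
#>   coefficient norm (SD units): 2.78

recon     <- predict(fit, type = "mesh")
reference <- degrade_mesh(subject$mesh, noise_sd_mm = 1, seed = 4)
tr        <- rigid_register(recon, reference)
distance_report(apply_transform(recon, tr), reference)
#> distance_report (symmetric, n = 580): 0.788 +/- 0.547 mm, max 2.526 mm
```

Reading the numbers: the camera was recovered at 2.99 px/mm and 8.2°
rotation (truth: 3 px/mm, ~8°); the mean landmark reprojection error of
~1.1 px matches the 1 px observation noise; and the reconstructed surface
lies 0.79 ± 0.55 mm from a reference whose own noise floor is about
0.8 mm (1 mm normal noise has mean offset `√(2/π) ≈ 0.8` mm) — i.e. the
reconstruction error is at the reference noise level. With
`noise_sd_px = 0` and `noise_sd_mm = 0` the same pipeline returns mean
errors below 0.001 mm.

A thin command-line front end (`inst/cli/morphfit`) wraps the same
functions: `simulate`, `fit`, `validate` and `run` subcommands writing
PLY/STL meshes, CSV landmarks and JSON reports.

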