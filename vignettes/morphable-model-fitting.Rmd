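---
title: "Morphable-model fitting and surface validation: methods"
author: "morphfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphable-model fitting and surface validation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphfit)
```

## The problem

Clinical assessment of facial shape — for instance in facial palsy, where
asymmetry of the soft tissue is itself the quantity of interest — calls for
3D face geometry, but 3D acquisition (depth cameras, MRI) is expensive and
not always available. A long-standing alternative is to recover a plausible
3D face *shape* from a single 2D photograph by constraining the
reconstruction with a statistical model of facial shape learned from a
population, and then to ask, quantitatively, how far such reconstructions
are from sensor-measured surfaces. `morphfit` implements that loop:
model construction, single-image landmark fitting, the analytic scoring
functions used by deep reconstruction pipelines, and surface-distance
validation — plus a synthetic-data generator so that every stage can be
exercised and tested end to end without any subject data.

## The statistical shape model

A corpus of triangle meshes in dense correspondence (every mesh has the
same vertex count and vertex semantics) is flattened to vectors
$S = (x_1, y_1, z_1, \dots, x_m, y_m, z_m)^\top \in \mathbb{R}^{3m}$,
in millimetres. The morphable model is the usual PCA decomposition

$$ S(\alpha) \;=\; S_0 + \sum_{j=1}^{k} B_j\,\sigma_j\,\alpha_j , $$

with $S_0$ the corpus mean, $B_j$ orthonormal principal modes and
$\sigma_j$ the per-mode standard deviations. Three conventions are fixed
once and used everywhere:

* **Flattening is interleaved per vertex** (x, y, z, x, y, z, ...);
  `flatten_mesh()` / `unflatten()` are exact inverses.
* **Basis columns are unit norm**; the natural scale of each mode lives in
  `mode_sd` ($\sigma_j$, mm), so user-facing coefficients $\alpha$ are
  dimensionless, in standard-deviation units. This makes the ridge prior
  in the fitter a dimensionless Mahalanobis penalty.
* **PCA is computed by thin SVD of the centred data matrix** — the
  $3m \times 3m$ covariance is never formed, so $m$ in the tens of
  thousands is unproblematic. Mode signs follow a deterministic
  convention (largest-magnitude entry positive) so results are bit-stable.
  With $n$ training shapes at most $n - 1$ modes exist;
  `build_morphable_model()` enforces $k \le n-1$ and by default keeps the
  smallest $k$ explaining 99% of variance.

## Landmark fitting with a scaled orthographic camera

A face photographed at arm's length or farther has little depth variation
relative to the camera distance, so the perspective camera is well
approximated by the *scaled orthographic* (weak perspective) model: a 3D
point $p$ maps to $s\,[(Rp)_x + t_x,\; (Rp)_y + t_y]$, with rotation $R$,
2D translation $t$ (model units) and scale $s$ (px/mm). Image coordinates
follow the usual convention: origin top-left, x right, y down.

Given $L$ detected 2D landmarks $x_i$ paired with model vertices, the fit
minimises

$$ E(\alpha, R, t, s) \;=\; \frac{1}{L}\sum_{i=1}^{L}
   \bigl\| x_i - \mathrm{SOP}(v_i(\alpha); R, t, s) \bigr\|^2
   \;+\; \lambda \|\alpha\|^2 . $$

The $1/L$ normalisation makes the objective an interpretable mean squared
pixel error. The ridge term (default $\lambda = 10^{-3}$) is needed
because a 68-landmark problem under-determines models with many modes;
because $\alpha$ is in SD units, $\lambda \|\alpha\|^2$ is exactly a
scaled Gaussian shape prior.

`fit_landmarks()` alternates two exact half-steps:

1. **Pose step.** For fixed shape, the affine 2×3 camera is solved by
   linear least squares on centred data and projected to the nearest
   scaled rotation via SVD ($s$ = mean of the two singular values, proper
   rotation enforced) — the classic pose-from-orthography construction —
   then polished by a damped Gauss–Newton iteration to the exact
   minimiser. With noiseless weak-perspective data the recovery is exact
   to machine precision (`estimate_pose()`).
2. **Shape step.** For fixed pose the objective is a linear ridge system
   in $\alpha$, solved in closed form (`estimate_coeffs_given_pose()`).

Each half-step solves its subproblem exactly, so the objective trace is
non-increasing — an invariant the test suite asserts. Because this
coordinate descent has slow tail convergence when shape and pose are
strongly coupled (thousands of alternations to squeeze out the last few
orders of magnitude on noiseless data), the default configuration finishes
with a *joint* damped Gauss–Newton refinement over $(\alpha, R, t, s)$ on
the identical objective. The refinement is monotone too, converges
quadratically, and can be disabled (`fit_config(refine = FALSE)`) to study
the bare alternation.

Initialisation is $\alpha = 0$ with the pose estimated from the mean
shape's landmark vertices; convergence is declared at a relative objective
decrease below `rel_tol` ($10^{-8}$ by default, at most `max_iters = 100`
alternations). Degenerate geometry is refused: fewer than 4
correspondences or collinear landmark vertices are errors, coplanar sets
fit with a warning (their out-of-plane reflection is unobservable).

A note on scale: a monocular weak-perspective reconstruction carries no
absolute scale — $s$ absorbs it. Validation therefore registers with a
similarity transform by default (below).

## Articulated models, shading, and loss functions

The second family of reconstruction methods replaces direct optimisation
with learned encoders; what is *analytic* in those pipelines is
implemented here as evaluable functions so their components can be tested
and reused:

* `articulated_deform()` — a blend-skinned head rig: template plus linear
  shape/pose-corrective/expression blendshapes, then linear blend skinning
  about $k = 4$ joints (neck, jaw, two eyeballs) with per-vertex weights
  that must sum to one. The pose corrective uses the standard linearised
  feature, the flattened $(R_j - I)$ entries of the joint rotations. At
  rest the template is returned exactly; a pure global rotation is a
  rigid motion.
* `dual_3dmm()` — the identity + expression shape model and linear texture
  model $S = \bar S + B_{id}\alpha + B_{exp}\beta$,
  $T = \bar T + B_t\delta$.
* `sh_radiosity()` — Lambertian shading as a 9-term real spherical
  harmonics expansion in the vertex normal (bands 0–2), times per-vertex
  albedo. The SH constant table (Ramamoorthi–Hanrahan convention) is
  defined once in the code and shared with the tests' independent oracle.
* Losses: `photometric_loss()` (attention-weighted mean of the
  **un-squared** per-pixel l2 colour difference — implemented exactly as
  commonly printed, though many implementations square it; documented
  because the difference matters), `landmark_loss()` (weighted mean pixel
  distance; the default weights are 20 for mouth and nose landmarks and 0
  elsewhere, kept as the published convention despite the unusual zero —
  overridable), `perception_loss()` (1 − cosine of deep-feature vectors),
  `coef_reg_loss()` (weights 1.0 / 0.8 / 0.0017), `texture_flatten_loss()`
  (summed per-channel population variance over a skin region), plus
  eye-closure, soft-symmetry, and shape-consistency components.
  `coarse_loss()` / `detail_loss()` aggregate them with unit weights by
  default; the Markov-random-field detail score has no self-contained
  published definition and is accepted as an externally supplied scalar
  (default 0).

## Validation: registration and surface distances

`point_to_surface_distances()` computes the exact Euclidean distance from
each query point to the nearest point of any mesh triangle, handling
vertex, edge and interior closest-point cases (Ericson's region
classification, vectorised over triangles). `distance_report()`
summarises source-vertex distances against a target surface as
mean ± SD and max; `symmetric` mode pools both directions. The `max` of
the report is the (sampled) classical Hausdorff distance; the headline
mean ± SD is what surface-validation tables conventionally print.

`rigid_register()` aligns a reconstruction to a reference with trimmed
similarity ICP: centroid/RMS-spread initialisation, nearest-neighbour
correspondences, a closed-form Umeyama similarity update on the best 90%
of matches (trimming survives partially overlapping surfaces, e.g. an
occluded jaw), iterated to a $10^{-6}$ relative RMS change or 50
iterations. Scale is estimated by default because of the monocular scale
ambiguity; `allow_scale = FALSE` gives strictly rigid registration.
Distance statistics are invariant under a common rigid motion of both
meshes — asserted in the tests.

## The synthetic generator

Because real corpora and references cannot ship with the package, the
generator produces the full study environment from a seed:

* `make_truth_model()` — a triangulated ellipsoid head with face-like
  proportions (about 180 × 220 × 150 mm), deformation modes that are
  smooth low-spatial-frequency displacement fields (random low-order
  spherical-harmonic mixtures, orthonormalised), mode SDs log-spaced from
  5 mm to 0.5 mm — the scale of dominant human face variation — and 68
  landmark vertices placed deterministically in an iBUG-style layout with
  named groups (jaw, brow, nose, eyelid upper/lower, eye corners, mouth),
  so landmark weighting and eye-closure scoring are exercisable.
* `sample_subject()` — coefficients drawn i.i.d. $N(0, c^2)$ in SD units:
  the Gaussian low-rank population that a PCA morphable model implicitly
  assumes, stated explicitly.
* `observe_landmarks()` — projected landmark vertices plus i.i.d.
  Gaussian pixel noise (detector surrogate).
* `degrade_mesh()` — reference-sensor emulation: `kinect` mode displaces
  vertices along normals with 1 mm-class Gaussian noise (typical
  structured-light depth error); `mri` mode applies a smooth
  low-frequency bias (0.3 mm) plus small jitter (0.1 mm), emulating
  slowly varying segmentation bias. Both scale linearly with the
  requested noise level, so a zero-noise scenario has exact references.
* `make_scenario()` — bundles model, subjects, near-frontal random poses
  (≤ 15°, 2–4 px/mm) and observations. All generators are pure functions
  of their seed; two calls are bit-identical, and the caller's RNG stream
  is left untouched.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: real faces are not smooth ellipsoid
deformations (no nose/lip geometry beyond the landmark layout), landmark
detectors have structured, pose-dependent errors rather than i.i.d.
Gaussian ones, real references have holes and occlusions rather than
uniform noise, and the fitted model here shares the truth model's basis,
so model misspecification is only probed indirectly (truth and fitted
$k$ may differ in scenarios). The synthetic results certify the
*algorithms*, not clinical accuracy.

## Numerical choices and degenerate inputs

* SVD sign convention (largest-|entry| positive) for model modes; QR
  orthonormalisation for generator fields.
* Pose Gauss–Newton uses step-halving damping; a step is only accepted if
  the objective decreases, which guarantees the monotone trace.
* Ridge systems with $\lambda = 0$ raise an explicit singular-system
  error advising $\lambda > 0$.
* Zero-variance corpora (identical meshes) build with a warning and zero
  mode SDs; coefficient projection treats zero-SD modes as zero.
* ICP keeps at least 3 correspondences regardless of the trim fraction;
  collinear sources are refused.
* Meshes with degenerate faces (repeated vertex indices) are refused at
  construction; STL input is accepted only for validation meshes because
  the format destroys shared vertex indexing.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run synthetic studies at sizes
chosen to exercise every code path while completing in minutes on one
CPU: truth models of 150–300 vertices with up to 10 modes, 68 landmarks,
20-instance Monte-Carlo repetitions, and 200 randomized instances for the
exact-distance oracle. The algorithms are dimension-independent; the
53,490-vertex topology of classic face models appears in the tests only
to pin the flattened dimension ($3m = 160{,}470$).

## Known limitations

* Perspective effects are not modelled; close-range photographs violate
  the weak-perspective assumption systematically.
* The fitter uses landmarks only — no photometric term enters the
  optimisation (the photometric losses are scoring functions here).
* Landmark weights of zero (the published mouth/nose convention) discard
  most landmarks if used in the fitter's objective; the fitter therefore
  uses unweighted residuals, and the weighted loss is a separate scoring
  function.
* Binary PLY/STL files are not read; ASCII variants only.
* Registration is similarity-rigid; non-rigid residual deformation
  (expression mismatch between photograph and reference scan) is
  reported as error, not compensated.
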