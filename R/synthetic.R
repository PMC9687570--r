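## Synthetic study generator: a ground-truth morphable model over a
## face-proportioned ellipsoid head, Gaussian low-rank subject sampling,
## noisy scaled-orthographic landmark observations, and sensor-like
## degraded reference meshes (structured-light/Kinect-style ~1 mm vertex
## noise; MRI-segmentation-style smooth bias). Every generator is a pure
## function of its seed.

# evaluate under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# latitude-longitude triangulated ellipsoid; returns a triangle_mesh with
# n_lat * n_lon + 2 vertices (two poles). semi_axes in mm.
ellipsoid_mesh <- function(n_lat, n_lon, semi_axes = c(90, 110, 75)) {
  phi <- pi * seq_len(n_lat) / (n_lat + 1)          # polar angle from +y pole
  th <- 2 * pi * (seq_len(n_lon) - 1) / n_lon
  grid <- expand.grid(th = th, phi = phi)
  # head axes: x right, y down (image convention), z towards the camera
  dirs <- cbind(sin(grid$phi) * cos(grid$th),
                -cos(grid$phi),
                sin(grid$phi) * sin(grid$th))
  V <- rbind(c(0, -1, 0), dirs, c(0, 1, 0))
  V <- sweep(V, 2L, semi_axes, "*")
  idx <- function(i, j) 1L + (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  F <- list()
  for (j in seq_len(n_lon))                          # top fan
    F[[length(F) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
  for (i in seq_len(n_lat - 1L)) for (j in seq_len(n_lon)) {
    F[[length(F) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
    F[[length(F) + 1L]] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  }
  bottom <- as.integer(n_lat * n_lon + 2L)
  for (j in seq_len(n_lon))                          # bottom fan
    F[[length(F) + 1L]] <- c(bottom, idx(n_lat, j + 1L), idx(n_lat, j))
  triangle_mesh(V, do.call(rbind, F))
}

# canonical 68-slot landmark layout on the front of the head, iBUG-style
# grouping; coordinates in the unit front disc (x right, y down).
landmark_layout <- function() {
  pts <- list(); grp <- character(0)
  add <- function(x, y, g) {
    pts[[length(pts) + 1L]] <<- cbind(x, y)
    grp <<- c(grp, rep(g, length(x)))
  }
  t <- seq(-1, 1, length.out = 17)                   # jaw contour (U-shape)
  add(0.80 * sin(t * pi / 2), 0.15 + 0.72 * cos(t * pi / 2), "jaw")
  add(seq(-0.60, -0.15, length.out = 5), rep(-0.45, 5), "brow")
  add(seq(0.15, 0.60, length.out = 5), rep(-0.45, 5), "brow")
  add(rep(0, 4), seq(-0.30, 0.10, length.out = 4), "nose")   # bridge
  add(seq(-0.20, 0.20, length.out = 5), rep(0.22, 5), "nose") # base
  eye <- function(cx) {
    rx <- 0.12; ry <- 0.055
    add(cx + c(rx, -rx), c(0, 0) - 0.25, "eye_corner")
    add(cx + c(rx / 2, -rx / 2), rep(-0.25 - ry, 2), "eye_upper")
    add(cx + c(-rx / 2, rx / 2), rep(-0.25 + ry, 2), "eye_lower")
  }
  eye(-0.35); eye(0.35)
  a12 <- 2 * pi * (0:11) / 12                        # outer lip ring
  add(0.26 * cos(a12), 0.48 + 0.11 * sin(a12), "mouth")
  a8 <- 2 * pi * (0:7) / 8                           # inner lip ring
  add(0.16 * cos(a8), 0.48 + 0.045 * sin(a8), "mouth")
  list(points = do.call(rbind, pts), groups = grp)
}

#' Generate a ground-truth morphable model
#'
#' Builds a synthetic "population truth" morphable model: the base head is
#' a triangulated ellipsoid with face-like proportions (about 180 x 220 x
#' 150 mm); the deformation modes are smooth, low-spatial-frequency vertex
#' displacement fields (random low-order spherical-harmonic mixtures over
#' the head surface), orthonormalised, with per-mode standard deviations
#' log-spaced from 5 mm down to 0.5 mm. 68 landmark vertices are picked
#' deterministically at canonical facial positions on the front of the
#' head, with iBUG-style named groups (jaw, brow, nose, eyelid upper/lower,
#' eye corners, mouth).
#'
#' @param seed integer RNG seed; identical seeds give bit-identical models.
#' @param m_vertices target vertex count (`>= 50`); the realised count is
#'   the nearest latitude-longitude grid size (reported in `model$m`).
#' @param k_modes number of deformation modes, in `[1, 30]`.
#' @return a `morphable_model` with extra fields `landmark_groups` (length
#'   68), `eyelid_upper` / `eyelid_lower` (paired landmark slots for
#'   eye-closure scoring).
#' @export
make_truth_model <- function(seed, m_vertices = 300, k_modes = 10) {
  if (m_vertices < 50) stop("m_vertices must be >= 50", call. = FALSE)
  if (k_modes < 1 || k_modes > 30)
    stop("k_modes must be in [1, 30]", call. = FALSE)
  n_lon <- max(8L, 2L * round(sqrt(m_vertices / 2)))
  n_lat <- max(5L, round((m_vertices - 2) / n_lon))
  base <- ellipsoid_mesh(n_lat, n_lon)
  m <- n_vertices(base)
  dirs <- base$vertices / sqrt(rowSums(base$vertices^2))
  Phi <- sh_basis(dirs)                              # smooth field generators
  k <- as.integer(k_modes)
  fields <- with_seed(seed, {
    W <- array(stats::rnorm(9L * 3L * k), dim = c(9L, 3L, k))
    out <- matrix(0, 3L * m, k)
    for (j in seq_len(k)) {
      disp <- Phi %*% W[, , j]                       # m x 3 smooth field
      out[, j] <- as.numeric(t(disp))
    }
    out
  })
  qr_ <- qr(fields)
  basis <- qr.Q(qr_)[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                            # deterministic sign
    piv <- which.max(abs(basis[, j]))
    if (basis[piv, j] < 0) basis[, j] <- -basis[, j]
  }
  mode_sd <- exp(seq(log(5), log(0.5), length.out = k))
  lay <- landmark_layout()
  disc <- lay$points
  z <- sqrt(pmax(0, 1 - rowSums(disc^2)))
  targets <- cbind(disc[, 1], disc[, 2], z)
  lmk <- integer(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    score <- drop(dirs %*% targets[i, ])
    ord <- order(score, decreasing = TRUE)
    lmk[i] <- ord[which.min(ord %in% lmk)]           # first free best match
  }
  model <- structure(
    list(mean_shape = flatten_mesh(base), basis = basis, mode_sd = mode_sd,
         faces = base$faces, landmark_vertex_ids = lmk,
         n_train = NA_integer_, m = m, k = k,
         landmark_groups = lay$groups,
         eyelid_upper = which(lay$groups == "eye_upper"),
         eyelid_lower = which(lay$groups == "eye_lower")),
    class = "morphable_model")
  model
}

#' Sample a synthetic subject from a morphable model
#'
#' Draws shape coefficients i.i.d. `Normal(0, coeff_scale^2)` (SD units —
#' the Gaussian low-rank population implicit in a PCA morphable model) and
#' synthesizes the subject's mesh.
#'
#' @param model a `morphable_model`.
#' @param coeff_scale positive coefficient scale (1 = population SD).
#' @param seed integer RNG seed.
#' @return list with `alpha` (length `k`) and `mesh` (`triangle_mesh`).
#' @export
sample_subject <- function(model, coeff_scale = 1, seed = 1) {
  stopifnot_model(model)
  if (coeff_scale <= 0) stop("coeff_scale must be > 0", call. = FALSE)
  alpha <- with_seed(seed, stats::rnorm(model$k, sd = coeff_scale))
  list(alpha = alpha, mesh = synthesize_shape(model, alpha))
}

#' Observe noisy 2D landmarks of a subject
#'
#' Projects the model's landmark vertices of a subject mesh with a scaled
#' orthographic camera and adds i.i.d. Gaussian pixel noise — a stand-in
#' for an automatic 68-point landmark detector.
#'
#' @param mesh the subject `triangle_mesh` (same vertex semantics as
#'   `model`).
#' @param model the `morphable_model` supplying `landmark_vertex_ids`.
#' @param pose an `sop_pose`.
#' @param noise_sd_px landmark noise SD in pixels (`>= 0`).
#' @param seed integer RNG seed.
#' @return a `landmarks2d` with ids `1:68` (slots into the model's
#'   landmark table).
#' @export
observe_landmarks <- function(mesh, model, pose, noise_sd_px = 0, seed = 1) {
  stopifnot_model(model); stopifnot_mesh(mesh)
  if (noise_sd_px < 0) stop("noise_sd_px must be >= 0", call. = FALSE)
  P <- mesh$vertices[model$landmark_vertex_ids, , drop = FALSE]
  x <- sop_project(P, pose)
  if (noise_sd_px > 0)
    x <- x + with_seed(seed,
                       matrix(stats::rnorm(length(x), sd = noise_sd_px),
                              ncol = 2L))
  landmarks2d(x)
}

#' Degrade a mesh with sensor-like noise
#'
#' Produces a reference mesh the way a measurement device would: `kinect`
#' mode displaces every vertex along its normal by i.i.d. Gaussian noise of
#' SD `noise_sd_mm` (structured-light depth-sensor behaviour, about 1 mm);
#' `mri` mode applies a smooth low-spatial-frequency bias field along the
#' normals (SD `0.3 * noise_sd_mm`) plus a small jitter (SD
#' `0.1 * noise_sd_mm`), emulating slowly varying segmentation bias.
#' `noise_sd_mm = 0` returns the mesh unchanged in either mode.
#'
#' @param mesh a `triangle_mesh`.
#' @param noise_sd_mm noise level in millimetres (`>= 0`; 1.0 reproduces
#'   the nominal device levels).
#' @param seed integer RNG seed.
#' @param mode `"kinect"` or `"mri"`.
#' @return a degraded `triangle_mesh`.
#' @export
degrade_mesh <- function(mesh, noise_sd_mm = 1.0, seed = 1,
                         mode = c("kinect", "mri")) {
  mode <- match.arg(mode)
  stopifnot_mesh(mesh)
  if (noise_sd_mm < 0) stop("noise_sd_mm must be >= 0", call. = FALSE)
  if (noise_sd_mm == 0) return(mesh)
  N <- vertex_normals(mesh)
  m <- n_vertices(mesh)
  d <- with_seed(seed, {
    if (mode == "kinect") {
      stats::rnorm(m, sd = noise_sd_mm)
    } else {
      ctr <- colMeans(mesh$vertices)
      dirs <- sweep(mesh$vertices, 2L, ctr)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      bias <- drop(sh_basis(dirs) %*% stats::rnorm(9))
      bsd <- stats::sd(bias)
      if (bsd > 0) bias <- bias / bsd
      0.3 * noise_sd_mm * bias + stats::rnorm(m, sd = 0.1 * noise_sd_mm)
    }
  })
  triangle_mesh(mesh$vertices + d * N, mesh$faces)
}

#' Generate a full synthetic truth scenario
#'
#' Bundles a ground-truth model, `n_subjects` sampled subjects with random
#' near-frontal poses, and their noisy landmark observations; the noise
#' levels for landmark observation and reference-mesh degradation are
#' carried along for the pipeline. Fully reproducible from `seed`.
#'
#' @param seed integer RNG seed.
#' @param n_subjects number of subjects.
#' @param m_vertices,k_modes truth-model size (see [make_truth_model()]).
#' @param coeff_scale subject coefficient scale (SD units).
#' @param landmark_noise_sd landmark observation noise, pixels.
#' @param mesh_noise_sd reference-mesh noise level, millimetres.
#' @return an object of class `truth_scenario`: list with `model`,
#'   `subjects` (each with `alpha`, `mesh`, `pose`, `landmarks`),
#'   `landmark_noise_sd`, `mesh_noise_sd`, `seed`.
#' @export
make_scenario <- function(seed, n_subjects = 4, m_vertices = 300,
                          k_modes = 10, coeff_scale = 1,
                          landmark_noise_sd = 1.0, mesh_noise_sd = 1.0) {
  if (landmark_noise_sd < 0 || mesh_noise_sd < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  model <- make_truth_model(seed, m_vertices, k_modes)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    si <- derive_seed(seed, i)
    subj <- sample_subject(model, coeff_scale, seed = si)
    pose <- with_seed(si + 1L, random_frontal_pose())
    lmk <- observe_landmarks(subj$mesh, model, pose,
                             noise_sd_px = landmark_noise_sd, seed = si + 2L)
    subjects[[i]] <- list(alpha = subj$alpha, mesh = subj$mesh,
                          pose = pose, landmarks = lmk)
  }
  structure(list(model = model, subjects = subjects,
                 landmark_noise_sd = landmark_noise_sd,
                 mesh_noise_sd = mesh_noise_sd, seed = seed),
            class = "truth_scenario")
}

#' @export
print.truth_scenario <- function(x, ...) {
  cat(sprintf(
    "truth_scenario: %d subjects, k = %d, landmark noise %g px, mesh noise %g mm (seed %d)\n",
    length(x$subjects), x$model$k, x$landmark_noise_sd, x$mesh_noise_sd,
    x$seed))
  invisible(x)
}

# small deterministic per-subject seed derivation, kept within 32-bit range
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 9973) %% .Machine$integer.max)
}

# near-frontal pose: rotation up to ~15 deg about a random axis, scale in
# [2, 4] px/mm, translation placing the face inside a typical image
random_frontal_pose <- function() {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, 15 * pi / 180)
  s <- stats::runif(1, 2, 4)
  t <- stats::runif(2, 100, 200)
  sop_pose(rotation_exp(ax * ang), t, s)
}
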