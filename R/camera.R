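## Scaled orthographic (weak perspective) camera and landmark fitting.
##
## Image convention: origin top-left, x right, y down, pixel centres at
## integer coordinates. A pose maps model millimetres to image pixels.

#' Scaled orthographic pose
#'
#' A weak-perspective camera: rotation `R` (3x3, proper orthonormal),
#' 2D translation `t` (in model units, i.e. millimetres) and isotropic
#' scale `s` (pixels per millimetre). A 3D point `p` projects to
#' `s * ( [R p]_xy + t )`.
#'
#' @param R 3x3 rotation matrix, `R'R = I`, `det(R) = +1`.
#' @param t length-2 translation.
#' @param s positive scale, pixels per millimetre.
#' @return an object of class `sop_pose`.
#' @export
sop_pose <- function(R = diag(3), t = c(0, 0), s = 1) {
  R <- as.matrix(R)
  if (!identical(dim(R), c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0)
    stop("R must be a proper 3x3 rotation matrix", call. = FALSE)
  t <- as.numeric(t)
  if (length(t) != 2L || !all(is.finite(t)))
    stop("t must be a finite length-2 vector", call. = FALSE)
  s <- as.numeric(s)
  if (length(s) != 1L || !is.finite(s) || s <= 0)
    stop("s must be a positive scalar", call. = FALSE)
  structure(list(R = R, t = t, s = s), class = "sop_pose")
}

#' @export
print.sop_pose <- function(x, ...) {
  ang <- rotation_angle(x$R)
  cat(sprintf("sop_pose: scale %.4g px/mm, rotation %.2f deg, t = (%.2f, %.2f)\n",
              x$s, ang * 180 / pi, x$t[1], x$t[2]))
  invisible(x)
}

#' Project 3D points with a scaled orthographic camera
#'
#' @param points3d `n x 3` matrix of 3D points (millimetres).
#' @param pose an `sop_pose`.
#' @return `n x 2` matrix of pixel coordinates.
#' @export
sop_project <- function(points3d, pose) {
  if (!inherits(pose, "sop_pose")) stop("'pose' must be an sop_pose",
                                        call. = FALSE)
  P <- as.matrix(points3d)
  if (is.vector(points3d) && length(points3d) == 3L) P <- matrix(points3d, 1L)
  if (ncol(P) != 3L || !all(is.finite(P)))
    stop("points3d must be finite n x 3", call. = FALSE)
  rot <- P %*% t(pose$R[1:2, , drop = FALSE])
  pose$s * sweep(rot, 2L, pose$t, "+")
}

## ---- rotation helpers ------------------------------------------------------

#' Axis-angle rotation helpers
#'
#' `rotation_exp()` is the Rodrigues exponential map: a length-3 axis-angle
#' vector (direction = axis, norm = angle in radians) to a 3x3 rotation
#' matrix. `rotation_angle()` returns the geodesic angle of a rotation
#' matrix (use `rotation_angle(R1 %*% t(R2))` for the angle between two).
#'
#' @param w length-3 axis-angle vector, radians.
#' @return `rotation_exp()`: a 3x3 rotation matrix; `rotation_angle()`: an
#'   angle in `[0, pi]`.
#' @export
rotation_exp <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3) + skew3(w))
  k <- w / th
  K <- skew3(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3L, 3L)
}

#' @rdname rotation_exp
#' @param R 3x3 rotation matrix.
#' @export
rotation_angle <- function(R) {
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2)))
}

## ---- pose estimation -------------------------------------------------------

# mean squared reprojection error (the fitting objective's data term)
sop_cost <- function(P, x, pose) {
  r <- x - sop_project(P, pose)
  mean(rowSums(r^2))
}

#' Estimate a scaled orthographic pose from 2D-3D correspondences
#'
#' Pose-from-correspondences for a weak-perspective camera ("POS with
#' iteration"): the 2x3 affine camera is solved by linear least squares on
#' centred data and projected onto the nearest scaled rotation by SVD
#' (scale = mean of the two singular values, proper rotation enforced);
#' a damped Gauss-Newton refinement then polishes `(R, t, s)` to the exact
#' minimiser of the mean squared reprojection error. With noiseless
#' scaled-orthographic data the true pose is recovered to machine precision.
#'
#' @param points3d `n x 3` model points, `n >= 4`, not collinear. Coplanar
#'   sets are accepted with a warning: the out-of-plane reflection of the
#'   returned rotation is unobservable and the two solutions have equal cost.
#' @param points2d `n x 2` observed pixel coordinates.
#' @return an `sop_pose` with attribute `cost` (mean squared reprojection
#'   error, px^2).
#' @export
estimate_pose <- function(points3d, points2d) {
  P <- as.matrix(points3d); x <- as.matrix(points2d)
  if (nrow(P) < 4L)
    stop("at least 4 correspondences are required", call. = FALSE)
  if (nrow(P) != nrow(x) || ncol(P) != 3L || ncol(x) != 2L)
    stop("points3d must be n x 3 and points2d n x 2 with equal n",
         call. = FALSE)
  pbar <- colMeans(P); xbar <- colMeans(x)
  Pc <- sweep(P, 2L, pbar); xc <- sweep(x, 2L, xbar)
  sv <- svd(Pc)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate geometry: 3D points are collinear", call. = FALSE)
  coplanar <- sv$d[3] < 1e-8 * sv$d[1]
  if (coplanar)
    warning("3D points are coplanar; pose has a reflection ambiguity",
            call. = FALSE)
  # affine camera by (pseudo-inverse) least squares: xc ~ Pc A', A is 2x3
  dinv <- ifelse(sv$d > 1e-10 * sv$d[1], 1 / sv$d, 0)
  A <- t(sv$v %*% (dinv * crossprod(sv$u, xc)))
  pose <- project_to_scaled_rotation(A, pbar, xbar)
  polish_pose(P, x, pose)
}

# nearest scaled rotation to a 2x3 affine camera; rebuild t from centroids
project_to_scaled_rotation <- function(A, pbar, xbar) {
  sv <- svd(A)
  s <- mean(sv$d)
  s <- max(s, 1e-12)
  R12 <- sv$u %*% t(sv$v)                       # 2 x 3, orthonormal rows
  r3 <- c(R12[1, 2] * R12[2, 3] - R12[1, 3] * R12[2, 2],
          R12[1, 3] * R12[2, 1] - R12[1, 1] * R12[2, 3],
          R12[1, 1] * R12[2, 2] - R12[1, 2] * R12[2, 1])
  R <- rbind(R12, r3)
  t <- xbar / s - drop(R12 %*% pbar)
  sop_pose(R, t, s)
}

# damped Gauss-Newton on (rotation increment, t, s); monotone in cost
polish_pose <- function(P, x, pose, max_iters = 60L, tol = 1e-14) {
  n <- nrow(P)
  i1 <- seq.int(1L, 2L * n, 2L)
  i2 <- i1 + 1L
  msqe <- function(R, t, s) {                    # mean squared reproj error
    v2 <- P %*% t(R[1:2, , drop = FALSE])
    mean((x[, 1] - s * (v2[, 1] + t[1]))^2 +
           (x[, 2] - s * (v2[, 2] + t[2]))^2)
  }
  R <- pose$R; tt <- pose$t; s <- pose$s
  cost <- msqe(R, tt, s)
  J <- matrix(0, 2L * n, 6L)                     # columns: w(3), t(2), s
  for (it in seq_len(max_iters)) {
    v <- P %*% t(R)                              # rotated points, n x 3
    r <- numeric(2L * n)
    r[i1] <- x[, 1] - s * (v[, 1] + tt[1])
    r[i2] <- x[, 2] - s * (v[, 2] + tt[2])
    # d proj / d w  = s * (-[v]_x)[1:2, ]  (left-multiplied increment exp(w^))
    J[i1, 2] <- s * v[, 3]
    J[i1, 3] <- -s * v[, 2]
    J[i2, 1] <- -s * v[, 3]
    J[i2, 3] <- s * v[, 1]
    J[i1, 4] <- s
    J[i2, 5] <- s
    J[i1, 6] <- v[, 1] + tt[1]
    J[i2, 6] <- v[, 2] + tt[2]
    step <- tryCatch(solve(crossprod(J) + 1e-12 * diag(6), crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    step <- drop(step)
    improved <- FALSE
    conv <- FALSE
    for (damp in 0:10) {
      d <- step / 2^damp
      s_new <- s + d[6]
      if (s_new <= 0) next
      R_new <- rotation_project(rotation_exp(d[1:3]) %*% R)
      t_new <- tt + d[4:5]
      c_new <- msqe(R_new, t_new, s_new)
      if (c_new < cost) {
        R <- R_new; tt <- t_new; s <- s_new
        improved <- TRUE
        conv <- (cost - c_new) <= tol * max(cost, 1e-30)
        cost <- c_new
        break
      }
    }
    if (!improved || conv) break
  }
  structure(list(R = R, t = tt, s = s), class = "sop_pose", cost = cost)
}

# re-orthonormalise after accumulated exp-map updates
rotation_project <- function(R) {
  sv <- svd(R)
  Q <- sv$u %*% t(sv$v)
  if (det(Q) < 0) Q <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  Q
}

## ---- landmarks -------------------------------------------------------------

#' 2D facial landmarks
#'
#' @param points `L x 2` matrix of pixel coordinates (origin top-left,
#'   x right, y down).
#' @param ids landmark identifiers, one per row, distinct; integer slots
#'   indexing the model's `landmark_vertex_ids`. Defaults to `1:L`.
#' @return an object of class `landmarks2d`.
#' @export
landmarks2d <- function(points, ids = seq_len(nrow(points))) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L || !all(is.finite(points)))
    stop("landmark points must be finite L x 2", call. = FALSE)
  ids <- as.integer(ids)
  if (length(ids) != nrow(points) || anyDuplicated(ids))
    stop("ids must be distinct, one per landmark", call. = FALSE)
  structure(list(points = points, ids = ids), class = "landmarks2d")
}

#' @export
print.landmarks2d <- function(x, ...) {
  cat("landmarks2d:", nrow(x$points), "points\n")
  invisible(x)
}

# resolve landmark slots -> model vertex indices; returns list with the
# landmark-block mean positions (L x 3) and basis slab (3L x k, SD-scaled)
landmark_blocks <- function(model, landmarks) {
  if (is.null(model$landmark_vertex_ids))
    stop("model has no landmark_vertex_ids", call. = FALSE)
  slot <- landmarks$ids
  if (any(slot < 1L | slot > length(model$landmark_vertex_ids)))
    stop("landmark ids outside the model's landmark table", call. = FALSE)
  vid <- model$landmark_vertex_ids[slot]
  rows <- as.integer(t(outer(vid - 1L, 1:3, function(v, c) 3L * v + c)))
  list(vid = vid,
       mean = matrix(model$mean_shape[rows], ncol = 3L, byrow = TRUE),
       basis_sd = model$basis[rows, , drop = FALSE] *
         rep(1, length(rows)) %o% model$mode_sd)
}

# landmark 3D positions for coefficients alpha given precomputed blocks
landmark_positions <- function(blocks, alpha) {
  blocks$mean + matrix(drop(blocks$basis_sd %*% alpha), ncol = 3L, byrow = TRUE)
}

#' Shape coefficients from landmarks at a fixed pose
#'
#' Solves the linear ridge system for the shape coefficients minimising
#' \deqn{\frac{1}{L}\sum_i \| x_i - \mathrm{SOP}(f_{0,i} + \textstyle\sum_j
#'   B_{j,i}\sigma_j\alpha_j) \|^2 + \lambda \|\alpha\|^2,}
#' the camera held fixed. The solution is unique when `lambda > 0` or the
#' design matrix has full column rank.
#'
#' @param model a `morphable_model` with landmark vertices.
#' @param landmarks a `landmarks2d`.
#' @param pose an `sop_pose`.
#' @param lambda ridge weight on the (SD-unit) coefficients, `>= 0`.
#' @return coefficient vector of length `model$k`.
#' @export
estimate_coeffs_given_pose <- function(model, landmarks, pose, lambda = 1e-3) {
  stopifnot_model(model)
  if (!inherits(landmarks, "landmarks2d"))
    stop("'landmarks' must be a landmarks2d", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  blocks <- landmark_blocks(model, landmarks)
  coeff_step(model, blocks, landmarks$points, pose, lambda)
}

coeff_step <- function(model, blocks, x, pose, lambda) {
  L <- nrow(x)
  k <- model$k
  R12 <- pose$R[1:2, , drop = FALSE]
  # G[2(i-1)+a, j] = s * (R12 %*% basis-block_i)[a, j]
  arr <- blocks$basis_sd
  dim(arr) <- c(3L, L * k)
  G <- pose$s * (R12 %*% arr)
  dim(G) <- c(2L * L, k)
  rhs <- x - pose$s * sweep(blocks$mean %*% t(R12), 2L, pose$t, "+")
  r <- as.numeric(t(rhs))
  A <- crossprod(G) / L + lambda * diag(k)
  alpha <- tryCatch(drop(solve(A, crossprod(G, r) / L)),
                    error = function(e)
                      stop("singular coefficient system; use lambda > 0",
                           call. = FALSE))
  alpha
}

#' Fit configuration for landmark-based reconstruction
#'
#' @param prior_weight ridge weight `lambda` on SD-unit shape coefficients.
#'   The default `1e-3` keeps the problem well-posed when the number of
#'   landmarks is small relative to the model rank.
#' @param max_iters maximum alternation iterations.
#' @param rel_tol relative decrease of the objective at which the
#'   alternation is declared converged.
#' @param init_alpha starting coefficients (default zero = mean shape).
#' @param refine run a damped joint Gauss-Newton refinement over
#'   `(alpha, pose)` after the alternation (default `TRUE`). The refinement
#'   minimises the same objective and never increases it; it converges
#'   quadratically where the alternation's coordinate descent is slow.
#' @return a `fit_config` list.
#' @export
fit_config <- function(prior_weight = 1e-3, max_iters = 100L,
                       rel_tol = 1e-8, init_alpha = NULL, refine = TRUE) {
  if (prior_weight < 0) stop("prior_weight must be >= 0", call. = FALSE)
  if (max_iters < 1L) stop("max_iters must be >= 1", call. = FALSE)
  if (rel_tol <= 0) stop("rel_tol must be > 0", call. = FALSE)
  structure(list(prior_weight = prior_weight, max_iters = as.integer(max_iters),
                 rel_tol = rel_tol, init_alpha = init_alpha,
                 refine = isTRUE(refine)),
            class = "fit_config")
}

# joint damped Gauss-Newton over (alpha, rotation increment, t, s) on
# E = (1/L) sum ||x - proj||^2 + lambda ||alpha||^2; monotone in cost
refine_fit <- function(model, blocks, x, alpha, pose, lambda,
                       max_iters = 50L, tol = 1e-14) {
  L <- nrow(x)
  k <- model$k
  i1 <- seq.int(1L, 2L * L, 2L)
  i2 <- i1 + 1L
  obj <- function(a, p) {
    v <- landmark_positions(blocks, a)
    r <- x - pose_project(v, p)
    mean(rowSums(r^2)) + lambda * sum(a^2)
  }
  pose_project <- function(v, p)
    p$s * sweep(v %*% t(p$R[1:2, , drop = FALSE]), 2L, p$t, "+")
  cost <- obj(alpha, pose)
  trace <- numeric(0)
  for (it in seq_len(max_iters)) {
    v <- landmark_positions(blocks, alpha)
    vr <- v %*% t(pose$R)
    r <- numeric(2L * L)
    r[i1] <- x[, 1] - pose$s * (vr[, 1] + pose$t[1])
    r[i2] <- x[, 2] - pose$s * (vr[, 2] + pose$t[2])
    # d proj / d alpha (the ridge design matrix of the coefficient step)
    arr <- blocks$basis_sd
    dim(arr) <- c(3L, L * k)
    G <- pose$s * (pose$R[1:2, , drop = FALSE] %*% arr)
    dim(G) <- c(2L * L, k)
    J <- matrix(0, 2L * L, k + 6L)
    J[, seq_len(k)] <- G
    J[i1, k + 2L] <- pose$s * vr[, 3]
    J[i1, k + 3L] <- -pose$s * vr[, 2]
    J[i2, k + 1L] <- -pose$s * vr[, 3]
    J[i2, k + 3L] <- pose$s * vr[, 1]
    J[i1, k + 4L] <- pose$s
    J[i2, k + 5L] <- pose$s
    J[i1, k + 6L] <- vr[, 1] + pose$t[1]
    J[i2, k + 6L] <- vr[, 2] + pose$t[2]
    D <- diag(c(rep(lambda, k), numeric(6)), k + 6L)
    H <- crossprod(J) / L + D
    g <- crossprod(J, r) / L - c(lambda * alpha, numeric(6))
    step <- tryCatch(drop(solve(H + 1e-12 * diag(k + 6L), g)),
                     error = function(e) NULL)
    if (is.null(step)) break
    improved <- FALSE
    conv <- FALSE
    for (damp in 0:12) {
      d <- step / 2^damp
      s_new <- pose$s + d[k + 6L]
      if (s_new <= 0) next
      cand_pose <- structure(
        list(R = rotation_project(rotation_exp(d[k + 1:3]) %*% pose$R),
             t = pose$t + d[k + 4:5], s = s_new),
        class = "sop_pose")
      cand_alpha <- alpha + d[seq_len(k)]
      c_new <- obj(cand_alpha, cand_pose)
      if (c_new < cost) {
        alpha <- cand_alpha
        pose <- cand_pose
        improved <- TRUE
        conv <- (cost - c_new) <= tol * max(cost, 1e-30)
        cost <- c_new
        trace <- c(trace, c_new)
        break
      }
    }
    if (!improved || conv) {
      stationary <- TRUE
      break
    }
  }
  list(alpha = alpha, pose = pose, trace = trace, cost = cost,
       converged = exists("stationary", inherits = FALSE))
}

#' Fit a morphable model to 2D landmarks
#'
#' Reconstructs a 3D face shape from a single set of 2D landmarks by
#' alternating minimisation of
#' \deqn{E(\alpha, R, t, s) = \frac{1}{L}\sum_{i=1}^{L}
#'   \| x_i - \mathrm{SOP}(v_i(\alpha); R, t, s) \|^2
#'   + \lambda \|\alpha\|^2}
#' over the scaled orthographic pose (solved by [estimate_pose()]-style
#' closed form plus Gauss-Newton polish) and the shape coefficients (an
#' exact linear ridge solve). Each half-step solves its subproblem, so the
#' objective trace is non-increasing. By default a joint damped
#' Gauss-Newton refinement over `(alpha, pose)` then polishes the result
#' to the local minimiser of the same objective (the alternation alone is
#' a coordinate descent whose tail convergence is slow when shape and pose
#' are strongly coupled); set `refine = FALSE` in the config for the bare
#' alternation.
#'
#' @param model a `morphable_model` with landmark vertices.
#' @param landmarks a `landmarks2d`.
#' @param config a [fit_config()].
#' @return an object of class `morphfit_fit` with components `coeffs`,
#'   `pose`, `cost_trace`, `converged`, `model`, `landmarks`, `config`.
#'   Methods: `print`, `summary`, `coef`, `fitted` (projected landmarks),
#'   `residuals` (observed minus fitted, px), `predict` (reconstructed mesh
#'   or projected landmarks), `plot` (objective trace).
#' @examples
#' model <- make_truth_model(seed = 1, m_vertices = 200, k_modes = 5)
#' subj <- sample_subject(model, seed = 2)
#' pose <- sop_pose(s = 3, t = c(120, 150))
#' obs <- observe_landmarks(subj$mesh, model, pose, noise_sd_px = 0, seed = 3)
#' fit <- fit_landmarks(model, obs, fit_config(prior_weight = 1e-8))
#' max(abs(coef(fit) - subj$alpha)) < 1e-3
#' @export
fit_landmarks <- function(model, landmarks, config = fit_config()) {
  stopifnot_model(model)
  if (!inherits(landmarks, "landmarks2d"))
    stop("'landmarks' must be a landmarks2d", call. = FALSE)
  if (!inherits(config, "fit_config"))
    stop("'config' must be a fit_config", call. = FALSE)
  blocks <- landmark_blocks(model, landmarks)
  x <- landmarks$points
  L <- nrow(x)
  lambda <- config$prior_weight
  alpha <- if (is.null(config$init_alpha)) numeric(model$k) else
    check_coeffs(model, config$init_alpha)
  pose <- estimate_pose(landmark_positions(blocks, alpha), x)
  trace <- attr(pose, "cost") + lambda * sum(alpha^2)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(config$max_iters)) {
    iters <- it
    alpha <- coeff_step(model, blocks, x, pose, lambda)
    v <- landmark_positions(blocks, alpha)
    pose <- polish_pose(v, x, pose, max_iters = 8L)
    cur <- attr(pose, "cost") + lambda * sum(alpha^2)
    trace <- c(trace, cur)
    prev <- trace[length(trace) - 1L]
    if (prev - cur <= config$rel_tol * max(prev, .Machine$double.xmin)) {
      converged <- TRUE
      break
    }
  }
  if (config$refine) {
    ref <- refine_fit(model, blocks, x, alpha, pose, lambda)
    alpha <- ref$alpha
    pose <- ref$pose
    trace <- c(trace, ref$trace)
    converged <- converged || ref$converged   # stationary point reached
  }
  structure(list(coeffs = alpha, pose = pose, cost_trace = trace,
                 converged = converged, iterations = iters, model = model,
                 landmarks = landmarks, config = config),
            class = "morphfit_fit")
}

#' @export
print.morphfit_fit <- function(x, ...) {
  cat("Morphable-model landmark fit\n")
  cat(sprintf("  %d landmarks, %d shape modes, lambda = %g\n",
              nrow(x$landmarks$points), x$model$k, x$config$prior_weight))
  cat(sprintf("  objective: %.6g after %d alternation iterations (%s)\n",
              utils::tail(x$cost_trace, 1L), x$iterations,
              if (x$converged) "converged" else "not converged"))
  print(x$pose)
  invisible(x)
}

#' @export
summary.morphfit_fit <- function(object, ...) {
  r <- residuals(object)
  pe <- sqrt(rowSums(r^2))
  out <- list(fit = object,
              reproj_px = c(mean = mean(pe), sd = stats::sd(pe),
                            max = max(pe)),
              coeff_norm = sqrt(sum(object$coeffs^2)))
  class(out) <- "summary.morphfit_fit"
  out
}

#' @export
print.summary.morphfit_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  reprojection error [px]: mean %.4g, sd %.4g, max %.4g\n",
              x$reproj_px["mean"], x$reproj_px["sd"], x$reproj_px["max"]))
  cat(sprintf("  coefficient norm (SD units): %.4g\n", x$coeff_norm))
  invisible(x)
}

#' @export
coef.morphfit_fit <- function(object, ...) object$coeffs

#' @export
fitted.morphfit_fit <- function(object, ...) {
  blocks <- landmark_blocks(object$model, object$landmarks)
  sop_project(landmark_positions(blocks, object$coeffs), object$pose)
}

#' @export
residuals.morphfit_fit <- function(object, ...) {
  object$landmarks$points - fitted(object)
}

#' Predict from a landmark fit
#'
#' @param object a `morphfit_fit`.
#' @param type `"mesh"` for the reconstructed `triangle_mesh` (model frame,
#'   millimetres) or `"landmarks"` for the projected landmark pixels.
#' @param ... unused.
#' @export
predict.morphfit_fit <- function(object, type = c("mesh", "landmarks"), ...) {
  type <- match.arg(type)
  if (type == "mesh") synthesize_shape(object$model, object$coeffs)
  else fitted(object)
}

#' @export
plot.morphfit_fit <- function(x, ...) {
  graphics::plot(seq_along(x$cost_trace) - 1L, x$cost_trace, type = "b",
                 log = "y", xlab = "iteration", ylab = "objective",
                 main = "Landmark-fit objective trace", ...)
  invisible(x)
}
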