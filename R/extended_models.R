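## Analytic building blocks of the two deep reconstruction methods:
## an articulated blend-skinned head model with shape/pose/expression
## blendshapes, an identity/expression/texture dual 3DMM, low-order
## spherical-harmonics shading, and the training losses as evaluable
## scoring functions. No networks and no training: coefficients, rendered
## pixels, deep features and displacement maps are supplied inputs.

#' Articulated blend-skinned head model
#'
#' A template mesh with additive shape, pose-corrective and expression
#' blendshape bases, deformed by linear blend skinning (LBS) about `k`
#' joints. The canonical head rig has `k = 4` joints: neck, jaw and the
#' two eyeballs.
#'
#' @param template length-`3n` template shape vector (interleaved, mm).
#' @param faces face matrix for the `n` vertices.
#' @param shape_basis,pose_basis,expr_basis `3n x |beta|`, `3n x 9k`,
#'   `3n x |psi|` blendshape matrices (any may have 0 columns). The pose
#'   basis is indexed by the flattened `(R_j - I)` entries of the `k` joint
#'   rotations, the standard linearised pose corrective.
#' @param joints `k x 3` joint positions (mm).
#' @param parents length-`k` integer parent indices (0 = root, i.e. the
#'   global rotation); each parent must precede its child.
#' @param skin_weights `k x n` blend weights; every column non-negative and
#'   summing to 1.
#' @return an object of class `articulated_model`.
#' @export
articulated_model <- function(template, faces, shape_basis, pose_basis,
                              expr_basis, joints, parents, skin_weights) {
  template <- as.numeric(template)
  n <- length(template) / 3L
  if (n != round(n)) stop("template length must be divisible by 3",
                          call. = FALSE)
  joints <- as.matrix(joints)
  k <- nrow(joints)
  if (ncol(joints) != 3L) stop("joints must be k x 3", call. = FALSE)
  parents <- as.integer(parents)
  if (length(parents) != k || any(parents < 0L | parents >= seq_len(k)))
    stop("parents must be length k with each parent preceding its child",
         call. = FALSE)
  skin_weights <- as.matrix(skin_weights)
  if (!identical(dim(skin_weights), c(as.integer(k), as.integer(n))))
    stop("skin_weights must be k x n", call. = FALSE)
  if (any(skin_weights < -1e-12) ||
      max(abs(colSums(skin_weights) - 1)) > 1e-8)
    stop("skin weight columns must be non-negative and sum to 1",
         call. = FALSE)
  chk <- function(B, name, ncol_expect = NULL) {
    B <- as.matrix(B)
    if (nrow(B) != 3L * n)
      stop(name, " must have 3n rows", call. = FALSE)
    if (!is.null(ncol_expect) && ncol(B) != ncol_expect)
      stop(name, " must have ", ncol_expect, " columns", call. = FALSE)
    B
  }
  structure(list(template = template, faces = as.matrix(faces),
                 shape_basis = chk(shape_basis, "shape_basis"),
                 pose_basis = chk(pose_basis, "pose_basis", 9L * k),
                 expr_basis = chk(expr_basis, "expr_basis"),
                 joints = joints, parents = parents,
                 skin_weights = skin_weights, n = as.integer(n),
                 k = as.integer(k)),
            class = "articulated_model")
}

# linearised pose feature: concatenated (R_j - I) entries, column-major,
# for the k joint rotations (global rotation excluded)
pose_feature <- function(theta, k) {
  out <- numeric(9L * k)
  for (j in seq_len(k)) {
    Rj <- rotation_exp(theta[3L * j + 1:3])
    out[9L * (j - 1L) + 1:9] <- as.numeric(Rj - diag(3))
  }
  out
}

#' Deform an articulated head model
#'
#' Adds the blendshape offsets to the template,
#' `T_P = T + S beta + P pose_feature(theta) + E psi`, then applies linear
#' blend skinning: each vertex is moved by the weight-blended rigid
#' transforms of the joints, each joint rotating about its (shape-corrected)
#' position, composed down the kinematic chain under the global rotation.
#'
#' @param model an `articulated_model`.
#' @param beta,psi shape and expression coefficients (lengths matching the
#'   basis column counts).
#' @param theta pose vector of length `3k + 3`, radians, axis-angle: the
#'   first 3 entries are the global rotation, then 3 per joint.
#' @return a `triangle_mesh`.
#' @export
articulated_deform <- function(model, beta, psi, theta) {
  if (!inherits(model, "articulated_model"))
    stop("expected an 'articulated_model'", call. = FALSE)
  k <- model$k
  theta <- as.numeric(theta)
  if (length(theta) != 3L * k + 3L)
    stop("theta must have length 3k + 3 = ", 3L * k + 3L, call. = FALSE)
  beta <- as.numeric(beta); psi <- as.numeric(psi)
  if (length(beta) != ncol(model$shape_basis))
    stop("beta length must match shape_basis", call. = FALSE)
  if (length(psi) != ncol(model$expr_basis))
    stop("psi length must match expr_basis", call. = FALSE)
  v <- model$template
  if (length(beta)) v <- v + drop(model$shape_basis %*% beta)
  v <- v + drop(model$pose_basis %*% pose_feature(theta, k))
  if (length(psi)) v <- v + drop(model$expr_basis %*% psi)
  V <- matrix(v, ncol = 3L, byrow = TRUE)
  Rg <- rotation_exp(theta[1:3])
  # world transform of each joint: global rotation, then chain of local
  # rotations about the joint positions
  Rw <- vector("list", k); tw <- vector("list", k)
  for (j in seq_len(k)) {
    Rl <- rotation_exp(theta[3L * j + 1:3])
    pj <- model$joints[j, ]
    # local: x -> Rl (x - pj) + pj
    tl <- pj - drop(Rl %*% pj)
    p <- model$parents[j]
    if (p == 0L) {
      Rw[[j]] <- Rg %*% Rl
      tw[[j]] <- drop(Rg %*% tl)
    } else {
      Rw[[j]] <- Rw[[p]] %*% Rl
      tw[[j]] <- drop(Rw[[p]] %*% tl) + tw[[p]]
    }
  }
  out <- matrix(0, nrow(V), 3L)
  for (j in seq_len(k)) {
    w <- model$skin_weights[j, ]
    out <- out + w * (V %*% t(Rw[[j]]) +
                        matrix(tw[[j]], nrow(V), 3L, byrow = TRUE))
  }
  triangle_mesh(out, model$faces)
}

#' Evaluate a dual identity/expression/texture 3DMM
#'
#' Linear model `S = S_mean + Bid alpha + Bexp beta` and
#' `T = T_mean + Bt delta`: shape is mean plus identity and expression
#' offsets, texture is mean plus a texture offset, all linear in their
#' coefficients.
#'
#' @param mean_shape,mean_tex mean shape (length `3n`) and mean texture
#'   vectors.
#' @param Bid,Bexp,Bt identity, expression and texture bases (rows matching
#'   the respective means; any may have 0 columns).
#' @param alpha,beta,delta coefficient vectors.
#' @return list with components `shape` and `texture`.
#' @export
dual_3dmm <- function(mean_shape, mean_tex, Bid, Bexp, Bt,
                      alpha, beta, delta) {
  mean_shape <- as.numeric(mean_shape); mean_tex <- as.numeric(mean_tex)
  ev <- function(mu, B, coef, bname, cname) {
    B <- as.matrix(B)
    if (ncol(B) != length(coef))
      stop(cname, " length must match ", bname, " columns", call. = FALSE)
    if (ncol(B) == 0L) return(mu)
    if (nrow(B) != length(mu))
      stop(bname, " rows must match its mean vector", call. = FALSE)
    mu + drop(B %*% as.numeric(coef))
  }
  s <- ev(mean_shape, as.matrix(Bid), alpha, "Bid", "alpha")
  s <- s - mean_shape + ev(mean_shape, as.matrix(Bexp), beta, "Bexp", "beta")
  list(shape = s, texture = ev(mean_tex, as.matrix(Bt), delta, "Bt", "delta"))
}

## ---- spherical harmonics ---------------------------------------------------

# Real spherical harmonics, bands 0-2, with normalisation constants folded
# in (Ramamoorthi & Hanrahan convention). This single table is the
# definition used by sh_basis() and by the package's tests.
SH_CONSTANTS <- c(Y00 = 0.2820947917738781,    # 1/2 sqrt(1/pi)
                  Y1 = 0.4886025119029199,     # sqrt(3/(4 pi))
                  Y2a = 1.0925484305920792,    # sqrt(15/(4 pi))
                  Y20 = 0.31539156525252005,   # 1/4 sqrt(5/pi)
                  Y22 = 0.5462742152960396)    # 1/4 sqrt(15/pi)

#' Real spherical-harmonics basis, bands 0-2
#'
#' Evaluates the nine real SH basis functions at unit normals, in the order
#' `(Y00, Y1-1, Y10, Y11, Y2-2, Y2-1, Y20, Y21, Y22)` i.e.
#' `(const, y, z, x, xy, yz, 3z^2-1, xz, x^2-y^2)` with the standard
#' normalisation constants folded in.
#'
#' @param normals `n x 3` matrix of unit normals.
#' @return `n x 9` basis matrix.
#' @export
sh_basis <- function(normals) {
  N <- as.matrix(normals)
  if (is.vector(normals) && length(normals) == 3L) N <- matrix(normals, 1L)
  if (ncol(N) != 3L) stop("normals must be n x 3", call. = FALSE)
  len <- sqrt(rowSums(N^2))
  if (any(abs(len - 1) > 1e-6))
    stop("normals must be unit length (max deviation ",
         format(max(abs(len - 1))), ")", call. = FALSE)
  x <- N[, 1]; y <- N[, 2]; z <- N[, 3]
  cbind(SH_CONSTANTS[["Y00"]] + 0 * x,
        SH_CONSTANTS[["Y1"]] * y,
        SH_CONSTANTS[["Y1"]] * z,
        SH_CONSTANTS[["Y1"]] * x,
        SH_CONSTANTS[["Y2a"]] * x * y,
        SH_CONSTANTS[["Y2a"]] * y * z,
        SH_CONSTANTS[["Y20"]] * (3 * z^2 - 1),
        SH_CONSTANTS[["Y2a"]] * x * z,
        SH_CONSTANTS[["Y22"]] * (x^2 - y^2))
}

#' Spherical-harmonics radiosity of mesh vertices
#'
#' Shades each vertex as its texture (albedo) value times a 9-term real SH
#' expansion in the vertex normal:
#' \deqn{C(n_i, t_i) = t_i \cdot \sum_{b=1}^{9} \gamma_b \Phi_b(n_i).}
#'
#' @param normals `n x 3` unit normals.
#' @param texture per-vertex texture: length-`n` vector (grey) or `n x c`
#'   matrix (one column per colour channel).
#' @param gamma SH lighting coefficients: length-9 vector shared by all
#'   channels, or a `9 x c` matrix with one column per channel.
#' @return shaded values with the shape of `texture`.
#' @export
sh_radiosity <- function(normals, texture, gamma) {
  Phi <- sh_basis(normals)
  tex <- if (is.matrix(texture)) texture else matrix(as.numeric(texture))
  if (!is.matrix(gamma) && length(gamma) != 9L)
    stop("gamma must have 9 coefficients per channel", call. = FALSE)
  g <- if (is.matrix(gamma)) gamma else
    matrix(as.numeric(gamma), 9L, ncol(tex))
  if (nrow(g) != 9L)
    stop("gamma must have 9 coefficients per channel", call. = FALSE)
  if (ncol(g) != ncol(tex))
    stop("gamma channels must match texture channels", call. = FALSE)
  if (nrow(tex) != nrow(Phi))
    stop("texture rows must match normals", call. = FALSE)
  out <- tex * (Phi %*% g)
  if (is.matrix(texture)) out else drop(out)
}

## ---- loss functions --------------------------------------------------------

as_channel_matrix <- function(I) {
  if (is.array(I) && length(dim(I)) == 3L)
    matrix(I, prod(dim(I)[1:2]), dim(I)[3])
  else if (is.matrix(I)) I
  else matrix(as.numeric(I))
}

#' Photometric loss
#'
#' Attention-weighted mean, over the face-region mask, of the per-pixel
#' (un-squared) l2 colour difference:
#' \deqn{\frac{\sum_{i \in M} A_i \, \|I_i - I'_i\|_2}{\sum_{i \in M} A_i}.}
#' Note the per-pixel norm is not squared — the loss is in the same units
#' as the pixel values.
#'
#' @param I,I_rendered images as `h x w x c` arrays or `n x c` matrices
#'   (values typically in `[0, 1]`).
#' @param A skin-attention weights per pixel, in `[0, 1]`; defaults to 1.
#' @param M face-region mask per pixel, in `[0, 1]` (0/1 selects pixels);
#'   defaults to 1 everywhere.
#' @return scalar loss.
#' @export
photometric_loss <- function(I, I_rendered, A = NULL, M = NULL) {
  Im <- as_channel_matrix(I); Jm <- as_channel_matrix(I_rendered)
  if (!identical(dim(Im), dim(Jm)))
    stop("images must have identical shape", call. = FALSE)
  n <- nrow(Im)
  A <- if (is.null(A)) rep(1, n) else as.numeric(A)
  M <- if (is.null(M)) rep(1, n) else as.numeric(M)
  if (length(A) != n || length(M) != n)
    stop("mask shape must match the images", call. = FALSE)
  if (any(A < 0 | A > 1) || any(M < 0 | M > 1))
    stop("masks must take values in [0, 1]", call. = FALSE)
  w <- A * M
  denom <- sum(w)
  if (denom <= 0)
    stop("undefined loss: the masked region has zero attention mass",
         call. = FALSE)
  d <- sqrt(rowSums((Im - Jm)^2))
  sum(w * d) / denom
}

#' Landmark loss
#'
#' Weighted mean Euclidean distance between detected and projected
#' landmarks, `(1/N) sum_n w_n ||q_n - q'_n||`. The default weights follow
#' the mouth/nose emphasis convention: 20 for mouth and nose landmarks and
#' 0 for all others (supply `groups`, or pass explicit `weights`).
#'
#' @param q,q_proj `N x 2` matrices of detected and projected landmarks.
#' @param weights length-`N` non-negative weights; overrides `groups`.
#' @param groups optional character vector of landmark group names (e.g.
#'   `"mouth"`, `"nose"`, `"jaw"`) used to build the default weights.
#' @return scalar loss (pixels).
#' @export
landmark_loss <- function(q, q_proj, weights = NULL, groups = NULL) {
  q <- as.matrix(q); q_proj <- as.matrix(q_proj)
  if (!identical(dim(q), dim(q_proj)) || ncol(q) != 2L || nrow(q) < 1L)
    stop("q and q_proj must be equal-size N x 2 with N >= 1", call. = FALSE)
  N <- nrow(q)
  if (is.null(weights)) {
    weights <- if (is.null(groups)) rep(1, N)
    else default_landmark_weights(groups)
  }
  if (length(weights) != N || any(weights < 0))
    stop("weights must be length N and non-negative", call. = FALSE)
  mean(weights * sqrt(rowSums((q - q_proj)^2)))
}

#' @rdname landmark_loss
#' @export
default_landmark_weights <- function(groups) {
  ifelse(groups %in% c("mouth", "nose"), 20, 0)
}

#' Perception loss
#'
#' One minus the cosine similarity of two deep feature vectors,
#' `1 - <f, f'> / (||f|| ||f'||)`; lies in `[0, 2]` and is invariant to
#' positive rescaling of either vector.
#'
#' @param f_I,f_I_rendered feature vectors of equal length, non-zero norm.
#' @return scalar in `[0, 2]`.
#' @export
perception_loss <- function(f_I, f_I_rendered) {
  f1 <- as.numeric(f_I); f2 <- as.numeric(f_I_rendered)
  if (length(f1) != length(f2))
    stop("feature vectors must have equal length", call. = FALSE)
  n1 <- sqrt(sum(f1^2)); n2 <- sqrt(sum(f2^2))
  if (n1 == 0 || n2 == 0)
    stop("undefined loss: zero-norm feature vector", call. = FALSE)
  1 - sum(f1 * f2) / (n1 * n2)
}

#' Coefficient regularisation loss
#'
#' Weighted squared l2 norms of the identity, expression and texture
#' coefficient vectors, `w_a ||alpha||^2 + w_b ||beta||^2 + w_d ||delta||^2`,
#' pulling the solution towards the mean face. Default weights
#' `(1.0, 0.8, 0.0017)`.
#'
#' @param alpha,beta,delta coefficient vectors (may be empty).
#' @param weights length-3 non-negative weights for alpha, beta, delta.
#' @return scalar loss.
#' @export
coef_reg_loss <- function(alpha, beta = numeric(0), delta = numeric(0),
                          weights = c(1.0, 0.8, 0.0017)) {
  if (length(weights) != 3L || any(weights < 0))
    stop("weights must be 3 non-negative values", call. = FALSE)
  weights[1] * sum(as.numeric(alpha)^2) +
    weights[2] * sum(as.numeric(beta)^2) +
    weights[3] * sum(as.numeric(delta)^2)
}

#' Texture flattening loss
#'
#' Sum over colour channels of the (population) variance of the texture
#' values within a predefined smooth-skin region (cheek, nose, forehead);
#' penalises high-frequency texture inside the region.
#'
#' @param texture `n x c` per-vertex texture matrix (or length-`n` vector).
#' @param region_ids indices of the vertices forming the skin region.
#' @return scalar loss.
#' @export
texture_flatten_loss <- function(texture, region_ids) {
  tex <- if (is.matrix(texture)) texture else matrix(as.numeric(texture))
  region_ids <- as.integer(region_ids)
  if (length(region_ids) == 0L)
    stop("region_ids must be non-empty", call. = FALSE)
  if (any(region_ids < 1L | region_ids > nrow(tex)))
    stop("region_ids out of range", call. = FALSE)
  sub <- tex[region_ids, , drop = FALSE]
  mu <- colMeans(sub)
  sum(colMeans(sweep(sub, 2L, mu)^2))      # population variance per channel
}

#' Eye-closure loss
#'
#' Mean absolute difference between predicted and detected vertical
#' eyelid gaps, over upper/lower eyelid landmark pairs: penalises the
#' relative variation between landmarks on the upper and lower eyelid.
#'
#' @param q,q_proj `N x 2` detected and projected landmark matrices.
#' @param upper_ids,lower_ids equal-length index vectors of paired
#'   upper/lower eyelid landmarks (rows of `q`).
#' @return scalar loss (pixels).
#' @export
eye_closure_loss <- function(q, q_proj, upper_ids, lower_ids) {
  if (length(upper_ids) != length(lower_ids) || length(upper_ids) == 0L)
    stop("upper_ids and lower_ids must be equal-length, non-empty",
         call. = FALSE)
  q <- as.matrix(q); q_proj <- as.matrix(q_proj)
  gap_det <- q[lower_ids, 2] - q[upper_ids, 2]
  gap_prd <- q_proj[lower_ids, 2] - q_proj[upper_ids, 2]
  mean(abs(gap_prd - gap_det))
}

#' Soft symmetry loss for a UV displacement map
#'
#' Mean absolute difference between a displacement map and its horizontal
#' flip; zero for a bilaterally symmetric map. Used to regularise detail
#' reconstruction under self-occlusion.
#'
#' @param D displacement map, a numeric matrix (UV grid).
#' @return scalar loss.
#' @export
symmetry_loss <- function(D) {
  D <- as.matrix(D)
  mean(abs(D - D[, rev(seq_len(ncol(D))), drop = FALSE]))
}

#' Shape-consistency loss
#'
#' Squared l2 distance between the identity-shape coefficients recovered
#' from two images of the same subject.
#'
#' @param beta_a,beta_b equal-length coefficient vectors.
#' @return scalar loss.
#' @export
shape_consistency_loss <- function(beta_a, beta_b) {
  a <- as.numeric(beta_a); b <- as.numeric(beta_b)
  if (length(a) != length(b))
    stop("coefficient vectors must have equal length", call. = FALSE)
  sum((a - b)^2)
}

aggregate_loss <- function(components, required, weights, defaults = list()) {
  for (nm in names(defaults))
    if (is.null(components[[nm]])) components[[nm]] <- defaults[[nm]]
  missing <- setdiff(required, names(components))
  if (length(missing))
    stop("missing loss component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  w <- stats::setNames(rep(1, length(required)), required)
  if (!is.null(weights)) w[names(weights)] <- unlist(weights)
  sum(vapply(required, function(nm) w[[nm]] * components[[nm]], 0))
}

#' Aggregate coarse-reconstruction loss
#'
#' Sum of the coarse-stage loss components: landmark, eye closure,
#' photometric, identity (perception on face-recognition embeddings),
#' shape consistency across same-subject images, and coefficient
#' regularisation. Aggregation weights default to 1 for every term.
#'
#' @param components named list with entries `landmark`, `eye`,
#'   `photometric`, `identity`, `shape_consistency`, `regularization`
#'   (each a scalar, typically from the corresponding loss function).
#' @param weights optional named per-term weights (default all 1).
#' @return scalar total loss.
#' @export
coarse_loss <- function(components, weights = NULL) {
  aggregate_loss(components,
                 c("landmark", "eye", "photometric", "identity",
                   "shape_consistency", "regularization"), weights)
}

#' Aggregate detail-reconstruction loss
#'
#' Sum of the detail-stage components: detail photometric loss, an
#' externally supplied Markov-random-field detail score (`mrf`, default 0
#' because its definition is external to this package), soft symmetry of
#' the displacement map, and detail regularisation (`||D||^2`).
#'
#' @param components named list with entries `photometric_detail`,
#'   `symmetry`, `regularization_detail` and optionally `mrf`.
#' @param weights optional named per-term weights (default all 1).
#' @return scalar total loss.
#' @export
detail_loss <- function(components, weights = NULL) {
  aggregate_loss(components,
                 c("photometric_detail", "mrf", "symmetry",
                   "regularization_detail"),
                 weights, defaults = list(mrf = 0))
}
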