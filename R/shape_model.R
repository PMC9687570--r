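#' Flatten a mesh into a shape vector
#'
#' Serialises vertices in interleaved per-vertex order
#' `(x1, y1, z1, x2, y2, z2, ...)` — the convention used throughout the
#' package for shape vectors, PCA bases and blendshape matrices.
#'
#' @param mesh a `triangle_mesh`.
#' @return numeric vector of length `3 * n_vertices(mesh)`, millimetres.
#' @examples
#' m <- triangle_mesh(rbind(c(1, 2, 3)), matrix(integer(0), 0, 3))
#' flatten_mesh(m)  # c(1, 2, 3)
#' @export
flatten_mesh <- function(mesh) {
  stopifnot_mesh(mesh)
  as.numeric(t(mesh$vertices))
}

#' Rebuild a mesh from a shape vector
#'
#' Inverse of [flatten_mesh()]: `unflatten(flatten_mesh(m), m$faces)`
#' reproduces `m` exactly.
#'
#' @param vec shape vector, length divisible by 3, interleaved order.
#' @param faces face index matrix valid for `length(vec) / 3` vertices.
#' @return a `triangle_mesh`.
#' @export
unflatten <- function(vec, faces) {
  if (!is.numeric(vec) || length(vec) %% 3L != 0L)
    stop("shape vector length must be divisible by 3", call. = FALSE)
  triangle_mesh(matrix(vec, ncol = 3L, byrow = TRUE), faces)
}

#' Build a PCA morphable model from a corresponded mesh corpus
#'
#' All corpus meshes must share a vertex count, vertex semantics and face
#' list. Shapes are flattened, centred on the corpus mean, and decomposed by
#' thin SVD (the covariance matrix is never formed). The returned basis has
#' unit-norm, pairwise-orthonormal columns; the natural scale of each mode
#' lives in `mode_sd` (millimetres, `singular value / sqrt(n - 1)`), so that
#' user-facing shape coefficients are dimensionless, in standard-deviation
#' units. Basis column signs follow a deterministic convention: the entry of
#' largest absolute value in each column is made positive.
#'
#' @param corpus list of `triangle_mesh`, identical vertex counts and faces.
#' @param k number of modes to keep, `1 <= k <= length(corpus) - 1`. The
#'   default keeps the smallest `k` explaining at least 99\% of total
#'   variance.
#' @param landmark_vertex_ids integer vector of distinct vertex indices
#'   (1-based) marking the model's named landmarks, or `NULL`.
#' @return an object of class `morphable_model` with fields `mean_shape`,
#'   `basis` (`3m x k`), `mode_sd` (length `k`), `faces`,
#'   `landmark_vertex_ids`, `n_train`.
#' @export
build_morphable_model <- function(corpus, k = NULL, landmark_vertex_ids = NULL) {
  if (!is.list(corpus) || length(corpus) < 2L)
    stop("corpus must be a list of at least 2 meshes", call. = FALSE)
  lapply(corpus, stopifnot_mesh)
  m <- n_vertices(corpus[[1L]])
  faces <- corpus[[1L]]$faces
  for (msh in corpus) {
    if (n_vertices(msh) != m || !identical(msh$faces, faces))
      stop("corpus meshes must share vertex count and face list", call. = FALSE)
  }
  n <- length(corpus)
  X <- vapply(corpus, flatten_mesh, numeric(3L * m))   # 3m x n
  mean_shape <- rowMeans(X)
  Xc <- X - mean_shape
  sv <- svd(Xc, nu = n - 1L, nv = 0L)
  sd_all <- sv$d[seq_len(n - 1L)] / sqrt(n - 1)
  if (is.null(k)) {
    tot <- sum(sd_all^2)
    k <- if (tot <= 0) 1L else
      min(which(cumsum(sd_all^2) >= 0.99 * tot))
  }
  k <- as.integer(k)
  if (k < 1L || k > n - 1L)
    stop("k must satisfy 1 <= k <= n - 1 = ", n - 1L, call. = FALSE)
  basis <- sv$u[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|entry| of each column positive
  for (j in seq_len(k)) {
    piv <- which.max(abs(basis[, j]))
    if (basis[piv, j] < 0) basis[, j] <- -basis[, j]
  }
  mode_sd <- sd_all[seq_len(k)]
  near_zero <- mode_sd <= .Machine$double.eps * max(sd_all[1L], 1) * 10
  if (any(near_zero))
    warning("corpus has (near-)zero variance in ", sum(near_zero),
            " requested mode(s); mode_sd contains zeros", call. = FALSE)
  if (!is.null(landmark_vertex_ids)) {
    landmark_vertex_ids <- as.integer(landmark_vertex_ids)
    if (anyDuplicated(landmark_vertex_ids) ||
        any(landmark_vertex_ids < 1L | landmark_vertex_ids > m))
      stop("landmark_vertex_ids must be distinct vertex indices in [1, m]",
           call. = FALSE)
  }
  structure(list(mean_shape = mean_shape, basis = basis, mode_sd = mode_sd,
                 faces = faces, landmark_vertex_ids = landmark_vertex_ids,
                 n_train = n, m = m, k = k),
            class = "morphable_model")
}

#' @export
print.morphable_model <- function(x, ...) {
  cat("morphable_model:", x$m, "vertices,", x$k, "modes (from",
      x$n_train, "training shapes)\n")
  cat("  mode SDs [mm]:", paste(sprintf("%.3g", utils::head(x$mode_sd, 8L)),
                                collapse = " "),
      if (x$k > 8L) "..." else "", "\n")
  if (!is.null(x$landmark_vertex_ids))
    cat("  landmarks:", length(x$landmark_vertex_ids), "vertices\n")
  invisible(x)
}

stopifnot_model <- function(model) {
  if (!inherits(model, "morphable_model"))
    stop("expected a 'morphable_model' object", call. = FALSE)
  invisible(model)
}

check_coeffs <- function(model, alpha) {
  alpha <- as.numeric(alpha)
  if (length(alpha) != model$k)
    stop("coefficient vector length ", length(alpha),
         " does not match model k = ", model$k, call. = FALSE)
  if (!all(is.finite(alpha)))
    stop("non-finite shape coefficients", call. = FALSE)
  alpha
}

#' Synthesize a mesh from shape coefficients
#'
#' Evaluates the linear shape model
#' \deqn{S(\alpha) = S_0 + \sum_j B_j \, \sigma_j \, \alpha_j}
#' where \eqn{B_j} are the unit-norm PCA modes and \eqn{\sigma_j} the
#' per-mode standard deviations; `alpha` is dimensionless (SD units).
#'
#' @param model a `morphable_model`.
#' @param alpha numeric coefficient vector of length `model$k`.
#' @return a `triangle_mesh`.
#' @export
synthesize_shape <- function(model, alpha) {
  stopifnot_model(model)
  alpha <- check_coeffs(model, alpha)
  v <- model$mean_shape + drop(model$basis %*% (model$mode_sd * alpha))
  unflatten(v, model$faces)
}

#' Project a mesh onto the model's coefficient space
#'
#' Least-squares shape coefficients of a corresponded mesh: the orthogonal
#' projection of the centred shape vector onto the PCA span, rescaled to SD
#' units. Exact inverse of [synthesize_shape()] for in-span shapes; for a
#' general mesh the out-of-span residual norm is attached as attribute
#' `residual` (millimetres).
#'
#' @inheritParams synthesize_shape
#' @param mesh a `triangle_mesh` with `model$m` vertices.
#' @return numeric coefficient vector with attribute `residual`.
#' @export
project_coeffs <- function(model, mesh) {
  stopifnot_model(model)
  stopifnot_mesh(mesh)
  if (n_vertices(mesh) != model$m)
    stop("mesh vertex count ", n_vertices(mesh),
         " does not match model m = ", model$m, call. = FALSE)
  d <- flatten_mesh(mesh) - model$mean_shape
  proj <- drop(crossprod(model$basis, d))           # orthonormal columns
  alpha <- ifelse(model$mode_sd > 0, proj / model$mode_sd, 0)
  res <- sqrt(max(0, sum(d^2) - sum(proj^2)))
  structure(alpha, residual = res)
}

#' Save / load a morphable model
#'
#' The model is stored as a single JSON archive: mean shape, basis, per-mode
#' SDs, face list, landmark vertex indices, plus a metadata block recording
#' `m`, `k`, units (mm) and the interleaved flattening convention.
#'
#' @param model a `morphable_model`.
#' @param path file path (conventionally `.json`).
#' @return `path` invisibly; `read_morphable_model()` returns the model.
#' @export
write_morphable_model <- function(model, path) {
  stopifnot_model(model)
  obj <- list(
    metadata = list(format = "morphfit-model", version = 1L,
                    m = model$m, k = model$k, n_train = model$n_train,
                    units = "mm",
                    flattening = "interleaved x1,y1,z1,...,xm,ym,zm"),
    mean_shape = model$mean_shape,
    basis = model$basis,
    mode_sd = model$mode_sd,
    faces = model$faces,
    landmark_vertex_ids = model$landmark_vertex_ids)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_morphable_model
#' @export
read_morphable_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$metadata$format) || obj$metadata$format != "morphfit-model")
    stop("not a morphfit model archive", call. = FALSE)
  lmk <- obj$landmark_vertex_ids
  if (length(lmk) == 0L) lmk <- NULL else lmk <- as.integer(lmk)
  structure(list(mean_shape = as.numeric(obj$mean_shape),
                 basis = matrix(as.numeric(obj$basis), ncol = obj$metadata$k),
                 mode_sd = as.numeric(obj$mode_sd),
                 faces = matrix(as.integer(obj$faces), ncol = 3L),
                 landmark_vertex_ids = lmk,
                 n_train = obj$metadata$n_train,
                 m = obj$metadata$m, k = obj$metadata$k),
            class = "morphable_model")
}
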