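# Independent oracles and tiny fixtures used across the test files.
# Oracles are deliberately written with different algorithms from the
# package implementations they check.

# closest point on one triangle by KKT case enumeration: unconstrained
# least squares in barycentric (u, v), else the best of the three clamped
# edge projections
oracle_point_tri_dist <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a
  M <- cbind(ab, ac)
  uv <- tryCatch(solve(crossprod(M), crossprod(M, p - a)),
                 error = function(e) c(-1, -1))
  u <- uv[1]; v <- uv[2]
  if (u >= 0 && v >= 0 && u + v <= 1)
    return(sqrt(sum((a + u * ab + v * ac - p)^2)))
  seg <- function(q0, q1) {
    d <- q1 - q0
    t <- sum((p - q0) * d) / sum(d * d)
    t <- min(1, max(0, t))
    sqrt(sum((q0 + t * d - p)^2))
  }
  min(seg(a, b), seg(a, c), seg(b, c))
}

oracle_point_mesh_dist <- function(p, mesh) {
  V <- mesh$vertices; F <- mesh$faces
  min(vapply(seq_len(nrow(F)), function(i)
    oracle_point_tri_dist(p, V[F[i, 1], ], V[F[i, 2], ], V[F[i, 3], ]), 0))
}

# brute-force scaled orthographic projection, scalar arithmetic
oracle_sop <- function(P, R, t, s) {
  out <- matrix(0, nrow(P), 2)
  for (i in seq_len(nrow(P))) {
    q <- R %*% P[i, ]
    out[i, ] <- s * c(q[1] + t[1], q[2] + t[2])
  }
  out
}

# term-by-term real SH evaluation, bands 0-2, from the same published
# constant table the package documents
oracle_sh <- function(n) {
  x <- n[1]; y <- n[2]; z <- n[3]
  c(0.282095,
    0.488603 * y, 0.488603 * z, 0.488603 * x,
    1.092548 * x * y, 1.092548 * y * z,
    0.315392 * (3 * z^2 - 1),
    1.092548 * x * z, 0.546274 * (x^2 - y^2))
}

# per-vertex weighted-transform LBS, scalar loops, flat hierarchy handled
# by explicit world-transform recursion
oracle_lbs <- function(V, joints, parents, rots, Rg, W) {
  k <- nrow(joints)
  Rw <- vector("list", k); tw <- vector("list", k)
  for (j in seq_len(k)) {
    tl <- joints[j, ] - rots[[j]] %*% joints[j, ]
    if (parents[j] == 0) {
      Rw[[j]] <- Rg %*% rots[[j]]
      tw[[j]] <- as.numeric(Rg %*% tl)
    } else {
      Rw[[j]] <- Rw[[parents[j]]] %*% rots[[j]]
      tw[[j]] <- as.numeric(Rw[[parents[j]]] %*% tl) + tw[[parents[j]]]
    }
  }
  out <- matrix(0, nrow(V), 3)
  for (i in seq_len(nrow(V))) for (j in seq_len(k))
    out[i, ] <- out[i, ] + W[j, i] * (Rw[[j]] %*% V[i, ] + tw[[j]])
  out
}

# small fixtures ------------------------------------------------------------

tetra_mesh <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
}

unit_square_mesh <- function(z = 0) {
  triangle_mesh(rbind(c(0, 0, z), c(1, 0, z), c(1, 1, z), c(0, 1, z)),
                rbind(c(1, 2, 3), c(1, 3, 4)))
}

random_rotation <- function() {
  w <- stats::rnorm(3)
  rotation_exp(w / sqrt(sum(w^2)) * stats::runif(1, 0, pi / 2))
}

random_small_mesh <- function(n_tri = 20, spread = 10) {
  # random triangle soup as an indexed mesh (vertices shared at random to
  # exercise vertex/edge cases); every vertex appears in some face
  V <- matrix(stats::rnorm(3 * (n_tri + 2), sd = spread), ncol = 3)
  F <- t(vapply(seq_len(n_tri),
                function(i) sort(sample.int(nrow(V), 3)), integer(3)))
  used <- sort(unique(as.integer(F)))
  triangle_mesh(V[used, , drop = FALSE],
                matrix(match(as.integer(F), used), ncol = 3))
}
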