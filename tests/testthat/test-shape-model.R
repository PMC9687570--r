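make_corpus <- function(model, n, seed = 1, coeff_scale = 1) {
  lapply(seq_len(n), function(i)
    sample_subject(model, coeff_scale, seed = seed * 1000 + i)$mesh)
}

test_that("two-sample PCA has the closed-form single mode", {
  base <- tetra_mesh()
  m2 <- base
  delta <- 0.7
  m2$vertices[2, 1] <- m2$vertices[2, 1] + 2 * delta
  model <- build_morphable_model(list(base, m2), k = 1)
  # mode concentrated on vertex 2's x coordinate, sd = delta * sqrt(2)
  expect_equal(model$mode_sd, delta * sqrt(2), tolerance = 1e-12)
  expect_equal(abs(model$basis[4, 1]), 1, tolerance = 1e-12)
  expect_equal(sum(model$basis[-4, 1]^2), 0, tolerance = 1e-20)
  expect_equal(model$mean_shape[4], base$vertices[2, 1] + delta)
})

test_that("corpus errors are caught", {
  base <- tetra_mesh()
  other <- triangle_mesh(base$vertices[1:3, ], rbind(c(1, 2, 3)))
  expect_error(build_morphable_model(list(base, other)), "share vertex count")
  expect_error(build_morphable_model(list(base)), "at least 2")
  expect_error(build_morphable_model(make_corpus(
    make_truth_model(seed = 1, m_vertices = 100, k_modes = 3), 4), k = 4),
    "k must satisfy")
  expect_warning(build_morphable_model(list(base, base), k = 1),
                 "zero variance")
})

test_that("built models satisfy orthonormality and variance conservation", {
  truth <- make_truth_model(seed = 5, m_vertices = 150, k_modes = 6)
  corpus <- make_corpus(truth, 12, seed = 9)
  n <- length(corpus)
  model <- build_morphable_model(corpus, k = n - 1)
  expect_lt(max(abs(crossprod(model$basis) - diag(n - 1))), 1e-8)
  expect_true(all(diff(model$mode_sd) <= 1e-12))
  X <- vapply(corpus, flatten_mesh, numeric(3 * truth$m))
  total_var <- sum(apply(X, 1, stats::var))
  expect_equal(sum(model$mode_sd^2), total_var, tolerance = 1e-6)
})

test_that("training shapes are reconstructed exactly at full rank", {
  truth <- make_truth_model(seed = 2, m_vertices = 120, k_modes = 4)
  corpus <- make_corpus(truth, 8, seed = 4)
  model <- build_morphable_model(corpus, k = 7)
  for (mesh in corpus[c(1, 5)]) {
    alpha <- project_coeffs(model, mesh)
    recon <- synthesize_shape(model, alpha)
    expect_lt(max(abs(recon$vertices - mesh$vertices)), 1e-6)
  }
})

test_that("translation equivariance: mean shifts, basis and sd unchanged", {
  truth <- make_truth_model(seed = 6, m_vertices = 100, k_modes = 3)
  corpus <- make_corpus(truth, 6, seed = 7)
  v <- c(12, -5, 30)
  shifted <- lapply(corpus, function(m)
    triangle_mesh(sweep(m$vertices, 2, v, "+"), m$faces))
  m1 <- build_morphable_model(corpus, k = 3)
  m2 <- build_morphable_model(shifted, k = 3)
  expect_equal(m2$mean_shape, m1$mean_shape + rep(v, truth$m),
               tolerance = 1e-8)
  expect_lt(max(abs(m2$basis - m1$basis)), 1e-8)
  expect_equal(m2$mode_sd, m1$mode_sd, tolerance = 1e-8)
})

test_that("synthesize is linear and symmetric about the mean", {
  model <- make_truth_model(seed = 8, m_vertices = 100, k_modes = 5)
  mean_mesh <- synthesize_shape(model, numeric(5))
  expect_equal(mean_mesh$vertices,
               unflatten(model$mean_shape, model$faces)$vertices)
  e1 <- c(1, 0, 0, 0, 0)
  m_e1 <- synthesize_shape(model, e1)
  expect_equal(flatten_mesh(m_e1),
               model$mean_shape + model$mode_sd[1] * model$basis[, 1])
  a <- c(0.3, -1.2, 0.5, 2, -0.7)
  plus <- synthesize_shape(model, a)
  minus <- synthesize_shape(model, -a)
  expect_equal(plus$vertices + minus$vertices, 2 * mean_mesh$vertices,
               tolerance = 1e-10)
  expect_error(synthesize_shape(model, numeric(3)), "length")
})

test_that("project_coeffs inverts synthesize_shape and splits residuals", {
  model <- make_truth_model(seed = 10, m_vertices = 100, k_modes = 5)
  expect_equal(as.numeric(project_coeffs(
    model, synthesize_shape(model, numeric(5)))), numeric(5))
  set.seed(42)
  a <- rnorm(5)
  ahat <- project_coeffs(model, synthesize_shape(model, a))
  expect_lt(max(abs(as.numeric(ahat) - a)), 1e-8)
  # out-of-span perturbation: coefficients unchanged, residual = its norm
  perp <- rnorm(3 * model$m)
  perp <- perp - model$basis %*% crossprod(model$basis, perp)
  mesh <- unflatten(model$mean_shape +
                      model$basis %*% (model$mode_sd * a) + perp,
                    model$faces)
  ahat2 <- project_coeffs(model, mesh)
  expect_lt(max(abs(as.numeric(ahat2) - a)), 1e-8)
  expect_equal(attr(ahat2, "residual"), sqrt(sum(perp^2)), tolerance = 1e-8)
})

test_that("mode subspace is recovered from a large synthetic corpus", {
  truth <- make_truth_model(seed = 11, m_vertices = 120, k_modes = 10)
  corpus <- make_corpus(truth, 200, seed = 12)
  model <- build_morphable_model(corpus, k = 10)
  # principal angles between true and recovered 10-dim subspaces
  sv <- svd(crossprod(truth$basis, model$basis))$d
  angles <- acos(pmin(1, sv)) * 180 / pi
  expect_lt(max(angles), 5)
})

test_that("model archive round-trips through JSON", {
  model <- make_truth_model(seed = 13, m_vertices = 100, k_modes = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_morphable_model(model, path)
  back <- read_morphable_model(path)
  expect_equal(back$mean_shape, model$mean_shape)
  expect_equal(back$basis, model$basis, ignore_attr = TRUE)
  expect_equal(back$mode_sd, model$mode_sd)
  expect_identical(back$faces, model$faces)
  expect_equal(back$landmark_vertex_ids, model$landmark_vertex_ids)
  a <- c(0.5, -1, 0.25, 2)
  expect_equal(synthesize_shape(back, a)$vertices,
               synthesize_shape(model, a)$vertices)
})
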