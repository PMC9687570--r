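# toy articulated rig: 8 cube corners, global + 2 joints
toy_rig <- function() {
  V <- as.matrix(expand.grid(x = c(0, 10), y = c(0, 10), z = c(0, 10)))
  n <- nrow(V)
  W <- rbind(rep(0.25, n), rep(0.75, n))
  articulated_model(template = as.numeric(t(V)),
                    faces = rbind(c(1, 2, 3), c(5, 6, 7)),
                    shape_basis = matrix(0, 3 * n, 2),
                    pose_basis = matrix(0, 3 * n, 18),
                    expr_basis = matrix(0, 3 * n, 1),
                    joints = rbind(c(5, 5, 0), c(5, 5, 10)),
                    parents = c(0L, 1L), skin_weights = W)
}

test_that("articulated model validates its rig", {
  V <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  bad_w <- matrix(0.4, 2, 8)  # columns sum to 0.8
  expect_error(articulated_model(as.numeric(t(V)), rbind(c(1, 2, 3)),
                                 matrix(0, 24, 0), matrix(0, 24, 18),
                                 matrix(0, 24, 0), rbind(c(0, 0, 0), c(1, 1, 1)),
                                 c(0L, 1L), bad_w), "sum to 1")
})

test_that("rest pose returns the template exactly", {
  rig <- toy_rig()
  out <- articulated_deform(rig, beta = c(0, 0), psi = 0,
                            theta = numeric(9))
  expect_identical(as.numeric(t(out$vertices)), rig$template)
})

test_that("a pure global rotation is a rigid motion", {
  rig <- toy_rig()
  th <- c(0.4, -0.2, 0.7, numeric(6))
  out <- articulated_deform(rig, c(0, 0), 0, th)
  V0 <- matrix(rig$template, ncol = 3, byrow = TRUE)
  D0 <- as.matrix(dist(V0))
  D1 <- as.matrix(dist(out$vertices))
  expect_lt(max(abs(D0 - D1)), 1e-8)
  # and equals the rotation applied directly
  expect_equal(out$vertices, V0 %*% t(rotation_exp(th[1:3])),
               tolerance = 1e-10)
})

test_that("LBS matches an independent per-vertex weighted-transform oracle", {
  rig <- toy_rig()
  set.seed(5)
  th <- rnorm(9, sd = 0.3)
  out <- articulated_deform(rig, c(0, 0), 0, th)
  rots <- list(rotation_exp(th[4:6]), rotation_exp(th[7:9]))
  expected <- oracle_lbs(matrix(rig$template, ncol = 3, byrow = TRUE),
                         rig$joints, rig$parents, rots,
                         rotation_exp(th[1:3]), rig$skin_weights)
  expect_equal(out$vertices, expected, tolerance = 1e-10)
})

test_that("blendshape offsets add before skinning", {
  rig <- toy_rig()
  B <- matrix(0, 24, 2)
  B[1, 1] <- 1            # vertex 1 x
  rig$shape_basis <- B
  out0 <- articulated_deform(rig, c(0, 0), 0, numeric(9))
  out1 <- articulated_deform(rig, c(2, 0), 0, numeric(9))
  expect_equal(out1$vertices[1, 1] - out0$vertices[1, 1], 2)
  expect_equal(out1$vertices[-1, ], out0$vertices[-1, ])
})

test_that("dual 3DMM is linear and matches matrix arithmetic", {
  set.seed(9)
  n <- 12
  ms <- rnorm(3 * n); mt <- rnorm(3 * n)
  Bid <- matrix(rnorm(3 * n * 4), ncol = 4)
  Bexp <- matrix(rnorm(3 * n * 3), ncol = 3)
  Bt <- matrix(rnorm(3 * n * 2), ncol = 2)
  z <- dual_3dmm(ms, mt, Bid, Bexp, Bt, numeric(4), numeric(3), numeric(2))
  expect_equal(z$shape, ms)
  expect_equal(z$texture, mt)
  a1 <- rnorm(4); a2 <- rnorm(4); b <- rnorm(3); d <- rnorm(2)
  out <- dual_3dmm(ms, mt, Bid, Bexp, Bt, a1, b, d)
  expect_equal(out$shape, ms + drop(Bid %*% a1) + drop(Bexp %*% b),
               tolerance = 1e-12)
  expect_equal(out$texture, mt + drop(Bt %*% d), tolerance = 1e-12)
  # superposition in alpha
  f <- function(a) dual_3dmm(ms, mt, Bid, Bexp, Bt, a, b, d)$shape
  expect_equal(f(a1 + a2) - f(a1) - f(a2) + f(numeric(4)),
               rep(0, 3 * n), tolerance = 1e-10)
})

test_that("SH basis has 9 functions and matches the published constants", {
  set.seed(3)
  N <- matrix(rnorm(30), ncol = 3)
  N <- N / sqrt(rowSums(N^2))
  Phi <- sh_basis(N)
  expect_identical(ncol(Phi), 9L)
  for (i in seq_len(nrow(N)))
    expect_equal(Phi[i, ], oracle_sh(N[i, ]), tolerance = 1e-5,
                 ignore_attr = TRUE)
  expect_error(sh_basis(N * 1.01), "unit length")
})

test_that("SH radiosity: ambient term, zero texture, full oracle", {
  set.seed(4)
  N <- matrix(rnorm(24), ncol = 3)
  N <- N / sqrt(rowSums(N^2))
  tex <- runif(8)
  g_amb <- c(2.5, numeric(8))
  expect_equal(sh_radiosity(N, tex, g_amb), tex * 2.5 * 0.2820948,
               tolerance = 1e-6)
  expect_equal(sh_radiosity(N, numeric(8), rnorm(9)), numeric(8))
  g <- rnorm(9)
  manual <- vapply(1:8, function(i) tex[i] * sum(g * oracle_sh(N[i, ])), 0)
  expect_equal(sh_radiosity(N, tex, g), manual, tolerance = 1e-5)
  # per-channel coefficients
  g3 <- matrix(rnorm(27), 9, 3)
  tex3 <- matrix(runif(24), 8, 3)
  out <- sh_radiosity(N, tex3, g3)
  expect_equal(out[, 2], tex3[, 2] * drop(sh_basis(N) %*% g3[, 2]))
  expect_error(sh_radiosity(N, tex, rnorm(8)), "9 coefficients")
})

test_that("photometric loss: closed forms, oracle, permutation invariance", {
  set.seed(6)
  I <- array(runif(5 * 4 * 3), dim = c(5, 4, 3))
  expect_equal(photometric_loss(I, I), 0)
  shift <- I + 0.1
  expect_equal(photometric_loss(I, shift), 0.1 * sqrt(3), tolerance = 1e-12)
  A <- runif(20); M <- rep(1, 20)
  J <- array(runif(60), dim = c(5, 4, 3))
  Im <- matrix(I, 20, 3); Jm <- matrix(J, 20, 3)
  manual <- {
    num <- 0; den <- 0
    for (i in 1:20) {
      num <- num + A[i] * sqrt(sum((Im[i, ] - Jm[i, ])^2))
      den <- den + A[i]
    }
    num / den
  }
  expect_equal(photometric_loss(I, J, A, M), manual, tolerance = 1e-12)
  perm <- sample(20)
  expect_equal(photometric_loss(Im[perm, ], Jm[perm, ], A[perm], M[perm]),
               photometric_loss(Im, Jm, A, M), tolerance = 1e-12)
  expect_error(photometric_loss(I, J, A * 0, M), "zero attention")
})

test_that("landmark loss closed forms and mouth/nose default weights", {
  q <- matrix(0, 68, 2)
  qp <- q
  expect_equal(landmark_loss(q, qp), 0)
  groups <- c(rep("jaw", 17), rep("brow", 10), rep("nose", 9),
              rep("eye", 12), rep("mouth", 20))
  qp[49, ] <- c(3, 4)       # one mouth landmark off by a 3-4-5 triangle
  expect_equal(landmark_loss(q, qp, groups = groups), 20 * 5 / 68)
  set.seed(8)
  q <- matrix(rnorm(20), 10, 2); qp <- matrix(rnorm(20), 10, 2)
  w <- runif(10, 0, 5)
  manual <- mean(sapply(1:10, function(i)
    w[i] * sqrt(sum((q[i, ] - qp[i, ])^2))))
  expect_equal(landmark_loss(q, qp, weights = w), manual, tolerance = 1e-12)
})

test_that("perception loss spans [0, 2] and is scale invariant", {
  f <- c(1, 2, 3)
  expect_equal(perception_loss(f, 2 * f), 0)
  expect_equal(perception_loss(c(1, 0), c(0, 1)), 1)
  expect_equal(perception_loss(f, -f), 2)
  set.seed(10)
  g <- rnorm(3)
  expect_equal(perception_loss(f, g), perception_loss(5 * f, 0.01 * g),
               tolerance = 1e-12)
  expect_error(perception_loss(f, c(0, 0, 0)), "zero-norm")
})

test_that("coefficient regularisation uses the printed weights", {
  expect_equal(coef_reg_loss(numeric(3), numeric(2), numeric(4)), 0)
  expect_equal(coef_reg_loss(c(1, 0), numeric(0), numeric(0)), 1.0)
  expect_equal(coef_reg_loss(1, 1, 1), 1.8017)
})

test_that("texture flattening is the summed per-channel variance", {
  expect_equal(texture_flatten_loss(matrix(0.5, 10, 3), 1:10), 0)
  tex <- matrix(c(0, 2), 2, 3)   # two vertices, grey 0 and 2, all channels
  expect_equal(texture_flatten_loss(tex, 1:2), 3)
  set.seed(12)
  tex <- matrix(runif(30), 10, 3)
  ids <- c(2, 5, 7, 9)
  pvar <- function(x) mean((x - mean(x))^2)
  expect_equal(texture_flatten_loss(tex, ids),
               sum(apply(tex[ids, ], 2, pvar)), tolerance = 1e-12)
  expect_error(texture_flatten_loss(tex, integer(0)), "non-empty")
})

test_that("eye closure and symmetry components behave", {
  q <- cbind(0, c(1, 3))      # upper at y=1, lower at y=3: gap 2
  qp <- cbind(0, c(1, 4))     # predicted gap 3
  expect_equal(eye_closure_loss(q, qp, upper_ids = 1, lower_ids = 2), 1)
  D <- matrix(runif(20), 4, 5)
  Dsym <- (D + D[, 5:1]) / 2
  expect_equal(symmetry_loss(Dsym), 0)
  expect_gt(symmetry_loss(D + diag(4) %*% matrix(1:5, 4, 5)), 0)
  expect_equal(shape_consistency_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(shape_consistency_loss(c(1, 2), c(2, 0)), 5)
})

test_that("coarse and detail aggregations sum their components", {
  zero <- list(landmark = 0, eye = 0, photometric = 0, identity = 0,
               shape_consistency = 0, regularization = 0)
  expect_equal(coarse_loss(zero), 0)
  one <- zero; one$photometric <- 0.37
  expect_equal(coarse_loss(one), 0.37)
  expect_error(coarse_loss(zero[-3]), "photometric")
  expect_equal(detail_loss(list(photometric_detail = 0.1, symmetry = 0.2,
                                regularization_detail = 0.3)), 0.6)  # mrf 0
  expect_equal(detail_loss(list(photometric_detail = 0.1, mrf = 1,
                                symmetry = 0, regularization_detail = 0)),
               1.1)
  expect_equal(coarse_loss(one, weights = list(photometric = 2)), 0.74)
})
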