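test_that("sop_project matches hand and brute-force results", {
  p <- rbind(c(1, 2, 3), c(-4, 5, -6))
  expect_equal(sop_project(p, sop_pose()), p[, 1:2])
  rot90 <- rotation_exp(c(0, 0, pi / 2))
  expect_equal(sop_project(rbind(c(1, 0, 0)), sop_pose(rot90, s = 2)),
               rbind(c(0, 2)), tolerance = 1e-12)
  set.seed(31)
  for (rep in 1:5) {
    P <- matrix(rnorm(30, sd = 40), ncol = 3)
    pose <- sop_pose(random_rotation(), rnorm(2, sd = 20), runif(1, 0.5, 5))
    expect_equal(sop_project(P, pose), oracle_sop(P, pose$R, pose$t, pose$s),
                 tolerance = 1e-12)
  }
})

test_that("pose constructor rejects invalid elements", {
  expect_error(sop_pose(diag(3) * 2), "rotation")
  expect_error(sop_pose(diag(c(1, -1, 1))), "rotation")  # reflection
  expect_error(sop_pose(s = -1), "positive")
  expect_error(sop_pose(t = c(1, NA)), "finite")
})

test_that("estimate_pose recovers exact poses and is shift-equivariant", {
  set.seed(17)
  P <- matrix(rnorm(3 * 12, sd = 50), ncol = 3)
  pose <- sop_pose(random_rotation(), c(10, -20), 2.5)
  x <- sop_project(P, pose)
  est <- estimate_pose(P, x)
  expect_lt(rotation_angle(est$R %*% t(pose$R)), 1e-6)
  expect_lt(abs(est$s - pose$s) / pose$s, 1e-8)
  expect_lt(max(abs(est$t - pose$t)), 1e-6)
  # translating the 2D observations shifts t by (dx, dy) / s only
  d <- c(35, -12)
  est2 <- estimate_pose(P, sweep(x, 2, d, "+"))
  expect_lt(rotation_angle(est2$R %*% t(est$R)), 1e-8)
  expect_equal(est2$s, est$s, tolerance = 1e-10)
  expect_equal(est2$t, est$t + d / est$s, tolerance = 1e-8)
})

test_that("estimate_pose rejects degenerate correspondence sets", {
  line <- cbind(1:6, 2 * (1:6), 3 * (1:6))
  expect_error(estimate_pose(line, cbind(1:6, 1:6)), "collinear")
  expect_error(estimate_pose(line[1:3, ], cbind(1:3, 1:3)), "at least 4")
  plane <- cbind(runif(8), runif(8), 0)
  expect_warning(estimate_pose(plane, plane[, 1:2]), "coplanar")
})

test_that("estimate_pose equals an independent nonlinear LS solution", {
  # general-purpose optimizer over a different parameterization (axis-angle
  # from identity), multi-start; costs must agree to 1e-8
  set.seed(99)
  for (rep in 1:20) {
    P <- matrix(rnorm(3 * 10, sd = 40), ncol = 3)
    pose <- sop_pose(random_rotation(), rnorm(2, sd = 10), runif(1, 1, 4))
    x <- sop_project(P, pose) + matrix(rnorm(20), ncol = 2)
    est <- estimate_pose(P, x)
    cost_est <- mean(rowSums((x - sop_project(P, est))^2))
    obj <- function(th) {
      s <- exp(th[6])
      proj <- s * sweep((P %*% t(rotation_exp(th[1:3])))[, 1:2],
                        2, th[4:5], "+")
      mean(rowSums((x - proj)^2))
    }
    starts <- list(c(0, 0, 0, 0, 0, 0),
                   c(0.3, -0.2, 0.1, colMeans(x) / 2, log(2)))
    cost_opt <- min(vapply(starts, function(s0)
      stats::optim(s0, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))$value, 0))
    expect_lt(cost_est, cost_opt + 1e-8)
  }
})

test_that("coefficients are recovered exactly at the true pose", {
  model <- make_truth_model(seed = 21, m_vertices = 200, k_modes = 8)
  pose <- sop_pose(rotation_exp(c(0.05, 0.1, -0.02)), c(120, 140), 3)
  # mean shape -> zero coefficients
  obs0 <- observe_landmarks(synthesize_shape(model, numeric(8)), model, pose)
  expect_lt(max(abs(estimate_coeffs_given_pose(model, obs0, pose,
                                               lambda = 0))), 1e-8)
  subj <- sample_subject(model, seed = 22)
  obs <- observe_landmarks(subj$mesh, model, pose)
  ahat <- estimate_coeffs_given_pose(model, obs, pose, lambda = 0)
  expect_lt(max(abs(ahat - subj$alpha)), 1e-6)
})

test_that("ridge limit shrinks coefficients monotonically to zero", {
  model <- make_truth_model(seed = 23, m_vertices = 200, k_modes = 6)
  pose <- sop_pose(s = 3, t = c(100, 100))
  obs <- observe_landmarks(sample_subject(model, seed = 24)$mesh, model, pose)
  norms <- vapply(c(0, 0.1, 10, 1000, 1e6), function(l)
    sqrt(sum(estimate_coeffs_given_pose(model, obs, pose, l)^2)), 0)
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[5], 1e-3)
})

test_that("fit_landmarks on mean-shape landmarks converges immediately", {
  model <- make_truth_model(seed = 25, m_vertices = 200, k_modes = 6)
  pose <- sop_pose(rotation_exp(c(0, 0.1, 0)), c(150, 150), 2.5)
  obs <- observe_landmarks(synthesize_shape(model, numeric(6)), model, pose)
  fit <- fit_landmarks(model, obs, fit_config(prior_weight = 1e-6))
  expect_true(fit$converged)
  expect_lte(fit$iterations, 2)
  expect_lt(max(abs(coef(fit))), 1e-4)
  expect_lt(rotation_angle(fit$pose$R %*% t(pose$R)), 1e-4)
})

test_that("fit_landmarks recovers a noiseless synthetic subject", {
  model <- make_truth_model(seed = 26, m_vertices = 250, k_modes = 10)
  subj <- sample_subject(model, seed = 27)
  pose <- sop_pose(rotation_exp(c(0.08, -0.1, 0.03)), c(160, 170), 3.2)
  obs <- observe_landmarks(subj$mesh, model, pose, noise_sd_px = 0)
  fit <- fit_landmarks(model, obs, fit_config(prior_weight = 1e-8))
  # per-landmark reprojection below 1e-4 px, reconstruction below 0.1 mm
  expect_lt(max(sqrt(rowSums(residuals(fit)^2))), 1e-4)
  recon <- predict(fit, "mesh")
  verr <- sqrt(rowSums((recon$vertices - subj$mesh$vertices)^2))
  expect_lt(mean(verr), 0.1)
  expect_true(all(diff(fit$cost_trace) <= 1e-10))
  # fitted/residual/print accessors are consistent
  expect_equal(fitted(fit) + residuals(fit), obs$points)
  expect_output(print(summary(fit)), "reprojection error")
})

test_that("reprojection cost is gauge-invariant under frame rotation", {
  # rotating the model frame by Q and compensating the pose leaves the
  # projections identical
  set.seed(41)
  P <- matrix(rnorm(30, sd = 30), ncol = 3)
  pose <- sop_pose(random_rotation(), c(5, 5), 2)
  Q <- random_rotation()
  expect_equal(sop_project(P, pose),
               sop_project(P %*% t(Q), sop_pose(pose$R %*% t(Q),
                                                pose$t, pose$s)),
               tolerance = 1e-9)
})

test_that("coefficient recovery RMSE is tiny across many noiseless subjects", {
  model <- make_truth_model(seed = 50, m_vertices = 200, k_modes = 10)
  errs <- vapply(1:50, function(i) {
    subj <- sample_subject(model, seed = 500 + i)
    set.seed(600 + i)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    pose <- sop_pose(rotation_exp(ax * runif(1, 0, 0.25)),
                     runif(2, 100, 200), runif(1, 2, 4))
    obs <- observe_landmarks(subj$mesh, model, pose, noise_sd_px = 0)
    fit <- fit_landmarks(model, obs, fit_config(prior_weight = 1e-8))
    sqrt(mean((coef(fit) - subj$alpha)^2))
  }, 0)
  expect_lt(max(errs), 1e-3)
})
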