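test_that("residualisation centres per unit/bin and z-scores residuals", {
  arr <- withr::with_seed(1, array(rpois(40 * 5 * 6, 4), dim = c(40, 5, 6),
                                   dimnames = list(NULL, NULL, paste0("u", 1:6))))
  res <- residualize(arr)
  expect_equal(dim(res), c(40, 30))
  expect_equal(colMeans(res), rep(0, 30), tolerance = 1e-12)
  # identical trials give all-zero residuals (dropped as zero-variance)
  flat <- array(rep(arr[1, , ], each = 3), dim = c(3, 5, 6),
                dimnames = dimnames(arr))
  expect_warning(res0 <- residualize(flat), "zero-variance")
  expect_equal(ncol(res0), 0)
  # planted shared trial gain shows up as positive residual correlation
  sim <- simulate_coupled_areas(n_trials = 80, shared_in = "omission", seed = 2)
  rx <- residualize(sim$x_omission)
  ry <- residualize(sim$y_omission)
  expect_gt(mean(cor(rowMeans(rx), rowMeans(ry))), 0.3)
})

test_that("closed-form ridge equals an independent iterative solver and OLS at 0", {
  set.seed(3)
  X <- matrix(rnorm(60 * 8), 60, 8)
  Y <- matrix(rnorm(60 * 3), 60, 3)
  lambda <- 2.5
  B <- ridge_solve(X, Y, lambda)
  # independent route: minimise the ridge loss per target by BFGS
  B_opt <- vapply(1:3, function(j) {
    stats::optim(rep(0, 8), function(b) {
      sum((Y[, j] - X %*% b)^2) + lambda * sum(b^2)
    }, gr = function(b) {
      -2 * drop(crossprod(X, Y[, j] - X %*% b)) + 2 * lambda * b
    }, method = "BFGS", control = list(maxit = 500, reltol = 1e-14))$par
  }, numeric(8))
  expect_lt(max(abs(B - B_opt)), 1e-6)
  # lambda = 0 on full-rank X equals ordinary least squares
  B0 <- ridge_solve(X, Y, 0)
  B_ls <- qr.coef(qr(X), Y)
  expect_lt(max(abs(B0 - B_ls)), 1e-8)
})

test_that("interaction strength is negative for omission-only shared latents", {
  sim <- simulate_coupled_areas(n_trials = 60, shared_in = "omission", seed = 4)
  out <- ridge_interaction_arrays(sim, seed = 5)
  expect_lt(out$difference, 0)
  expect_gt(out$r2_omission, 0.1)
  sim2 <- simulate_coupled_areas(n_trials = 60, shared_in = "stimulus", seed = 6)
  out2 <- ridge_interaction_arrays(sim2, seed = 7)
  expect_gt(out2$difference, 0)
})

test_that("ridge predictive performance is invariant to unit reordering", {
  sim <- simulate_coupled_areas(n_trials = 50, shared_in = "omission", seed = 8)
  out <- ridge_interaction_arrays(sim, seed = 9)
  perm <- withr::with_seed(10, sample(dim(sim$x_omission)[3]))
  sim_p <- sim
  sim_p$x_omission <- sim$x_omission[, , perm]
  sim_p$x_stimulus <- sim$x_stimulus[, , perm]
  out_p <- ridge_interaction_arrays(sim_p, seed = 9)
  expect_equal(out_p$r2_omission, out$r2_omission, tolerance = 1e-10)
  expect_equal(out_p$r2_stimulus, out$r2_stimulus, tolerance = 1e-10)
})

test_that("spike-level ridge interaction matches the condition carrying omissions", {
  # hippocampal step units share omission-locked fluctuations with nothing else;
  # here just exercise the spike-level path end to end on matched trials
  sess <- make_session(seed = 11, n_trials = 200)
  vis <- sess$units[sess$units$area == "VISp", ][1:12, ]
  hpc <- sess$units[sess$units$area == "CA1", ][1:10, ]
  out <- ridge_interaction(vis, hpc, sess$schedule, seed = 12)
  expect_true(is.finite(out$difference))
  expect_equal(out$n_trials, length(event_onsets(sess$schedule)))
  expect_lte(out$r2_stimulus, 1)
  expect_lte(out$r2_omission, 1)
})

test_that("canonical correlations obey their defining identities", {
  set.seed(13)
  X <- matrix(rnorm(200 * 6), 200, 6)
  # Y = X (up to renaming): all canonical correlations 1
  self <- cca_interaction(X, X, n_dims = 3)
  expect_equal(self$correlations, rep(1, 3), tolerance = 1e-6)
  # independent X, Y: correlations near the permutation-null level
  Y <- matrix(rnorm(200 * 6), 200, 6)
  indep <- cca_interaction(X, Y, n_dims = 3)
  null_level <- quantile(replicate(40, {
    cca_interaction(X[sample(200), ], Y, n_dims = 1)$correlations[1]
  }), 0.99)
  expect_lt(indep$correlations[1], null_level + 0.1)
  expect_true(all(diff(indep$correlations) <= 1e-9))
  # planted one-dimensional latent of strength rho
  rho <- 0.7
  lat <- rnorm(200)
  Xl <- sweep(matrix(rnorm(200 * 6), 200, 6), 1, lat * 1.2, "+")
  Yl <- sweep(matrix(rnorm(200 * 6), 200, 6), 1, lat * 1.2, "+")
  pl <- cca_interaction(Xl, Yl, n_dims = 2)
  # the canonical direction averages the 6 units, so private noise enters as 1/6
  shared_var <- 1.2^2 / (1.2^2 + 1 / 6)
  expect_equal(pl$correlations[1], shared_var, tolerance = 0.1)
  expect_lt(pl$correlations[2], null_level + 0.15)
  # agreement with the reference implementation when well-conditioned
  cc_ref <- stats::cancor(Xl, Yl)
  expect_equal(pl$correlations[1], cc_ref$cor[1], tolerance = 1e-6)
})
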