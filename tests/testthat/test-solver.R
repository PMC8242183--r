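test_that("objective matches a brute-force scalar-loop evaluation", {
  g <- voxel_grid(c(4, 4, 4), c(1, 1, 1))
  x <- random_volume(4, seed = 30)
  spec <- acquisition_spec("z", 2, g)
  ops <- forward_operators(list(spec))
  set.seed(31)
  y <- as_volume(array(rnorm(4 * 4 * 2), c(4, 4, 2)),
                 voxel_grid(c(4, 4, 2), c(1, 1, 2)))
  gs <- build_guidance(random_volume(4, seed = 32),
                       enumerate_shifts(c(-1, 1), c(0, 1), c(0, 1)))
  lambda <- 0.37
  obj <- objective_value(x, list(y), ops, gs, lambda)
  # independent evaluation: explicit residual loops
  ax <- apply_forward(x, rigid_identity(), spec)
  fid <- 0
  for (i in 1:4) for (j in 1:4) for (k in 1:2)
    fid <- fid + (ax$data[i, j, k] - y$data[i, j, k])^2
  reg <- 0
  for (m in seq_len(nrow(gs$shifts))) {
    s <- c(gs$shifts$alpha[m], gs$shifts$beta[m], gs$shifts$gamma[m])
    d <- brute_shift_difference(x$data, s) - gs$fields[[m]]$data
    reg <- reg + sum(abs(d))
  }
  expect_equal(obj$fidelity, fid, tolerance = 1e-10)
  expect_equal(obj$regularizer, reg, tolerance = 1e-10)
  expect_equal(obj$total, fid + lambda * reg, tolerance = 1e-10)
  # lambda = 0 collapses the total onto the fidelity
  obj0 <- objective_value(x, list(y), ops, gs, 0)
  expect_identical(obj0$total, obj0$fidelity)
})

test_that("objective is zero at an exact fit", {
  g <- voxel_grid(c(6, 6, 6), c(1, 1, 1))
  x <- random_volume(6, seed = 33)
  spec <- acquisition_spec("z", 1, g, n_slices = 6)
  fl <- identity_filter(g, "z")
  ops <- forward_operators(list(spec), filters = list(fl))
  gs <- build_guidance(x)  # guidance from x itself: g_s = D_s x exactly
  obj <- objective_value(x, list(apply_forward(x, rigid_identity(), spec, fl)),
                         ops, gs, 0.1)
  expect_lt(obj$total, 1e-18)
})

test_that("fidelity gradient matches central finite differences", {
  g <- voxel_grid(c(4, 4, 4), c(1, 1, 1))
  x <- random_volume(4, seed = 34)
  spec <- acquisition_spec("z", 2, g)
  ops <- forward_operators(list(spec))
  set.seed(35)
  y <- list(as_volume(array(rnorm(4 * 4 * 2), c(4, 4, 2)),
                      voxel_grid(c(4, 4, 2), c(1, 1, 2))))
  grad <- srrmri:::fidelity_gradient_arr(x$data, y, ops)
  fid_at <- function(arr)
    objective_value(as_volume(arr, g), y, ops, NULL, 0)$fidelity
  h <- 1e-5
  num <- array(0, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    ap <- x$data; am <- x$data
    ap[i, j, k] <- ap[i, j, k] + h
    am[i, j, k] <- am[i, j, k] - h
    num[i, j, k] <- (fid_at(ap) - fid_at(am)) / (2 * h)
  }
  expect_lt(max(abs(grad - num)) / max(abs(num)), 1e-4)
})

test_that("least squares with identity operators converges to the data", {
  g <- voxel_grid(c(12, 12, 12), c(1, 1, 1))
  spec <- acquisition_spec("z", 1, g, n_slices = 12)
  fl <- identity_filter(g, "z")
  y <- random_volume(12, seed = 36)
  res <- srr_reconstruct(list(y), list(spec),
                         list(rigid_identity()),
                         solver_config(lambda = 0, max_iters = 50,
                                       init = "zeros", tol = 1e-12),
                         filters = list(fl))
  rel <- sqrt(sum((res$volume$data - y$data)^2) / sum(y$data^2))
  expect_lt(rel, 1e-4)
})

test_that("backtracking keeps the objective non-increasing", {
  sim <- tiny_sim(n = 24, thickness = 4, noise_sd = 8, seed = 37)
  res <- srr_reconstruct(sim$scans, sim$specs, sim$transforms,
                         config = solver_config(lambda = 0.1,
                                                max_iters = 15))
  expect_true(all(diff(res$trace$total) <= 1e-9 * res$trace$total[1]))
  # trace bookkeeping: total = fidelity + lambda * regularizer
  expect_equal(res$trace$total,
               res$trace$fidelity + 0.1 * res$trace$regularizer,
               tolerance = 1e-10)
})

test_that("descent from the IAA start improves on the IAA objective", {
  sim <- tiny_sim(n = 24, thickness = 4, noise_sd = 0, seed = 38)
  res <- srr_reconstruct(sim$scans, sim$specs, sim$transforms,
                         config = solver_config(lambda = 0.1,
                                                max_iters = 15))
  expect_lt(res$trace$total[nrow(res$trace)], res$trace$total[1])
  # and the reconstruction moves towards the truth
  expect_gt(psnr(res$volume, sim$truth), psnr(res$iaa, sim$truth))
})

test_that("the TV mode runs the same solver with zero guidance", {
  sim <- tiny_sim(n = 24, thickness = 4, noise_sd = 8, seed = 39)
  res <- srr_reconstruct(sim$scans, sim$specs, sim$transforms,
                         config = solver_config(lambda = 0.1, mode = "tv",
                                                max_iters = 10))
  expect_true(all(diff(res$trace$total) <= 1e-9 * res$trace$total[1]))
  expect_equal(nrow(srrmri:::solver_shifts("tv")), 6)
})

test_that("lambda_sweep returns one scored row per weight", {
  sim <- tiny_sim(n = 24, thickness = 4, noise_sd = 8, seed = 40)
  sw <- lambda_sweep(sim$scans, sim$specs, sim$transforms, sim$truth,
                     lambdas = c(0, 0.1),
                     config = solver_config(max_iters = 5))
  expect_equal(sw$lambda, c(0, 0.1))
  expect_true(all(is.finite(sw$psnr_db)))
  expect_true(all(sw$ssim >= 0 & sw$ssim <= 1))
})

test_that("solver configuration validates its fields", {
  expect_error(solver_config(lambda = -1), "lambda")
  expect_error(solver_config(max_iters = 0), "max_iters")
})
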