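test_that("profile_sigma converts FWHM to Gaussian sigma", {
  expect_equal(round(profile_sigma(2), 4), 0.8493)
  expect_equal(profile_sigma(2 * sqrt(2 * log(2))), 1.0)
  expect_equal(profile_sigma(4), 2 * profile_sigma(2))
  expect_error(profile_sigma(0), "> 0")
})

test_that("the combined filter has unit DC gain and Gaussian attenuation", {
  g <- voxel_grid(c(24, 24, 24), c(0.5, 0.5, 0.5))
  spec <- acquisition_spec("z", 2, g)
  fl <- build_filter(spec)
  expect_identical(fl$transfer[1], 1)
  expect_equal(length(fl$keep), spec$n_slices)
  # band edge for contiguous 2 mm slices: f = 1/(2*thickness) = 0.25/mm
  i_edge <- which(abs(fl$freqs - 0.25) < 1e-12)
  expect_equal(fl$transfer[i_edge], exp(-pi^2 / (16 * log(2))),
               tolerance = 1e-10)
  expect_equal(fl$transfer[i_edge], 0.411, tolerance = 1e-3)
  # symmetry about DC
  expect_equal(fl$transfer[2:24], rev(fl$transfer[2:24]))
  expect_error(acquisition_spec("z", 2, g, n_slices = 40), "field of view")
  expect_error(acquisition_spec("z", 0.3, g), "in-plane")
})

test_that("forward operator preserves constants and attenuates in-band tones", {
  g <- voxel_grid(c(24, 24, 24), c(0.5, 0.5, 0.5))
  spec <- acquisition_spec("z", 2, g)
  fl <- build_filter(spec)
  c5 <- as_volume(array(5, c(24, 24, 24)), g)
  y <- apply_forward(c5, rigid_identity(), spec, fl)
  expect_equal(dim(y$data), c(24, 24, 6))
  expect_lt(max(abs(y$data - 5)), 1e-8)
  zc <- (0:23) * 0.5
  f1 <- 2 / (24 * 0.5)  # 2 cycles over the FoV, inside the keep band
  tone <- as_volume(array(rep(cos(2 * pi * f1 * zc), each = 24 * 24),
                          c(24, 24, 24)), g)
  att <- exp(-2 * pi^2 * profile_sigma(2)^2 * f1^2)
  ylr <- apply_forward(tone, rigid_identity(), spec, fl)
  zl <- (0:5) * 2
  expect_lt(max(abs(ylr$data[5, 9, ] - att * cos(2 * pi * f1 * zl))), 1e-6)
  # a tone beyond the keep band is annihilated
  f2 <- 5 / (24 * 0.5)
  tone2 <- as_volume(array(rep(cos(2 * pi * f2 * zc), each = 24 * 24),
                           c(24, 24, 24)), g)
  expect_lt(max(abs(apply_forward(tone2, rigid_identity(), spec, fl)$data)),
            1e-8)
})

test_that("forward operator is linear and non-expansive", {
  g <- voxel_grid(c(16, 16, 16), c(1, 1, 1))
  spec <- acquisition_spec("y", 4, g)
  fl <- build_filter(spec)
  a <- random_volume(16, seed = 21)
  b <- random_volume(16, seed = 22)
  ya <- apply_forward(a, rigid_identity(), spec, fl)
  yb <- apply_forward(b, rigid_identity(), spec, fl)
  comb <- as_volume(2 * a$data - 3 * b$data, g)
  ycomb <- apply_forward(comb, rigid_identity(), spec, fl)
  expect_lt(max(abs(ycomb$data - (2 * ya$data - 3 * yb$data))), 1e-8)
  # contraction in the volume-weighted norms
  expect_lte(vol_inner(ya, ya), vol_inner(a, a) * (1 + 1e-12))
})

test_that("adjoint satisfies the inner-product identity at identity pose", {
  g <- voxel_grid(c(24, 24, 24), c(0.5, 0.5, 0.5))
  for (axis in c("x", "y", "z")) {
    spec <- acquisition_spec(axis, 2, g)
    fl <- build_filter(spec)
    lr <- apply_forward(as_volume(array(0, g$shape), g),
                        rigid_identity(), spec, fl)$grid
    for (i in 1:4) {
      x <- random_volume(24, spacing = 0.5, seed = 100 + i)
      set.seed(200 + i)
      y <- as_volume(array(rnorm(prod(lr$shape)), lr$shape), lr)
      ax <- apply_forward(x, rigid_identity(), spec, fl)
      aty <- adjoint_forward(y, rigid_identity(), spec, fl)
      lhs <- vol_inner(ax, y)
      rhs <- vol_inner(x, aty)
      denom <- sqrt(sum(x$data^2)) * sqrt(sum(y$data^2))
      expect_lt(abs(lhs - rhs) / denom, 1e-6)
    }
  }
})

test_that("adjoint preserves constants and maps zero to zero", {
  g <- voxel_grid(c(24, 24, 24), c(0.5, 0.5, 0.5))
  spec <- acquisition_spec("z", 2, g)
  fl <- build_filter(spec)
  lrg <- voxel_grid(c(24, 24, 6), c(0.5, 0.5, 2))
  c7 <- as_volume(array(7, c(24, 24, 6)), lrg)
  expect_lt(max(abs(adjoint_forward(c7, rigid_identity(), spec, fl)$data - 7)),
            1e-8)
  z <- as_volume(array(0, c(24, 24, 6)), lrg)
  expect_true(all(adjoint_forward(z, rigid_identity(), spec, fl)$data == 0))
})

test_that("an all-pass filter makes forward and adjoint the identity", {
  g <- voxel_grid(c(12, 12, 12), c(1, 1, 1))
  spec <- acquisition_spec("z", 1, g, n_slices = 12)
  fl <- identity_filter(g, "z")
  v <- random_volume(12, seed = 31)
  expect_lt(max(abs(apply_forward(v, rigid_identity(), spec, fl)$data -
                      v$data)), 1e-10)
  expect_lt(max(abs(adjoint_forward(v, rigid_identity(), spec, fl)$data -
                      v$data)), 1e-10)
})

test_that("additive noise is seeded, unbiased in sd, and optional", {
  g <- voxel_grid(c(47, 47, 47), c(1, 1, 1))
  y <- as_volume(array(0, g$shape), g)
  expect_identical(add_noise(y, noise_model(0, 1))$data, y$data)
  n1 <- add_noise(y, noise_model(5, 9))
  n2 <- add_noise(y, noise_model(5, 9))
  expect_identical(n1$data, n2$data)
  expect_equal(sd(n1$data), 5, tolerance = 0.02)
})

test_that("simulating three orthogonal stacks yields the expected slice counts", {
  g <- voxel_grid(c(96, 96, 96), c(0.5, 0.5, 0.5))
  ph <- make_phantom(phantom_spec(grid = g, geometry_seed = 1))
  specs <- orthogonal_specs(g, 2)
  scans <- simulate_acquisitions(ph$image, specs,
                                 noise = noise_model(0, 1))
  expect_length(scans, 3)
  expect_equal(dim(scans[[1]]$data), c(96, 96, 24))
  expect_equal(dim(scans[[2]]$data), c(96, 24, 96))
  expect_equal(dim(scans[[3]]$data), c(24, 96, 96))
  # single-stack configuration
  one <- simulate_acquisitions(ph$image, specs[1],
                               noise = noise_model(0, 1))
  expect_length(one, 1)
  expect_error(simulate_acquisitions(ph$image, specs, specs[1:2]),
               "length")
})
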