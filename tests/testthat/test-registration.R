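test_that("rigid transform algebra: inverse and composition", {
  tr <- rigid_transform(c(0.05, -0.03, 0.08), c(2, -1, 3), c(10, 12, 8))
  inv <- invert_transform(tr)
  id <- compose_transforms(inv, tr)
  expect_lt(max(abs(id$rotation)), 1e-10)
  expect_lt(max(abs(id$translation)), 1e-10)
  id2 <- compose_transforms(tr, inv)
  expect_lt(max(abs(id2$rotation)), 1e-10)
  expect_lt(max(abs(id2$translation)), 1e-10)
  # composition acts like sequential application on points
  w <- c(3, -2, 7)
  apply_t <- function(t, w)
    as.numeric(rotation_matrix(t$rotation) %*% (w - t$center)) +
      t$center + t$translation
  t2 <- rigid_transform(c(-0.02, 0.04, 0.01), c(0.5, 1, -2), c(10, 12, 8))
  expect_equal(apply_t(compose_transforms(t2, tr), w),
               apply_t(t2, apply_t(tr, w)), tolerance = 1e-12)
})

test_that("transform serialization round-trips", {
  tr <- rigid_transform(c(0.05, -0.03, 0.08), c(2, -1, 3), c(10, 12, 8))
  back <- transform_from_list(transform_to_list(tr))
  expect_equal(back$rotation, tr$rotation)
  expect_equal(back$translation, tr$translation)
  expect_equal(back$center, tr$center)
})

test_that("self mutual information equals the marginal entropy", {
  v <- random_volume(20, seed = 3)
  mi <- mutual_information(v, v, bins = 32)
  # independent entropy computation with the same clipping and binning
  x <- as.numeric(v$data)
  q <- quantile(x, c(0.01, 0.99), names = FALSE)
  b <- pmin(pmax(floor((x - q[1]) / (q[2] - q[1]) * 32), 0), 31)
  p <- tabulate(b + 1L, 32)
  p <- p[p > 0] / length(b)
  expect_equal(mi, -sum(p * log(p)), tolerance = 1e-10)
})

test_that("mutual information of independent noise is near zero", {
  set.seed(8)
  g <- voxel_grid(c(48, 48, 48), c(1, 1, 1))
  a <- as_volume(array(runif(48^3), g$shape), g)
  b <- as_volume(array(runif(48^3), g$shape), g)
  expect_lt(mutual_information(a, b, bins = 32), 0.05)
})

test_that("mutual information is invariant under affine intensity remapping", {
  v <- random_volume(16, seed = 5)
  w <- random_volume(16, seed = 6)
  remapped <- as_volume(3 * w$data + 17, w$grid)
  expect_equal(mutual_information(v, w), mutual_information(v, remapped),
               tolerance = 1e-12)
  expect_error(mutual_information(v, w, bins = 4), "bins")
})

test_that("registering a volume to itself stays at identity", {
  ph <- small_phantom(n = 32, seed = 9)
  est <- register_rigid(ph$image, ph$image)
  expect_lt(max(abs(est$rotation)) * 180 / pi, 0.1)
  expect_lt(max(abs(est$translation)), 0.1)
  expect_true(attr(est, "improved"))
})

test_that("known rigid motion is recovered within 0.5 mm and 0.5 deg", {
  ph <- small_phantom(n = 48, seed = 3)
  fixed <- ph$image
  center <- fixed$grid$origin +
    (fixed$grid$shape - 1) * fixed$grid$spacing / 2
  true_t <- rigid_transform(c(2, -1, 1) * pi / 180, c(2, -1, 3), center)
  moving <- resample_to_grid(fixed, fixed$grid, true_t, order = 3)
  est <- register_rigid(moving, fixed)
  # moving(w) = fixed(T(w)), so the estimate should recover T^{-1}
  expected <- invert_transform(true_t)
  expect_lt(max(abs(est$rotation - expected$rotation)) * 180 / pi, 0.5)
  expect_lt(max(abs(est$translation - expected$translation)), 0.5)
  # and never scores below its initialization
  mi_est <- mutual_information(
    resample_to_grid(moving, fixed$grid, est, order = 1, fill = NA), fixed)
  mi_init <- mutual_information(
    resample_to_grid(moving, fixed$grid, rigid_identity(), order = 1,
                     fill = NA), fixed)
  expect_gte(mi_est, mi_init)
})

test_that("forward and backward registrations compose to near identity", {
  ph <- small_phantom(n = 48, seed = 13)
  a <- ph$image
  center <- a$grid$origin + (a$grid$shape - 1) * a$grid$spacing / 2
  tr <- rigid_transform(c(1.5, 0.5, -1) * pi / 180, c(1.5, -2, 1), center)
  b <- resample_to_grid(a, a$grid, tr, order = 3)
  t_ab <- register_rigid(a, b)
  t_ba <- register_rigid(b, a)
  comp <- compose_transforms(t_ab, t_ba)
  expect_lt(max(abs(comp$rotation)) * 180 / pi, 0.5)
  expect_lt(max(abs(comp$translation)), 0.5)
})
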