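# synthetic gmm_fit with known parameters, for the closed-form checks
fixed_fit <- function(means, sds = c(10, 10, 10),
                      weights = c(0.3, 0.4, 0.3), contrast = "t2") {
  structure(list(means = means, sds = sds, weights = weights,
                 assignment = if (contrast == "t2") c("GM", "WM", "CSF")
                              else c("CSF", "GM", "WM")),
            class = "gmm_fit")
}

test_that("EM recovers the parameters of a well-separated mixture", {
  set.seed(50)
  x <- c(rnorm(30000, 100, 10), rnorm(40000, 200, 10),
         rnorm(30000, 300, 10))
  fit <- fit_gmm3(x)
  expect_equal(fit$means, c(100, 200, 300), tolerance = 2 / 100)
  expect_lt(max(abs(fit$means - c(100, 200, 300))), 2)
  expect_lt(max(abs(fit$weights - c(0.3, 0.4, 0.3))), 0.02)
  expect_gte(fit$log_likelihood, fit$log_likelihood_init)
  expect_true(fit$converged)
})

test_that("EM separates near-delta clusters with exact weights", {
  set.seed(51)
  x <- c(rnorm(2500, 10, 0.1), rnorm(5000, 20, 0.1), rnorm(2500, 30, 0.1))
  fit <- fit_gmm3(x)
  expect_lt(max(abs(fit$weights - c(0.25, 0.5, 0.25))), 0.01)
  expect_error(fit_gmm3(rnorm(100)), "300")
})

test_that("EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(52)
  x <- c(rnorm(10000, 100, 12), rnorm(15000, 190, 15),
         rnorm(12000, 290, 18))
  fit <- fit_gmm3(x)
  mc <- mclust::Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(fit$means, sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("pure-tissue intervals have the half-FWHM width and coverage", {
  fit <- fixed_fit(c(0, 200, 300), sds = c(1, 10, 10))
  iv <- pure_tissue_interval(fit, 1)
  expect_equal(iv, c(-1.17741, 1.17741), tolerance = 1e-4)
  fit2 <- fixed_fit(c(0, 200, 300), sds = c(3, 10, 10))
  expect_equal(diff(pure_tissue_interval(fit2, 1)), 3 * diff(iv),
               tolerance = 1e-12)
  # coverage of a component by its own interval: erf(sqrt(log(2)))
  coverage <- 2 * pnorm(sqrt(2 * log(2))) - 1
  set.seed(53)
  draws <- rnorm(1e5, 200, 10)
  iv2 <- pure_tissue_interval(fit, 2)
  expect_equal(mean(draws >= iv2[1] & draws <= iv2[2]), coverage,
               tolerance = 0.01 / coverage)
  expect_equal(coverage, 0.761, tolerance = 1e-3)
})

test_that("PVE on pure well-separated classes sits at the analytic floor", {
  set.seed(54)
  n <- 125000
  lab <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  means <- c(100, 200, 300)[lab]
  x <- rnorm(n, means, 10)
  v <- as_volume(array(x, c(50, 50, 50)), voxel_grid(c(50, 50, 50), c(1, 1, 1)))
  region <- region_mask(v$grid, array(TRUE, c(50, 50, 50)))
  fit <- fit_gmm3(x)
  pve <- estimate_pve(v, region, fit)
  floor_pct <- 100 * (1 - (2 * pnorm(sqrt(2 * log(2))) - 1))
  expect_equal(pve, floor_pct, tolerance = 1 / floor_pct)
  # injecting mixed-intensity voxels raises the estimate monotonically
  pves <- vapply(c(0.05, 0.15, 0.3), function(q) {
    x2 <- x
    idx <- seq_len(round(q * n))
    x2[idx] <- 150  # midway between two pure classes
    v2 <- as_volume(array(x2, c(50, 50, 50)), v$grid)
    estimate_pve(v2, region, fit)
  }, numeric(1))
  expect_true(all(diff(c(pve, pves)) > 0))
  expect_true(all(pves >= 0 & pves <= 100))
})

test_that("background noise estimation is unbiased and scales", {
  g <- voxel_grid(c(22, 22, 22), c(1, 1, 1))
  const <- as_volume(array(4, g$shape), g)
  bg <- region_mask(g, array(TRUE, g$shape))
  expect_equal(estimate_noise_sd(const, bg), 0)
  set.seed(55)
  noisy <- as_volume(array(rnorm(22^3, 0, 10), g$shape), g)
  expect_equal(estimate_noise_sd(noisy, bg), 10, tolerance = 0.03)
  scaled <- as_volume(noisy$data * -3, g)
  expect_equal(estimate_noise_sd(scaled, bg),
               3 * estimate_noise_sd(noisy, bg), tolerance = 1e-12)
})

test_that("SNR reproduces the hand-worked decibel arithmetic", {
  fit <- fixed_fit(c(100, 200, 300))
  # equal component sds make peak and mixing weights proportional
  expect_equal(snr_db(fit, 10, "mixing"), 10 * log10(200 / 10),
               tolerance = 1e-12)
  expect_equal(snr_db(fit, 10, "peak"), 10 * log10(200 / 10),
               tolerance = 1e-12)
  same <- fixed_fit(c(150, 150.0001, 150.0002))
  expect_equal(snr_db(same, 10, "mixing"), 10 * log10(15), tolerance = 1e-4)
  expect_equal(snr_db(fit, 5, "mixing") - snr_db(fit, 10, "mixing"),
               10 * log10(2), tolerance = 1e-12)
  expect_error(snr_db(fit, 0), "> 0")
})

test_that("CNR reproduces the pairwise decibel arithmetic", {
  fit <- fixed_fit(c(100, 200, 300))  # GM 100, WM 200, CSF 300
  cnr <- cnr_db(fit, 10)
  expect_equal(unname(cnr["cnr_gm_wm"]), 10)    # |100-200|/10 = 10 -> 10 dB
  expect_equal(unname(cnr["cnr_csf_gm"]), 10 * log10(20))
  expect_equal(unname(cnr["cnr_csf_wm"]), 10)
  tied <- fixed_fit(c(100, 100.0, 300))
  expect_warning(ct <- cnr_db(tied, 10), "undefined")
  expect_true(is.na(ct["cnr_gm_wm"]))
  # |difference| = sigma gives 0 dB
  fit0 <- fixed_fit(c(100, 110, 300))
  expect_equal(unname(cnr_db(fit0, 10)["cnr_gm_wm"]), 0)
})

test_that("PSNR and SSIM behave as image-quality scores", {
  v <- small_phantom(n = 24, seed = 60)$image
  expect_equal(ssim(v, v), 1)
  expect_equal(psnr(v, v), Inf)
  shifted <- as_volume(v$data + 30, v$grid)
  expect_equal(psnr(shifted, v), 20 * log10(max(v$data) / 30),
               tolerance = 1e-12)
  set.seed(61)
  scores <- vapply(c(1, 5, 10), function(s)
    ssim(as_volume(v$data + rnorm(length(v$data), sd = s), v$grid), v),
    numeric(1))
  expect_true(all(diff(scores) < 0))
  other <- random_volume(12)
  expect_error(ssim(other, v), "grid")
})

test_that("the full quality report runs end to end on a noisy phantom", {
  ph <- small_phantom(n = 32, seed = 62, noise_sd = 8)
  rep <- quality_report(ph$image, reference = small_phantom(
    n = 32, seed = 62)$image)
  expect_s3_class(rep, "quality_report")
  expect_true(rep$pve_percent >= 0 && rep$pve_percent <= 100)
  expect_true(is.finite(rep$snr_db))
  expect_true(is.finite(rep$cnr_gm_wm))
  expect_gt(rep$noise_sd, 0)
  expect_true(is.finite(rep$psnr_db))
  expect_true(rep$ssim > 0 && rep$ssim <= 1)
})
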