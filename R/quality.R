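#' Fit a three-component Gaussian mixture to voxel intensities
#'
#' Expectation-maximization fit of a 3-component univariate Gaussian
#' mixture, the intensity model under which each pure tissue class (CSF,
#' GM, WM) contributes one Gaussian mode. Initialization is deterministic:
#' component means at the 25th/50th/75th intensity percentiles, equal
#' weights, and a common sd of half the inter-quartile spread. EM stops
#' when the log-likelihood improves by less than `tol`.
#'
#' @param intensities numeric vector of voxel values (>= 300 samples).
#' @param seed integer seed (kept for interface stability; the fit itself
#'   is deterministic).
#' @param contrast `"t2"` or `"t1"`; fixes the component-to-tissue
#'   assignment by ascending mean (T2-like: GM, WM, CSF; T1-like: CSF,
#'   GM, WM).
#' @param max_iter maximum EM iterations.
#' @param tol log-likelihood convergence threshold.
#' @return An object of class `gmm_fit`: `means`, `sds`, `weights` (each
#'   length 3, sorted by ascending mean), `assignment` (tissue label per
#'   component), `log_likelihood`, `n_iter`, `converged`.
#' @export
fit_gmm3 <- function(intensities, seed = 1L, contrast = c("t2", "t1"),
                     max_iter = 500L, tol = 1e-6) {
  contrast <- match.arg(contrast)
  x <- as.numeric(intensities)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 300) stop("fit_gmm3: need at least 300 samples, got ", n)
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  mu <- q
  sg <- rep(max((q[3] - q[1]) / 2, 1e-3 * max(sd(x), 1e-12)), 3)
  w <- rep(1 / 3, 3)
  loglik_of <- function(mu, sg, w) {
    dens <- vapply(1:3, function(k) w[k] * dnorm(x, mu[k], sg[k]),
                   numeric(n))
    sum(log(pmax(rowSums(dens), 1e-300)))
  }
  ll_init <- loglik_of(mu, sg, w)
  ll_old <- ll_init
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    dens <- vapply(1:3, function(k) w[k] * dnorm(x, mu[k], sg[k]),
                   numeric(n))
    tot <- pmax(rowSums(dens), 1e-300)
    resp <- dens / tot
    nk <- colSums(resp)
    if (any(nk < 1e-8))
      stop("fit_gmm3: EM degenerate (empty component); ",
           "use fewer components or more data")
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sg <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
    if (any(sg < 1e-10 * max(abs(mu), 1)))
      stop("fit_gmm3: EM degenerate (component sd collapsed to 0); ",
           "use fewer components or more data")
    ll <- sum(log(tot))
    # log-likelihood recomputed after the M step for the stopping rule
    ll_new <- loglik_of(mu, sg, w)
    if (abs(ll_new - ll_old) < tol) { converged <- TRUE; ll_old <- ll_new; break }
    ll_old <- ll_new
  }
  ord <- order(mu)
  assignment <- if (contrast == "t2") c("GM", "WM", "CSF")
                else c("CSF", "GM", "WM")
  structure(list(means = mu[ord], sds = sg[ord], weights = w[ord],
                 assignment = assignment, log_likelihood = ll_old,
                 log_likelihood_init = ll_init,
                 n_iter = it, converged = converged, contrast = contrast),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("<gmm_fit>\n")
  for (k in 1:3)
    cat(sprintf("  %-3s mean %.3f sd %.3f weight %.3f\n",
                x$assignment[k], x$means[k], x$sds[k], x$weights[k]))
  cat(sprintf("  logLik %.4f after %d iterations\n",
              x$log_likelihood, x$n_iter))
  invisible(x)
}

#' Pure-tissue intensity interval of a mixture component
#'
#' A voxel is considered pure tissue for component k when its intensity
#' lies within `mu_k +/- delta_k`, with `delta_k` half the FWHM of the
#' component Gaussian, i.e. `delta = sigma * sqrt(2 * log(2))`. For a draw
#' from the component itself the probability of falling inside is
#' `erf(sqrt(log(2))) ~ 0.761`, independent of mu and sigma.
#'
#' @param fit a [fit_gmm3()] result.
#' @param component component index 1-3 (ascending mean).
#' @return Numeric `c(low, high)`.
#' @export
pure_tissue_interval <- function(fit, component) {
  stopifnot(inherits(fit, "gmm_fit"), component %in% 1:3)
  mu <- fit$means[component]
  delta <- fit$sds[component] * sqrt(2 * log(2))
  c(mu - delta, mu + delta)
}

#' Partial-volume-effect estimate
#'
#' The fraction (in percent) of analysis-region voxels whose intensity
#' falls outside every component's pure-tissue interval. Voxels inside
#' some interval are attributed to a single tissue; the remainder are
#' taken to mix signal from more than one tissue. Note the estimator has
#' a floor even on perfectly pure classes: a pure Gaussian component only
#' places `erf(sqrt(log(2))) ~ 76.1%` of its own voxels inside its FWHM
#' interval, so well-separated pure classes still measure ~23.9%. The
#' measure is therefore comparative (between reconstructions of the same
#' scene), not an absolute mixed-voxel count.
#'
#' @param v a `volume`.
#' @param region a [region_mask()] selecting the analysis region.
#' @param fit a [fit_gmm3()] result for the region's intensities.
#' @return Percentage in `[0, 100]`.
#' @export
estimate_pve <- function(v, region, fit) {
  stopifnot(inherits(v, "volume"), inherits(region, "region_mask"),
            inherits(fit, "gmm_fit"))
  sel <- region$selected
  if (!any(sel)) stop("estimate_pve: empty analysis region")
  x <- v$data[sel]
  inside <- rep(FALSE, length(x))
  for (k in 1:3) {
    iv <- pure_tissue_interval(fit, k)
    inside <- inside | (x >= iv[1] & x <= iv[2])
  }
  100 * (length(x) - sum(inside)) / length(x)
}

#' Noise standard deviation from a background region
#'
#' @param v a `volume`.
#' @param background a [region_mask()] over signal-free background.
#' @return Sample standard deviation of the background intensities.
#' @export
estimate_noise_sd <- function(v, background) {
  stopifnot(inherits(v, "volume"), inherits(background, "region_mask"))
  sel <- background$selected
  if (!any(sel)) stop("estimate_noise_sd: empty background region")
  sd(v$data[sel])
}

#' Signal-to-noise ratio in dB from a mixture fit
#'
#' `SNR = 10 log10( sum(w_k s_k) / (sigma * sum(w_k)) )` with `s_k` the
#' component means and `sigma` the background noise sd. With
#' `weight_mode = "peak"` (default) `w_k` is the peak height of the k-th
#' weighted component density, `pi_k / (sigma_k sqrt(2 pi))`; with
#' `"mixing"` the mixing proportions `pi_k` are used directly (the voxel
#' fraction per tissue).
#'
#' @param fit a [fit_gmm3()] result.
#' @param noise_sd background noise sd (> 0).
#' @param weight_mode `"peak"` or `"mixing"`.
#' @return SNR in dB.
#' @export
snr_db <- function(fit, noise_sd, weight_mode = c("peak", "mixing")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(inherits(fit, "gmm_fit"))
  if (noise_sd <= 0) stop("snr_db: noise_sd must be > 0")
  w <- if (weight_mode == "peak")
    fit$weights / (fit$sds * sqrt(2 * pi))
  else fit$weights
  10 * log10(sum(w * fit$means) / (noise_sd * sum(w)))
}

#' Contrast-to-noise ratios in dB between tissue pairs
#'
#' `CNR = 10 log10( |s_i - s_j| / sigma )` for the three tissue pairs
#' CSF-GM, CSF-WM and GM-WM.
#'
#' @param fit a [fit_gmm3()] result.
#' @param noise_sd background noise sd (> 0).
#' @return Named numeric: `cnr_csf_gm`, `cnr_csf_wm`, `cnr_gm_wm` (dB;
#'   `NA` with a warning for a pair with identical means).
#' @export
cnr_db <- function(fit, noise_sd) {
  stopifnot(inherits(fit, "gmm_fit"))
  if (noise_sd <= 0) stop("cnr_db: noise_sd must be > 0")
  m <- fit$means
  names(m) <- fit$assignment
  pairs <- list(cnr_csf_gm = c("CSF", "GM"), cnr_csf_wm = c("CSF", "WM"),
                cnr_gm_wm = c("GM", "WM"))
  vapply(pairs, function(p) {
    d <- abs(m[p[1]] - m[p[2]])
    if (d == 0) {
      warning("cnr_db: identical means for pair ", paste(p, collapse = "-"),
              "; CNR undefined")
      return(NA_real_)
    }
    10 * log10(d / noise_sd)
  }, numeric(1))
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10( peak^2 / MSE )` with `peak` the maximum of the
#' reference volume.
#'
#' @param x a `volume` to score.
#' @param reference the ground-truth `volume` on the same grid.
#' @return PSNR in dB (`Inf` for identical volumes).
#' @export
psnr <- function(x, reference) {
  stopifnot(inherits(x, "volume"), inherits(reference, "volume"))
  if (!all(x$grid$shape == reference$grid$shape))
    stop("psnr: volumes must share a grid")
  mse <- mean((x$data - reference$data)^2)
  peak <- max(reference$data)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

# separable Gaussian smoothing along every axis (circular boundary)
gaussian_window_filter <- function(a, win = 11, sigma = 1.5) {
  half <- (win - 1) / 2
  k <- dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  d <- dim(a)
  for (axis in 1:3) {
    perm <- c(axis, setdiff(1:3, axis))
    m <- aperm(a, perm)
    dm <- dim(m)
    dim(m) <- c(dm[1], dm[2] * dm[3])
    m <- apply_kernel_circular(m, k)
    dim(m) <- dm
    a <- aperm(m, order(perm))
  }
  a
}

# column-wise circular convolution with a short symmetric kernel
apply_kernel_circular <- function(m, k) {
  n <- nrow(m)
  half <- (length(k) - 1) / 2
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    off <- j - 1 - half
    rows <- ((seq_len(n) - 1 + off) %% n) + 1
    out <- out + k[j] * m[rows, , drop = FALSE]
  }
  out
}

#' Structural similarity index
#'
#' Mean SSIM over the volume, computed with a separable Gaussian window
#' (11 voxels, sd 1.5) and the standard stabilizers
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` where `L` is the reference
#' dynamic range. Window statistics use a circular boundary.
#'
#' @param x a `volume` to score.
#' @param reference the ground-truth `volume` on the same grid.
#' @return SSIM in `[0, 1]` for non-negative-correlation images; exactly 1
#'   when `x` equals `reference`.
#' @export
ssim <- function(x, reference) {
  stopifnot(inherits(x, "volume"), inherits(reference, "volume"))
  if (!all(x$grid$shape == reference$grid$shape))
    stop("ssim: volumes must share a grid")
  a <- x$data; b <- reference$data
  L <- diff(range(b))
  if (L == 0) L <- 1
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  mu_a <- gaussian_window_filter(a)
  mu_b <- gaussian_window_filter(b)
  var_a <- gaussian_window_filter(a * a) - mu_a^2
  var_b <- gaussian_window_filter(b * b) - mu_b^2
  cov_ab <- gaussian_window_filter(a * b) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2)
  mean(num / den)
}

# Otsu threshold on 256 bins
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  nb <- 256L
  h <- tabulate(pmin(pmax(floor((x - rng[1]) / diff(rng) * nb), 0),
                     nb - 1) + 1L, nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nb))
  mu_t <- mu[nb]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  t_bin <- which.max(sigma_b)
  rng[1] + t_bin / nb * diff(rng)
}

# erode a logical array by one voxel (6-connectivity)
erode1 <- function(m) {
  out <- m
  n <- dim(m)
  for (axis in 1:3) {
    idx <- lapply(n, seq_len)
    i1 <- idx; i1[[axis]] <- c(1, seq_len(n[axis] - 1))
    i2 <- idx; i2[[axis]] <- c(seq_len(n[axis] - 1) + 1, n[axis])
    out <- out & m[i1[[1]], i1[[2]], i1[[3]]] & m[i2[[1]], i2[[2]], i2[[3]]]
  }
  out
}

#' Default analysis and background regions
#'
#' Analysis region: voxels above the Otsu threshold of the volume, eroded
#' by one voxel (drops the object rim, where air mixes in). Background
#' region: eight corner cubes of 10% linear size, which are signal-free
#' for any head-in-field acquisition.
#'
#' @param v a `volume`.
#' @return `default_analysis_region` / `default_background_region`: a
#'   [region_mask()].
#' @export
default_analysis_region <- function(v) {
  stopifnot(inherits(v, "volume"))
  thr <- otsu_threshold(as.numeric(v$data))
  region_mask(v$grid, erode1(v$data > thr))
}

#' @rdname default_analysis_region
#' @export
default_background_region <- function(v) {
  stopifnot(inherits(v, "volume"))
  n <- v$grid$shape
  w <- pmax(2L, as.integer(floor(n * 0.1)))
  sel <- array(FALSE, n)
  corners <- expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1))
  for (i in seq_len(nrow(corners))) {
    ix <- if (corners$x[i] == 0) 1:w[1] else (n[1] - w[1] + 1):n[1]
    iy <- if (corners$y[i] == 0) 1:w[2] else (n[2] - w[2] + 1):n[2]
    iz <- if (corners$z[i] == 0) 1:w[3] else (n[3] - w[3] + 1):n[3]
    sel[ix, iy, iz] <- TRUE
  }
  region_mask(v$grid, sel)
}

#' Full quality report for a reconstruction
#'
#' Runs the whole assessment chain: background-noise estimation, 3-class
#' mixture fit over the analysis region, partial-volume estimate, SNR and
#' the three pairwise CNRs, plus PSNR/SSIM when a ground-truth reference
#' is available (simulation studies).
#'
#' @param v a `volume` to assess.
#' @param reference optional ground-truth `volume`.
#' @param region analysis [region_mask()] (default [default_analysis_region()]).
#' @param background background [region_mask()]
#'   (default [default_background_region()]).
#' @param contrast `"t2"` or `"t1"`.
#' @param weight_mode SNR weighting, `"peak"` or `"mixing"`.
#' @param seed passed to [fit_gmm3()].
#' @return A list of class `quality_report` with fields `pve_percent`,
#'   `snr_db`, `cnr_csf_gm`, `cnr_csf_wm`, `cnr_gm_wm`, `noise_sd`,
#'   `psnr_db`, `ssim`, and the underlying `gmm` fit.
#' @export
quality_report <- function(v, reference = NULL, region = NULL,
                           background = NULL, contrast = c("t2", "t1"),
                           weight_mode = c("peak", "mixing"), seed = 1L) {
  contrast <- match.arg(contrast)
  weight_mode <- match.arg(weight_mode)
  if (is.null(region)) region <- default_analysis_region(v)
  if (is.null(background)) background <- default_background_region(v)
  noise <- estimate_noise_sd(v, background)
  fit <- fit_gmm3(v$data[region$selected], seed = seed, contrast = contrast)
  cnr <- suppressWarnings(cnr_db(fit, max(noise, 1e-12)))
  rep <- list(pve_percent = estimate_pve(v, region, fit),
              snr_db = if (noise > 0) snr_db(fit, noise, weight_mode)
                       else NA_real_,
              cnr_csf_gm = unname(cnr["cnr_csf_gm"]),
              cnr_csf_wm = unname(cnr["cnr_csf_wm"]),
              cnr_gm_wm = unname(cnr["cnr_gm_wm"]),
              noise_sd = noise,
              psnr_db = if (!is.null(reference)) psnr(v, reference)
                        else NA_real_,
              ssim = if (!is.null(reference)) ssim(v, reference)
                     else NA_real_,
              gmm = fit)
  class(rep) <- "quality_report"
  rep
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  cat(sprintf("  PVE %.2f%%  noise sd %.4g\n", x$pve_percent, x$noise_sd))
  cat(sprintf("  SNR %.2f dB  CNR CSF-GM %.2f  CSF-WM %.2f  GM-WM %.2f dB\n",
              x$snr_db, x$cnr_csf_gm, x$cnr_csf_wm, x$cnr_gm_wm))
  if (!is.na(x$psnr_db))
    cat(sprintf("  PSNR %.2f dB  SSIM %.4f\n", x$psnr_db, x$ssim))
  invisible(x)
}
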