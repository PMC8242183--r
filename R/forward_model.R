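#' Gaussian slice-profile standard deviation from FWHM
#'
#' The through-plane excitation profile of a 2D multi-slice acquisition is
#' modelled as a Gaussian whose full width at half maximum equals the
#' nominal slice thickness; this converts that FWHM to the Gaussian sigma.
#'
#' @param fwhm full width at half maximum, mm (> 0).
#' @return `fwhm / (2 * sqrt(2 * log(2)))`, in mm.
#' @export
profile_sigma <- function(fwhm) {
  if (any(fwhm <= 0)) stop("profile_sigma: fwhm must be > 0")
  fwhm / (2 * sqrt(2 * log(2)))
}

axis_index <- function(slice_axis) {
  match(match.arg(slice_axis, c("x", "y", "z")), c("x", "y", "z"))
}

#' Acquisition specification for one low-resolution stack
#'
#' Describes the geometry of a thick-slice 2D acquisition relative to the
#' high-resolution reconstruction lattice: which axis is the
#' slice-selection direction, the slice thickness, the in-plane spacing,
#' and the number of slices. Slices are contiguous (spacing equals
#' thickness, no gap or overlap), so by default
#' `n_slices = round(extent / slice_thickness)` along the slice axis.
#'
#' @param slice_axis one of `"x"`, `"y"`, `"z"`.
#' @param slice_thickness slice thickness in mm; must be at least the
#'   largest in-plane spacing (the stack is anisotropic).
#' @param hr_grid the reconstruction [voxel_grid()].
#' @param n_slices number of slices; defaults to the HR extent along the
#'   slice axis divided by the thickness, rounded.
#' @return An object of class `acquisition_spec` with fields `slice_axis`
#'   (axis label), `axis` (1-3), `slice_thickness`, `inplane_spacing`,
#'   `n_slices`, and `hr_grid`.
#' @export
acquisition_spec <- function(slice_axis, slice_thickness, hr_grid,
                             n_slices = NULL) {
  ax <- axis_index(slice_axis)
  inplane <- hr_grid$spacing[-ax]
  if (slice_thickness < max(inplane))
    stop("acquisition_spec: slice_thickness must be >= max in-plane spacing")
  extent <- grid_extent(hr_grid)[ax]
  if (is.null(n_slices)) n_slices <- round(extent / slice_thickness)
  n_slices <- as.integer(n_slices)
  if (n_slices < 1) stop("acquisition_spec: n_slices must be >= 1")
  if (n_slices * slice_thickness > extent + slice_thickness)
    stop("acquisition_spec: slices exceed the HR field of view")
  structure(list(slice_axis = c("x", "y", "z")[ax], axis = ax,
                 slice_thickness = slice_thickness,
                 inplane_spacing = inplane, n_slices = n_slices,
                 hr_grid = hr_grid),
            class = "acquisition_spec")
}

# fft-ordered spatial frequencies (cycles/mm) for n samples at spacing h
fft_freqs <- function(n, h) {
  k <- c(0:floor((n - 1) / 2), if (n > 1) -(ceiling((n - 1) / 2):1)) / (n * h)
  k
}

# HR-spectrum slot (1-based, fft order) for each LR-spectrum slot; for an
# even LR length the retained band includes the negative Nyquist sample
# and excludes the positive one.
keep_band_indices <- function(n_hr, n_lr) {
  # integer frequencies in LR fft slot order: 0 .. ceil(n/2)-1, then
  # -floor(n/2) .. -1
  k_lr_order <- c(0:(ceiling(n_lr / 2) - 1),
                  if (n_lr > 1) (-floor(n_lr / 2)):(-1))
  ifelse(k_lr_order >= 0, k_lr_order, n_hr + k_lr_order) + 1L
}

#' Combined slice-profile and downsampling frequency filter
#'
#' Builds the single frequency-domain operator realizing one thick-slice
#' acquisition along its slice axis: a Gaussian transfer
#' `exp(-2 pi^2 sigma^2 f^2)` (the Fourier transform of the slice profile,
#' with sigma from [profile_sigma()] of the slice thickness) followed by
#' truncation of the spectrum to the `n_slices` lowest frequencies centred
#' on DC. In-plane frequencies are untouched: only through-plane
#' resolution is degraded. For an even number of retained samples the band
#' keeps the negative-Nyquist sample and drops the positive one.
#'
#' @param spec an [acquisition_spec()].
#' @return An object of class `frequency_filter` with fields `slice_axis`,
#'   `axis`, `transfer` (length = HR samples along the axis, fft order),
#'   `keep` (HR spectrum slots retained, LR fft slot order), `n_hr`,
#'   `n_lr`, and `freqs` (cycles/mm, fft order).
#' @export
build_filter <- function(spec) {
  stopifnot(inherits(spec, "acquisition_spec"))
  ax <- spec$axis
  n_hr <- spec$hr_grid$shape[ax]
  h <- spec$hr_grid$spacing[ax]
  if (spec$n_slices > n_hr)
    stop("build_filter: n_slices exceeds HR samples along the slice axis")
  f <- fft_freqs(n_hr, h)
  sigma <- profile_sigma(spec$slice_thickness)
  transfer <- exp(-2 * pi^2 * sigma^2 * f^2)
  structure(list(slice_axis = spec$slice_axis, axis = ax,
                 transfer = transfer,
                 keep = keep_band_indices(n_hr, spec$n_slices),
                 n_hr = n_hr, n_lr = spec$n_slices, freqs = f),
            class = "frequency_filter")
}

#' An all-pass filter (identity operator) for a grid axis
#'
#' Convenience constructor used mainly in solver tests and single-grid
#' deconvolution settings: unit transfer, no truncation.
#'
#' @param hr_grid a [voxel_grid()].
#' @param slice_axis axis label.
#' @return A `frequency_filter` with `transfer = 1` everywhere and a full
#'   keep band.
#' @export
identity_filter <- function(hr_grid, slice_axis = "z") {
  ax <- axis_index(slice_axis)
  n <- hr_grid$shape[ax]
  structure(list(slice_axis = c("x", "y", "z")[ax], axis = ax,
                 transfer = rep(1, n), keep = seq_len(n),
                 n_hr = n, n_lr = n,
                 freqs = fft_freqs(n, hr_grid$spacing[ax])),
            class = "frequency_filter")
}

# Grid of the LR stack produced by a filter: HR grid decimated along the
# slice axis (same origin; spectral subsampling keeps the first sample at
# the HR origin).
lr_grid_for <- function(spec) {
  ax <- spec$axis
  shape <- spec$hr_grid$shape; spacing <- spec$hr_grid$spacing
  shape[ax] <- spec$n_slices
  spacing[ax] <- spec$hr_grid$shape[ax] * spec$hr_grid$spacing[ax] /
    spec$n_slices
  voxel_grid(shape, spacing, spec$hr_grid$origin)
}

is_identity_transform <- function(t) {
  all(t$rotation == 0) && all(t$translation == 0)
}

# Apply a 1D frequency-domain operation along `axis` of a 3D array.
# `fun` maps an (n x m) complex spectrum matrix (columns = lines) to a
# (n_out x m) spectrum matrix; returns the real inverse transform scaled
# by 1/n_in (the convention that preserves constants in the forward
# direction) or 1/n_out for the adjoint (caller chooses via `scale`).
apply_along_axis_fft <- function(arr, axis, fun, scale) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(arr, perm)
  dm <- dim(m)
  dim(m) <- c(dm[1], dm[2] * dm[3])
  spec <- mvfft(m)
  out_spec <- fun(spec)
  out <- Re(mvfft(out_spec, inverse = TRUE)) * scale
  dim(out) <- c(nrow(out_spec), dm[2], dm[3])
  aperm(out, order(perm))
}

#' Apply the acquisition forward operator
#'
#' Realizes one thick-slice acquisition of a high-resolution volume:
#' resample under the scan's rigid pose (order-3 B-spline), multiply the
#' through-plane spectrum by the Gaussian slice-profile transfer, and
#' truncate it to the retained low-frequency band (the downsampling).
#' Scaling preserves the mean intensity: a constant volume maps to the
#' same constant. Noise is not added here; see [add_noise()].
#'
#' @param x a `volume` on `spec$hr_grid`.
#' @param transform the scan's [rigid_transform()] pose.
#' @param spec an [acquisition_spec()].
#' @param filter the matching [build_filter()] output (built from `spec`
#'   if omitted).
#' @return The LR stack as a `volume` on the decimated grid.
#' @export
apply_forward <- function(x, transform = rigid_identity(), spec,
                          filter = build_filter(spec)) {
  stopifnot(inherits(x, "volume"), inherits(spec, "acquisition_spec"))
  if (!all(x$grid$shape == spec$hr_grid$shape))
    stop("apply_forward: volume is not on the spec's HR grid")
  if (!is_identity_transform(transform))
    x <- resample_to_grid(x, spec$hr_grid, transform, order = 3)
  keep <- filter$keep
  transfer <- filter$transfer
  n_hr <- filter$n_hr
  out <- apply_along_axis_fft(x$data, filter$axis, function(s) {
    (s * transfer)[keep, , drop = FALSE]
  }, scale = 1 / n_hr)
  as_volume(out, lr_grid_for(spec))
}

#' Adjoint of the acquisition forward operator
#'
#' The transpose of [apply_forward()] under voxel-volume-weighted L2 inner
#' products (the discretization of the continuous L2 inner product), which
#' makes the adjoint, like the forward map, preserve constants: zero-fill
#' upsampling of the through-plane spectrum into the HR band, conjugate
#' (real, symmetric) filter application, and resampling under the inverse
#' rigid pose. Satisfies
#' `sum(A x * y) * vox_lr == sum(x * At y) * vox_hr` to within the
#' interpolation error (exactly, for an identity pose).
#'
#' @param y an LR stack `volume` conforming to `spec`.
#' @param transform the scan's [rigid_transform()] pose.
#' @param spec an [acquisition_spec()].
#' @param filter the matching `frequency_filter`.
#' @return A `volume` on `spec$hr_grid`.
#' @export
adjoint_forward <- function(y, transform = rigid_identity(), spec,
                            filter = build_filter(spec)) {
  stopifnot(inherits(y, "volume"), inherits(spec, "acquisition_spec"))
  lr <- lr_grid_for(spec)
  if (!all(y$grid$shape == lr$shape))
    stop("adjoint_forward: stack shape does not conform to the spec")
  keep <- filter$keep
  transfer <- filter$transfer
  n_hr <- filter$n_hr
  n_lr <- filter$n_lr
  out <- apply_along_axis_fft(y$data, filter$axis, function(s) {
    full <- matrix(0 + 0i, n_hr, ncol(s))
    full[keep, ] <- s
    full * transfer
  }, scale = 1 / n_lr)
  v <- as_volume(out, spec$hr_grid)
  if (!is_identity_transform(transform))
    v <- resample_to_grid(v, spec$hr_grid, invert_transform(transform),
                          order = 3)
  v
}

#' Additive Gaussian noise model
#'
#' Thermal noise in magnitude MRI is well approximated as additive,
#' independent and Gaussian at SNR above about 3.
#'
#' @param sd noise standard deviation in intensity units (>= 0).
#' @param seed integer seed making draws reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd = 0, seed = 1L) {
  if (sd < 0) stop("noise_model: sd must be >= 0")
  structure(list(sd = sd, seed = as.integer(seed)), class = "noise_model")
}

#' Add acquisition noise to a volume
#'
#' @param y a `volume`.
#' @param noise a [noise_model()].
#' @return `y` plus independent zero-mean Gaussian draws of the model's
#'   sd; identical to `y` when `sd = 0`; deterministic given the seed.
#' @export
add_noise <- function(y, noise) {
  stopifnot(inherits(y, "volume"), inherits(noise, "noise_model"))
  if (noise$sd == 0) return(y)
  set.seed(noise$seed)
  as_volume(y$data + array(rnorm(length(y$data), sd = noise$sd),
                           dim(y$data)), y$grid)
}

#' Simulate a set of thick-slice acquisitions
#'
#' Runs [apply_forward()] followed by [add_noise()] for each scan; the
#' k-th scan uses an independent noise stream seeded `noise$seed + k`.
#' Three orthogonal specs reproduce the standard
#' axial/coronal/sagittal variable-slice-direction protocol; a single spec
#' is the single-stack (SISR) configuration.
#'
#' @param x ground-truth HR `volume`.
#' @param specs list of [acquisition_spec()].
#' @param transforms list of [rigid_transform()] (same length).
#' @param noise a [noise_model()].
#' @return List of LR `volume`s.
#' @export
simulate_acquisitions <- function(x, specs, transforms = NULL,
                                  noise = noise_model(0)) {
  if (is.null(transforms))
    transforms <- replicate(length(specs), rigid_identity(),
                            simplify = FALSE)
  if (length(specs) != length(transforms))
    stop("simulate_acquisitions: specs and transforms lengths differ")
  if (length(specs) < 1)
    stop("simulate_acquisitions: need at least one spec")
  lapply(seq_along(specs), function(k) {
    y <- apply_forward(x, transforms[[k]], specs[[k]])
    add_noise(y, noise_model(noise$sd, noise$seed + k))
  })
}
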