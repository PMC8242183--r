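#' Three-tissue intensity model
#'
#' Mean intensities and within-class standard deviations for the three
#' brain tissue classes (CSF, GM, WM), together with the contrast type
#' that fixes their ordering: in T2-like contrast GM < WM < CSF, in
#' T1-like contrast CSF < GM < WM.
#'
#' @param means named numeric length-3 `c(CSF=, GM=, WM=)` mean intensity
#'   per class; defaults emulate a T2-like scan (GM 100, WM 200, CSF 300).
#' @param sds non-negative within-class standard deviations (default 0,
#'   piecewise-constant tissue).
#' @param contrast `"t2"` or `"t1"`.
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(means = c(CSF = 300, GM = 100, WM = 200),
                         sds = c(CSF = 0, GM = 0, WM = 0),
                         contrast = c("t2", "t1")) {
  contrast <- match.arg(contrast)
  stopifnot(length(means) == 3, length(sds) == 3)
  nm <- c("CSF", "GM", "WM")
  if (is.null(names(means))) names(means) <- nm
  if (is.null(names(sds))) names(sds) <- nm
  means <- means[nm]; sds <- sds[nm]
  if (any(duplicated(means)))
    stop("tissue_model: class means must be pairwise distinct")
  if (any(sds < 0)) stop("tissue_model: sds must be non-negative")
  ok <- if (contrast == "t2")
    means["GM"] < means["WM"] && means["WM"] < means["CSF"]
  else
    means["CSF"] < means["GM"] && means["GM"] < means["WM"]
  if (!ok)
    stop("tissue_model: means violate the ", contrast, " contrast ordering")
  structure(list(class_names = nm, means = means, sds = sds,
                 contrast = contrast), class = "tissue_model")
}

#' Phantom specification
#'
#' @param grid reconstruction [voxel_grid()]; default 96^3 at 0.5 mm
#'   isotropic, the scale at which thick-slice simulation studies are
#'   typically run while staying desk-sized.
#' @param tissue_model a [tissue_model()].
#' @param geometry_seed integer seed controlling the random geometry.
#' @param noise_sd additive Gaussian noise standard deviation (>= 0).
#' @param n_blobs number of lobes in the outer shape (default 6).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = voxel_grid(c(96, 96, 96), c(0.5, 0.5, 0.5)),
                         tissue_model = srrmri::tissue_model(),
                         geometry_seed = 1L, noise_sd = 0, n_blobs = 6L) {
  if (noise_sd < 0) stop("phantom_spec: noise_sd must be >= 0")
  structure(list(grid = grid, tissue_model = tissue_model,
                 geometry_seed = as.integer(geometry_seed),
                 noise_sd = noise_sd, n_blobs = as.integer(n_blobs)),
            class = "phantom_spec")
}

# Smooth periodic random field on an n1 x n2 x n3 lattice: white Gaussian
# noise low-passed with a Gaussian transfer in the frequency domain and
# rescaled to unit standard deviation.
smooth_noise_field <- function(shape, smooth_vox = 6) {
  w <- array(rnorm(prod(shape)), shape)
  freqs <- lapply(shape, function(n) {
    k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1)) / n
    k
  })
  fx <- freqs[[1]]; fy <- freqs[[2]]; fz <- freqs[[3]]
  g1 <- exp(-2 * pi^2 * smooth_vox^2 * fx^2)
  g2 <- exp(-2 * pi^2 * smooth_vox^2 * fy^2)
  g3 <- exp(-2 * pi^2 * smooth_vox^2 * fz^2)
  gf <- outer(outer(g1, g2), g3)
  sm <- Re(fft(fft(w) * gf, inverse = TRUE)) / prod(shape)
  sm / sd(sm)
}

#' Generate a synthetic three-tissue phantom
#'
#' Builds a nested smooth geometry on the requested grid: an outer CSF
#' shell, a GM ribbon, and a WM core, all bounded by level sets of a
#' radius field perturbed with smoothed random noise so the GM/WM
#' interface is convoluted rather than spherical. The image assigns each
#' voxel its class mean plus independent Gaussian noise; the whole
#' construction is deterministic given `geometry_seed`.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `labels` (a `volume` of class indices: 0 background,
#'   1 CSF, 2 GM, 3 WM), `image` (a `volume`), and `boundary_mask` (a
#'   [region_mask()] marking foreground voxels 6-adjacent to a different
#'   foreground class).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$grid$shape
  if (any(shape < 16))
    stop("make_phantom: grid must be at least 16 voxels on every axis")
  set.seed(spec$geometry_seed)
  # normalized radius field, perturbed by two smooth noise fields at
  # different scales so that inner interfaces fold more than the outer one
  ax <- lapply(shape, function(n) (seq_len(n) - (n + 1) / 2) / (n / 2))
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  r <- sqrt(r2)
  pert_out <- smooth_noise_field(shape, smooth_vox = max(shape) / 8)
  pert_in <- smooth_noise_field(shape, smooth_vox = max(shape) / 16)
  rr_outer <- r * (1 + 0.10 * pert_out)
  rr_inner <- r * (1 + 0.10 * pert_out + 0.18 * pert_in)
  labels <- array(0L, shape)
  labels[rr_outer < 0.92] <- 1L            # CSF shell
  labels[rr_inner < 0.72] <- 2L            # GM ribbon
  labels[rr_inner < 0.50] <- 3L            # WM core
  tm <- spec$tissue_model
  class_means <- c(0, tm$means["CSF"], tm$means["GM"], tm$means["WM"])
  class_sds <- c(0, tm$sds["CSF"], tm$sds["GM"], tm$sds["WM"])
  img <- class_means[labels + 1L]
  if (any(class_sds > 0))
    img <- img + rnorm(length(img), sd = class_sds[labels + 1L])
  if (spec$noise_sd > 0)
    img <- img + rnorm(length(img), sd = spec$noise_sd)
  dim(img) <- shape
  bnd <- boundary_voxels(labels)
  list(labels = as_volume(array(as.numeric(labels), shape), spec$grid),
       image = as_volume(img, spec$grid),
       boundary_mask = region_mask(spec$grid, bnd))
}

# Logical array marking foreground voxels with at least one 6-face
# neighbour in a different nonzero class.
boundary_voxels <- function(labels) {
  n <- dim(labels)
  bnd <- array(FALSE, n)
  shift_cmp <- function(axis, by) {
    idx_a <- lapply(n, seq_len)
    idx_b <- idx_a
    if (by > 0) {
      idx_a[[axis]] <- 1:(n[axis] - 1); idx_b[[axis]] <- 2:n[axis]
    } else {
      idx_a[[axis]] <- 2:n[axis]; idx_b[[axis]] <- 1:(n[axis] - 1)
    }
    a <- labels[idx_a[[1]], idx_a[[2]], idx_a[[3]], drop = FALSE]
    b <- labels[idx_b[[1]], idx_b[[2]], idx_b[[3]], drop = FALSE]
    diff <- a != b & a != 0 & b != 0
    upd <- array(FALSE, n)
    upd[idx_a[[1]], idx_a[[2]], idx_a[[3]]] <- diff
    upd[idx_b[[1]], idx_b[[2]], idx_b[[3]]] <-
      upd[idx_b[[1]], idx_b[[2]], idx_b[[3]]] | diff
    upd
  }
  for (axis in 1:3) {
    bnd <- bnd | shift_cmp(axis, +1)
  }
  bnd
}

#' Fraction of foreground voxels on a tissue boundary
#'
#' Counts foreground voxels having at least one of their six face
#' neighbours in a different foreground class, divided by the number of
#' foreground voxels. Serves as the geometric ground truth for
#' partial-volume studies: in a thick-slice acquisition essentially all
#' mixed-signal voxels arise at these interfaces.
#'
#' @param labels a `volume` of integer class labels (0 = background).
#' @return Fraction in `[0, 1]`.
#' @export
ground_truth_boundary_fraction <- function(labels) {
  stopifnot(inherits(labels, "volume"))
  lab <- array(as.integer(round(labels$data)), dim(labels$data))
  fg <- sum(lab != 0L)
  if (fg == 0) stop("ground_truth_boundary_fraction: no foreground voxels")
  sum(boundary_voxels(lab)) / fg
}
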