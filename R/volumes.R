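#' @useDynLib srrmri, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft mvfft optim rnorm runif quantile sd dnorm
#' @importFrom utils head tail
NULL

#' Construct a voxel grid
#'
#' A `voxel_grid` describes an axis-aligned 3D sampling lattice: the number
#' of voxels per axis, the spacing between voxel centres in mm, and the
#' world position (mm) of voxel index `(0, 0, 0)`. World coordinates of a
#' voxel index `v` (0-based) are `origin + v * spacing`. Oblique lattices
#' are not modelled; inter-scan pose is carried by [rigid_transform()].
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing numeric vector of length 3, mm per voxel (all > 0).
#' @param origin numeric vector of length 3, world mm of voxel (0,0,0).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(shape < 1L)) stop("voxel_grid: all shape entries must be >= 1")
  if (any(spacing <= 0)) stop("voxel_grid: all spacing entries must be > 0")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %dx%dx%d, spacing %.4g x %.4g x %.4g mm>\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) <= tol * pmax(1, abs(a$spacing))) &&
    all(abs(a$origin - b$origin) <= tol * pmax(1, abs(b$origin), abs(a$origin)))
}

#' Physical extent of a grid along each axis
#'
#' Extent is measured as `shape * spacing`, i.e. the length of the field of
#' view counted in whole voxels (each voxel centre owns one spacing of
#' space).
#'
#' @param grid a [voxel_grid()].
#' @return numeric length-3 vector of extents in mm.
#' @export
grid_extent <- function(grid) grid$shape * grid$spacing

#' Construct a volume
#'
#' A `volume` couples a 3D numeric intensity array with its sampling grid.
#' All operations in the package maintain a NaN-free contract: any
#' out-of-field values created by resampling are filled with a finite
#' background value (0 by default).
#'
#' @param data 3D numeric array whose dimensions match `grid$shape`.
#' @param grid a [voxel_grid()]; alternatively supply `spacing`/`origin`.
#' @param spacing,origin used to build a grid when `grid` is missing.
#' @return An object of class `volume` with elements `data` and `grid`.
#' @export
as_volume <- function(data, grid = NULL, spacing = c(1, 1, 1),
                      origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3)
    stop("as_volume: data must be a 3D array, got dimensionality ",
         length(dim(data)))
  if (is.null(grid)) grid <- voxel_grid(dim(data), spacing, origin)
  if (!all(dim(data) == grid$shape))
    stop("as_volume: data dimensions do not match grid shape")
  storage.mode(data) <- "double"
  structure(list(data = data, grid = grid), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume %dx%dx%d, spacing %.4g x %.4g x %.4g mm, range [%.4g, %.4g]>\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              x$grid$spacing[1], x$grid$spacing[2], x$grid$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a region mask
#'
#' @param grid a [voxel_grid()].
#' @param selected logical 3D array matching `grid$shape`.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(grid, selected) {
  if (!all(dim(selected) == grid$shape))
    stop("region_mask: selected dimensions do not match grid shape")
  storage.mode(selected) <- "logical"
  structure(list(grid = grid, selected = selected), class = "region_mask")
}

#' Read a 3D NIfTI volume
#'
#' Volumes are reoriented to a canonical RAS-like layout on load so that
#' downstream axis conventions do not branch on acquisition orientation.
#' Spacing and origin are taken from the file's qform/sform affine; only
#' axis-aligned lattices are supported.
#'
#' @param path path to a readable NIfTI-1 file (.nii or .nii.gz).
#' @return A [as_volume()] `volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd != 3)
    stop("read_volume: expected 3D image, got ", nd, "D in ", path)
  RNifti::orientation(img) <- "RAS"
  aff <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- as.numeric(aff[1:3, 4])
  as_volume(array(as.numeric(img), dim = dim(img)),
            voxel_grid(dim(img), spacing, origin))
}

#' Write a volume as NIfTI-1
#'
#' @param v a `volume`.
#' @param path output path (.nii or .nii.gz); parent directory must exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume"))
  if (!dir.exists(dirname(path)))
    stop("write_volume: directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$grid$spacing
  aff <- diag(4)
  diag(aff)[1:3] <- v$grid$spacing
  aff[1:3, 4] <- v$grid$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume onto a target grid under a rigid transform
#'
#' Each target voxel's world coordinate `w` is mapped through the rigid
#' transform and the source volume is interpolated at the mapped point.
#' Order 3 uses an interpolating cubic B-spline (recursive prefilter,
#' mirror boundary), the interpolation family standard for multi-scan MRI
#' resampling; it reproduces the source values exactly at the knots and
#' reproduces constant and linear intensity fields in the interior.
#'
#' @param v source `volume`.
#' @param target target [voxel_grid()].
#' @param transform a [rigid_transform()]; identity by default.
#' @param order interpolation order, one of 0 (nearest), 1 (trilinear),
#'   3 (cubic B-spline, default).
#' @param fill value assigned to out-of-field samples (default 0,
#'   background air; `NA` can be used internally for validity masking).
#' @return A `volume` on `target`.
#' @export
resample_to_grid <- function(v, target, transform = rigid_identity(),
                             order = 3, fill = 0) {
  stopifnot(inherits(v, "volume"), inherits(target, "voxel_grid"))
  if (!order %in% c(0, 1, 3))
    stop("resample_to_grid: order must be 0, 1 or 3")
  if (any(target$shape < 1) || any(target$spacing <= 0))
    stop("resample_to_grid: degenerate target grid")
  src <- v$data
  if (order == 3) src <- cpp_bspline_prefilter(src, v$grid$shape)
  out <- cpp_resample3d(src, v$grid$shape, v$grid$spacing, v$grid$origin,
                        target$shape, target$spacing, target$origin,
                        rotation_matrix(transform$rotation),
                        transform$translation, transform$center,
                        as.integer(order), fill)
  as_volume(out, target)
}
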