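#' Enumerate gradient-guidance shift triples
#'
#' The gradient guidance is built from shift-difference fields
#' `I - shift(I, (alpha, beta, gamma))` over a set of integer shift
#' triples spanning several orientations and scales. The triple set is the
#' Cartesian product of the given ranges minus the all-zero triple and all
#' triples whose coordinate sum is negative (which would duplicate an
#' included triple up to sign). With the default ranges
#' `alpha in [-2, 2]`, `beta, gamma in [0, 2]` exactly 40 triples survive.
#'
#' @param alpha_range,beta_range,gamma_range integer length-2 ranges
#'   `c(lo, hi)` for the shift along x, y and z (voxels).
#' @return A data.frame with integer columns `alpha`, `beta`, `gamma`, in
#'   lexicographic order.
#' @export
enumerate_shifts <- function(alpha_range = c(-2, 2), beta_range = c(0, 2),
                             gamma_range = c(0, 2)) {
  g <- expand.grid(gamma = gamma_range[1]:gamma_range[2],
                   beta = beta_range[1]:beta_range[2],
                   alpha = alpha_range[1]:alpha_range[2])
  g <- g[, c("alpha", "beta", "gamma")]
  keep <- !(g$alpha == 0 & g$beta == 0 & g$gamma == 0) &
    (g$alpha + g$beta + g$gamma >= 0)
  g <- g[keep, , drop = FALSE]
  g <- g[order(g$alpha, g$beta, g$gamma), , drop = FALSE]
  rownames(g) <- NULL
  if (nrow(g) == 0)
    stop("enumerate_shifts: no shift triples survive the exclusions")
  g
}

# circularly shift a 3D array by integer voxels (positive = towards
# higher indices, with wrap-around)
circular_shift <- function(a, s) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax) {
    n <- d[ax]
    k <- ((seq_len(n) - 1 - s[ax]) %% n) + 1
    k
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Shift-difference gradient field
#'
#' Computes `v - shift(v, s)` where the shift is circular by
#' `(alpha, beta, gamma)` voxels along x, y, z. This single operator
#' family realizes both the guidance components (applied to the IAA
#' image) and the matching spatial gradients of the reconstruction, at
#' every orientation and scale in the shift set. The lattice sum of the
#' output is always exactly zero.
#'
#' @param v a `volume`.
#' @param s integer length-3 shift, or a one-row data.frame with columns
#'   `alpha`, `beta`, `gamma`.
#' @return A `volume` on the same grid.
#' @export
shift_difference <- function(v, s) {
  stopifnot(inherits(v, "volume"))
  if (is.data.frame(s)) s <- c(s$alpha[1], s$beta[1], s$gamma[1])
  s <- as.integer(s)
  as_volume(v$data - circular_shift(v$data, s), v$grid)
}

# adjoint of shift_difference: (I - S)^T = I - S^{-1}
shift_difference_adjoint <- function(v, s) {
  if (is.data.frame(s)) s <- c(s$alpha[1], s$beta[1], s$gamma[1])
  s <- as.integer(s)
  as_volume(v$data - circular_shift(v$data, -s), v$grid)
}

#' Interpolate-and-average (IAA) combination
#'
#' Voxelwise arithmetic mean of volumes already interpolated and aligned
#' onto a common high-resolution grid. This is the classical multi-scan
#' averaging baseline: it improves SNR by sqrt(n) but blurs tissue
#' boundaries because the thick-slice blur is never inverted.
#'
#' @param volumes list of `volume`s on identical grids.
#' @return The mean `volume`.
#' @export
iaa_combine <- function(volumes) {
  if (length(volumes) < 1) stop("iaa_combine: need at least one volume")
  g <- volumes[[1]]$grid
  for (v in volumes)
    if (!grids_equal(v$grid, g))
      stop("iaa_combine: volumes must share a common grid")
  acc <- volumes[[1]]$data
  if (length(volumes) > 1)
    for (k in 2:length(volumes)) acc <- acc + volumes[[k]]$data
  as_volume(acc / length(volumes), g)
}

#' Build the gradient-guidance set
#'
#' Computes one shift-difference field of the IAA image per shift triple.
#' The guidance is computed once and frozen: the solver's L1 term pulls
#' each matching shift-difference of the reconstruction towards these
#' fields, favouring edges where the averaged image has edges while
#' suppressing noise-induced gradients.
#'
#' @param iaa_image the IAA `volume` (reference image for the guidance).
#' @param shifts data.frame from [enumerate_shifts()].
#' @return An object of class `guidance_set`: list with `shifts` and
#'   `fields` (one `volume` per shift).
#' @export
build_guidance <- function(iaa_image, shifts = enumerate_shifts()) {
  stopifnot(inherits(iaa_image, "volume"))
  fields <- lapply(seq_len(nrow(shifts)), function(i)
    shift_difference(iaa_image, shifts[i, ]))
  structure(list(shifts = shifts, fields = fields), class = "guidance_set")
}
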