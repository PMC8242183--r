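#' Construct a rigid transform
#'
#' A 6-degree-of-freedom rigid-body transform representing inter-scan
#' motion: three fixed-axis rotation angles and a translation, applied
#' about a rotation centre as
#' `T(w) = R (w - center) + center + translation`, with
#' `R = Rz(rz) Ry(ry) Rx(rx)` (extrinsic x-y-z convention).
#'
#' @param rotation numeric length-3, rotation angles in radians about the
#'   world x, y and z axes.
#' @param translation numeric length-3, translation in mm.
#' @param center numeric length-3, rotation centre in world mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- as.numeric(rotation); translation <- as.numeric(translation)
  center <- as.numeric(center)
  stopifnot(length(rotation) == 3, length(translation) == 3,
            length(center) == 3)
  structure(list(rotation = rotation, translation = translation,
                 center = center), class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rigid_identity <- function() rigid_transform()

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform rot (deg) %.3f %.3f %.3f, trans (mm) %.3f %.3f %.3f>\n",
              x$rotation[1] * 180 / pi, x$rotation[2] * 180 / pi,
              x$rotation[3] * 180 / pi,
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation matrix of a rigid transform
#'
#' @param angles numeric length-3 fixed-axis angles (radians).
#' @return 3x3 rotation matrix `Rz(rz) Ry(ry) Rx(rx)`.
#' @export
rotation_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

# Recover fixed-axis angles from a rotation matrix R = Rz Ry Rx.
angles_from_matrix <- function(r) {
  ry <- asin(max(-1, min(1, -r[3, 1])))
  if (abs(cos(ry)) > 1e-12) {
    rx <- atan2(r[3, 2], r[3, 3])
    rz <- atan2(r[2, 1], r[1, 1])
  } else { # gimbal lock; fold everything into rx
    rx <- atan2(-r[2, 3], r[2, 2])
    rz <- 0
  }
  c(rx, ry, rz)
}

#' Invert a rigid transform
#'
#' @param t a [rigid_transform()].
#' @return The inverse transform (same rotation centre).
#' @export
invert_transform <- function(t) {
  r <- rotation_matrix(t$rotation)
  rigid_transform(angles_from_matrix(t(r)),
                  as.numeric(-t(r) %*% t$translation), t$center)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`
#' (`compose(second, first)(w) = second(first(w))`). Both must share a
#' rotation centre.
#'
#' @param second,first [rigid_transform()] objects with equal centres.
#' @return The composed [rigid_transform()].
#' @export
compose_transforms <- function(second, first) {
  if (max(abs(second$center - first$center)) > 1e-9)
    stop("compose_transforms: transforms must share a rotation centre")
  r2 <- rotation_matrix(second$rotation)
  r1 <- rotation_matrix(first$rotation)
  rigid_transform(angles_from_matrix(r2 %*% r1),
                  as.numeric(r2 %*% first$translation) + second$translation,
                  first$center)
}

#' Mutual information between two volumes
#'
#' Shannon mutual information (nats) of the joint intensity histogram,
#' computed over voxels that are in-field in both volumes (NA marks
#' out-of-field samples produced by resampling with `fill = NA`).
#' Intensities are clipped to the joint 1st-99th percentile range before
#' binning, a standard robustness measure against background and outlier
#' tails.
#'
#' @param a,b `volume`s on a common grid.
#' @param bins number of histogram bins per axis (>= 8; default 32).
#' @return Mutual information in nats.
#' @export
mutual_information <- function(a, b, bins = 32) {
  stopifnot(inherits(a, "volume"), inherits(b, "volume"))
  if (!all(a$grid$shape == b$grid$shape))
    stop("mutual_information: volumes must share a grid")
  if (bins < 8) stop("mutual_information: bins must be >= 8")
  va <- as.numeric(a$data); vb <- as.numeric(b$data)
  ok <- !is.na(va) & !is.na(vb)
  if (!any(ok)) stop("mutual_information: fields of view are disjoint")
  va <- va[ok]; vb <- vb[ok]
  qa <- quantile(va, c(0.01, 0.99), names = FALSE)
  qb <- quantile(vb, c(0.01, 0.99), names = FALSE)
  if (qa[1] == qa[2]) qa <- qa + c(-0.5, 0.5)
  if (qb[1] == qb[2]) qb <- qb + c(-0.5, 0.5)
  ia <- pmin(pmax(floor((va - qa[1]) / (qa[2] - qa[1]) * bins), 0), bins - 1)
  ib <- pmin(pmax(floor((vb - qb[1]) / (qb[2] - qb[1]) * bins), 0), bins - 1)
  joint <- tabulate(ia * bins + ib + 1L, nbins = bins * bins)
  p <- joint / sum(joint)
  px <- rowSums(matrix(p, bins, bins, byrow = TRUE))
  py <- colSums(matrix(p, bins, bins, byrow = TRUE))
  nz <- p > 0
  hxy <- -sum(p[nz] * log(p[nz]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  hx + hy - hxy
}

# Negative MI of (moving resampled under params) vs fixed, for the
# optimizer. Out-of-field samples are zero-filled (background) rather than
# excluded: scoring only the overlap rewards poses that shrink it, which
# flattens and even inverts the cost surface near the optimum.
mi_cost <- function(par, moving, fixed, center, bins, order) {
  tr <- rigid_transform(par[1:3] * pi / 180, par[4:6], center)
  m <- resample_to_grid(moving, fixed$grid, tr, order = order, fill = 0)
  -mutual_information(m, fixed, bins)
}

# Decimate a volume by 2 along every axis (voxel-centre subsampling after
# a light box smoothing) for the coarse registration level.
decimate2 <- function(v) {
  d <- v$data
  n <- dim(d)
  idx <- lapply(n, function(k) seq(1, k, by = 2))
  sub <- d[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  g <- voxel_grid(dim(sub), v$grid$spacing * 2, v$grid$origin)
  as_volume(sub, g)
}

#' Rigid registration by mutual-information maximization
#'
#' Aligns `moving` to `fixed` by maximizing mutual information over the six
#' rigid parameters with a derivative-free Nelder-Mead search on a two-level
#' coarse-to-fine schedule (half resolution, then full resolution). Both
#' volumes are expected to have been interpolated to a common
#' high-resolution grid beforehand. The rotation centre is the world centre
#' of the fixed volume. The result is deterministic given `init`, and is
#' never worse (in MI) than `init`: if the search fails to improve, `init`
#' is returned with `attr(, "improved") = FALSE`.
#'
#' @param moving,fixed `volume`s on a common grid.
#' @param init initial [rigid_transform()] (default identity).
#' @param bins histogram bins for [mutual_information()].
#' @param maxit Nelder-Mead iteration cap per level.
#' @return A [rigid_transform()] mapping fixed-grid world coordinates into
#'   the moving volume (suitable for [resample_to_grid()]), with attribute
#'   `improved`.
#' @export
register_rigid <- function(moving, fixed, init = rigid_identity(),
                           bins = 32, maxit = 300) {
  stopifnot(inherits(moving, "volume"), inherits(fixed, "volume"))
  center <- fixed$grid$origin + (fixed$grid$shape - 1) * fixed$grid$spacing / 2
  par0 <- c(init$rotation * 180 / pi, init$translation)
  # level 1: half resolution. A coarse translation pre-search widens the
  # capture range beyond the optimizer's initial simplex, then two
  # Nelder-Mead runs (the restart rebuilds the simplex) refine all six
  # parameters.
  mv2 <- decimate2(moving); fx2 <- decimate2(fixed)
  tgrid <- as.matrix(expand.grid(tx = c(-3, 0, 3), ty = c(-3, 0, 3),
                                 tz = c(-3, 0, 3)))
  costs <- apply(tgrid, 1, function(t)
    mi_cost(c(par0[1:3], par0[4:6] + t), mv2, fx2, center, bins, 1))
  best <- which.min(costs)
  par0_l1 <- c(par0[1:3], par0[4:6] + tgrid[best, ])
  o1 <- optim(par0_l1, mi_cost, moving = mv2, fixed = fx2, center = center,
              bins = bins, order = 1,
              method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = 1e-7,
                             parscale = rep(2, 6)))
  o1 <- optim(o1$par, mi_cost, moving = mv2, fixed = fx2, center = center,
              bins = bins, order = 1,
              method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = 1e-8))
  # level 2: full resolution, restarted with a small simplex for polish
  o2 <- optim(o1$par, mi_cost, moving = moving, fixed = fixed,
              center = center, bins = bins, order = 1,
              method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = 1e-9,
                             parscale = rep(0.3, 6)))
  o2b <- optim(o2$par, mi_cost, moving = moving, fixed = fixed,
               center = center, bins = bins, order = 1,
               method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-10,
                              parscale = rep(0.05, 6)))
  if (o2b$value <= o2$value) o2 <- o2b
  f_init <- mi_cost(par0, moving, fixed, center, bins, 1)
  if (o2$value <= f_init) {
    out <- rigid_transform(o2$par[1:3] * pi / 180, o2$par[4:6], center)
    attr(out, "improved") <- TRUE
  } else {
    warning("register_rigid: optimizer failed to improve on init")
    out <- rigid_transform(init$rotation, init$translation, center)
    attr(out, "improved") <- FALSE
  }
  out
}

#' Serialize / deserialize rigid transforms as JSON-friendly lists
#'
#' Angles are stored in degrees, translations and centres in mm.
#'
#' @param t a [rigid_transform()].
#' @return `transform_to_list`: a named list; `transform_from_list`: a
#'   [rigid_transform()].
#' @export
transform_to_list <- function(t) {
  list(rotation_deg = t$rotation * 180 / pi,
       translation_mm = t$translation, center_mm = t$center)
}

#' @rdname transform_to_list
#' @param x a list produced by `transform_to_list`.
#' @export
transform_from_list <- function(x) {
  rigid_transform(as.numeric(x$rotation_deg) * pi / 180,
                  as.numeric(x$translation_mm), as.numeric(x$center_mm))
}
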