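# shared fixtures and independent brute-force oracles

random_volume <- function(n = 8, spacing = 1, seed = 1) {
  set.seed(seed)
  as_volume(array(rnorm(n^3), c(n, n, n)),
            voxel_grid(c(n, n, n), rep(spacing, 3)))
}

small_phantom <- function(n = 48, spacing = 1, seed = 3, noise_sd = 0) {
  make_phantom(phantom_spec(
    grid = voxel_grid(c(n, n, n), rep(spacing, 3)),
    geometry_seed = seed, noise_sd = noise_sd))
}

# weighted inner products: the discretized continuous L2 products under
# which the forward/adjoint pair is defined
vol_inner <- function(a, b) sum(a$data * b$data) * prod(a$grid$spacing)

# brute-force voxel-loop shift difference (circular), independent of the
# package's vectorized implementation
brute_shift_difference <- function(arr, s) {
  d <- dim(arr)
  out <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    si <- ((i - 1 - s[1]) %% d[1]) + 1
    sj <- ((j - 1 - s[2]) %% d[2]) + 1
    sk <- ((k - 1 - s[3]) %% d[3]) + 1
    out[i, j, k] <- arr[i, j, k] - arr[si, sj, sk]
  }
  out
}

# brute-force boundary scan: foreground voxels with a 6-face neighbour in
# a different foreground class
brute_boundary_fraction <- function(lab) {
  d <- dim(lab)
  cnt <- 0; fg <- 0
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (lab[i, j, k] == 0) next
    fg <- fg + 1
    hit <- FALSE
    for (off in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                     c(0,0,1), c(0,0,-1))) {
      ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
          kk < 1 || kk > d[3]) next
      if (lab[ii, jj, kk] != 0 && lab[ii, jj, kk] != lab[i, j, k]) {
        hit <- TRUE; break
      }
    }
    if (hit) cnt <- cnt + 1
  }
  cnt / fg
}

# tiny 3-orthogonal-scan simulation used by several solver tests
tiny_sim <- function(n = 24, spacing = 1, thickness = 4, noise_sd = 0,
                     seed = 7) {
  ph <- small_phantom(n = n, spacing = spacing, seed = seed)
  g <- ph$image$grid
  specs <- orthogonal_specs(g, thickness)
  scans <- simulate_acquisitions(ph$image, specs,
                                 noise = noise_model(noise_sd, seed))
  list(truth = ph$image, grid = g, specs = specs, scans = scans,
       transforms = replicate(3, rigid_identity(), simplify = FALSE))
}
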