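#' Fast-spin-echo protocol parameters
#'
#' Bundles the acquisition parameters that determine 2D multi-slice
#' fast-spin-echo scan time: repetition time, phase-encode field of view
#' and voxel size, parallel-imaging acceleration, echo train length, and
#' number of excitations.
#'
#' @param TR repetition time, seconds (> 0).
#' @param FoV_p field of view in the phase-encode direction, mm.
#' @param S_p voxel size in the phase-encode direction, mm.
#' @param f_acc parallel-imaging acceleration factor (>= 1).
#' @param ETL echo train length (positive integer).
#' @param N_NEX number of excitations / averages (positive integer).
#' @param n_slices number of slices (positive integer).
#' @param slice_thickness slice thickness, mm.
#' @return An object of class `protocol_params`.
#' @export
protocol_params <- function(TR, FoV_p, S_p, f_acc = 1, ETL = 1, N_NEX = 1,
                            n_slices = 1, slice_thickness = 2) {
  vals <- c(TR = TR, FoV_p = FoV_p, S_p = S_p, f_acc = f_acc, ETL = ETL,
            N_NEX = N_NEX, n_slices = n_slices,
            slice_thickness = slice_thickness)
  if (any(vals <= 0))
    stop("protocol_params: all parameters must be strictly positive")
  if (f_acc < 1) stop("protocol_params: f_acc must be >= 1")
  for (nm in c("ETL", "N_NEX", "n_slices"))
    if (vals[[nm]] != round(vals[[nm]]))
      stop("protocol_params: ", nm, " must be integral")
  structure(as.list(vals), class = "protocol_params")
}

#' Scan time of a fast-spin-echo acquisition
#'
#' The scan time of a 2D FSE acquisition is the repetition time multiplied
#' by the number of excitation shots needed to cover the phase-encode
#' lines, times the number of averages:
#' `T = TR * ceil(FoV_p / (S_p * f_acc * ETL)) * N_NEX`.
#' The ceiling reflects that a partial echo train still costs a full shot.
#'
#' @param p a [protocol_params()].
#' @return Scan time in seconds.
#' @export
scan_time <- function(p) {
  stopifnot(inherits(p, "protocol_params"))
  p$TR * ceiling(p$FoV_p / (p$S_p * p$f_acc * p$ETL)) * p$N_NEX
}

#' Largest TR fitting a scan-time budget
#'
#' Inverts [scan_time()] for TR at a fixed time budget. With
#' `apply_ceiling = FALSE` (default) the shot count
#' `FoV_p / (S_p * f_acc * ETL)` is treated as continuous, which is how the
#' widely quoted "TR <= 13.1 s at 120 s per scan" figure arises; with
#' `apply_ceiling = TRUE` the shot count is rounded up to a whole number of
#' excitations before dividing, which is what a scanner actually schedules.
#' The two conventions differ whenever the shot count is fractional.
#'
#' @param T_budget scan-time budget, seconds (> 0).
#' @param p a [protocol_params()]; its `TR` field is ignored.
#' @param apply_ceiling logical; see Details.
#' @return Maximum TR in seconds.
#' @export
max_tr <- function(T_budget, p, apply_ceiling = FALSE) {
  stopifnot(inherits(p, "protocol_params"), T_budget > 0)
  steps <- p$FoV_p / (p$S_p * p$f_acc * p$ETL)
  if (apply_ceiling) steps <- ceiling(steps)
  T_budget / (steps * p$N_NEX)
}

#' Interleaved slice acquisition order
#'
#' Even-first ascending slice order with an interleave factor of 2: all
#' even-numbered slices in ascending order, then all odd-numbered slices,
#' i.e. `[2:2:N, 1:2:N-1]` in 1-based slice numbering. Interleaving
#' separates temporally adjacent excitations spatially, reducing slice
#' cross-talk.
#'
#' @param N number of slices (>= 1).
#' @return Integer vector: a permutation of `1:N`.
#' @export
interleaved_slice_order <- function(N) {
  N <- as.integer(N)
  if (length(N) != 1 || is.na(N) || N < 1)
    stop("interleaved_slice_order: N must be a positive integer")
  evens <- if (N >= 2) seq(2L, N, by = 2L) else integer(0)
  c(evens, seq(1L, N, by = 2L))
}

#' Phase-encode budget ratio
#'
#' Ratio of total phase-encoding steps between an acquisition scheme and a
#' reference scheme; used to compare the time cost of a multi-stack
#' low-resolution protocol against one direct high-resolution acquisition.
#'
#' @param steps_lr_total total phase-encode steps of the LR scheme (> 0).
#' @param steps_hr phase-encode steps of the direct HR acquisition (> 0).
#' @return The fraction `steps_lr_total / steps_hr`.
#' @export
encode_budget_ratio <- function(steps_lr_total, steps_hr) {
  if (steps_lr_total <= 0 || steps_hr <= 0)
    stop("encode_budget_ratio: both step counts must be > 0")
  steps_lr_total / steps_hr
}

#' Direct high-resolution acquisition trade-off arithmetic
#'
#' Quantifies what acquiring directly at a small isotropic voxel costs
#' relative to a larger one: the data factor `(voxel_lr / voxel_hr)^3`
#' (more k-space samples and, equally, the per-voxel signal reduction),
#' the scan time scaled by the squared ratio of in-plane phase encodes,
#' and the number of averages needed to recover the SNR of the large-voxel
#' scan (SNR grows with the square root of averages, so the factor must be
#' squared). `n_averages` follows the conventional reporting chain -
#' the data factor rounded to one decimal, squared, truncated to an
#' integer - while `n_averages_exact` carries the unrounded arithmetic.
#'
#' @param voxel_hr target isotropic voxel size, mm (> 0).
#' @param voxel_lr reference isotropic voxel size, mm (> 0).
#' @param base_time scan time at the reference voxel size, minutes.
#' @return A list with `data_factor`, `time_factor_minutes`, `n_averages`,
#'   and `n_averages_exact`.
#' @export
hr_tradeoff <- function(voxel_hr, voxel_lr, base_time = 6) {
  if (voxel_hr <= 0 || voxel_lr <= 0)
    stop("hr_tradeoff: voxel sizes must be > 0")
  ratio <- voxel_lr / voxel_hr
  data_factor <- ratio^3
  rounded <- round(data_factor, 1)
  list(data_factor = data_factor,
       time_factor_minutes = base_time * ratio^2,
       n_averages = trunc(rounded^2),
       n_averages_exact = data_factor^2)
}
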