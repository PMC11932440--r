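#' Compute an ADC map from a DWI acquisition
#'
#' Estimates the apparent diffusion coefficient per voxel from the mean
#' exponential decay of the diffusion signal:
#' `ADC = (1/N) * sum_i [ -ln(S_i / S0bar) ] / b`
#' over the N diffusion-weighted volumes, with `S0bar` the voxelwise average
#' of the b = 0 repetitions ([average_b0()]).
#'
#' Numerical guards (all counts reported in the result's attributes):
#' * voxels with `S0bar <= 0` (no reference signal, e.g. outside the head)
#'   are set to 0 and counted in `n_zero_s0`;
#' * each `S_i` is floored at `eps * S0bar` before the log so that noise
#'   zeros cannot produce infinities;
#' * negative per-direction decays (noise pushing `S_i` above `S0bar`) are
#'   kept in the mean, but the final voxel ADC is floored at 0 — the mean
#'   decay definition is preserved while ADC stays physically non-negative;
#'   floored voxels are counted in `n_floored`.
#'
#' @param volume a [dwi_volume()].
#' @param mask optional [binary_mask()] (or logical array); voxels outside
#'   are set to 0 without computation.
#' @param eps relative signal floor (fraction of `S0bar`), default 1e-6.
#' @return An [adc_map()] in mm^2/s with attributes `n_zero_s0` and
#'   `n_floored`.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(16, 16, 8),
#'                                     lesion_radius_mm = 5,
#'                                     anisotropy_fraction = 0, noise_sigma = 0))
#' adc <- compute_adc(ph$dwi, mask = ph$truth$brain_mask)
#' @export
compute_adc <- function(volume, mask = NULL, eps = 1e-6) {
  stopifnot(inherits(volume, "dwi_volume"))
  d <- dim(volume$signal)
  n_vox <- prod(d[1:3])
  m <- if (is.null(mask)) NULL else {
    mv <- if (inherits(mask, "binary_mask")) mask$values else mask
    if (!identical(dim(mv), d[1:3]))
      stop("mask shape does not match the volume", call. = FALSE)
    as.vector(mv)
  }
  sig <- matrix(volume$signal, n_vox, d[4L])
  s0 <- rowMeans(sig[, volume$b0_indices, drop = FALSE])
  active <- if (is.null(m)) rep(TRUE, n_vox) else m
  zero_s0 <- active & s0 <= 0
  active <- active & s0 > 0

  adc <- numeric(n_vox)
  n_floored <- 0L
  if (any(active)) {
    s0a <- s0[active]
    dwa <- sig[active, volume$direction_indices, drop = FALSE]
    dwa <- pmax(dwa, eps * s0a)               # column-recycled voxelwise floor
    val <- (log(s0a) - rowMeans(log(dwa))) / volume$scheme$bvalue
    n_floored <- sum(val < 0)
    adc[active] <- pmax(val, 0)
  }
  out <- adc_map(array(adc, dim = d[1:3]), volume$voxel_size)
  attr(out, "n_zero_s0") <- sum(zero_s0)
  attr(out, "n_floored") <- n_floored
  out
}

#' Convert an ADC map to reporting units
#'
#' The package computes ADC in mm^2/s; results are conventionally reported
#' in um^2/s (e.g. a threshold of 620e-6 mm^2/s is 620 um^2/s).
#'
#' @param map an [adc_map()] (or numeric array in mm^2/s).
#' @return A numeric array in um^2/s.
#' @export
adc_to_reporting_units <- function(map) {
  v <- if (inherits(map, "adc_map")) map$values else map
  v * 1e6
}
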