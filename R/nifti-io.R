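#' 4-D diffusion-weighted volume
#'
#' Container for magnitude DWI data: a 4-D signal array, its voxel geometry
#' and the gradient scheme describing the 4th axis. The 4th axis is
#' partitioned into b = 0 volumes (`b0_indices`) and diffusion-weighted
#' volumes (`direction_indices`, aligned with `scheme$directions` row order).
#'
#' @param signal 4-D non-negative numeric array (x, y, z, volume).
#' @param voxel_size length-3 numeric, voxel edge lengths in mm.
#' @param scheme a [gradient_scheme()].
#' @param b0_indices integer indices (into the 4th axis) of the b = 0 volumes.
#' @param direction_indices integer indices of the diffusion-weighted volumes,
#'   one per scheme direction, in direction order.
#'
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(signal, voxel_size, scheme, b0_indices, direction_indices) {
  if (length(dim(signal)) != 4L)
    stop("'signal' must be a 4-D array", call. = FALSE)
  if (min(signal) < 0)
    stop("magnitude DWI signal must be non-negative", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive numbers (mm)", call. = FALSE)
  if (!inherits(scheme, "gradient_scheme"))
    stop("'scheme' must be a gradient_scheme", call. = FALSE)
  b0_indices <- as.integer(b0_indices)
  direction_indices <- as.integer(direction_indices)
  if (length(b0_indices) != scheme$n_b0)
    stop(sprintf("scheme declares %d b0 volumes but %d b0 indices were given",
                 scheme$n_b0, length(b0_indices)), call. = FALSE)
  if (length(direction_indices) != nrow(scheme$directions))
    stop(sprintf("scheme has %d directions but %d direction indices were given",
                 nrow(scheme$directions), length(direction_indices)), call. = FALSE)
  idx <- sort(c(b0_indices, direction_indices))
  if (!identical(idx, seq_len(dim(signal)[4L])))
    stop("b0_indices and direction_indices must partition the 4th axis",
         call. = FALSE)
  structure(list(signal = signal, voxel_size = voxel_size, scheme = scheme,
                 b0_indices = b0_indices, direction_indices = direction_indices),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dwi_volume> %dx%dx%d voxels (%gx%gx%g mm), %d volumes (%d b0 + %d directions)\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              d[4], length(x$b0_indices), length(x$direction_indices)))
  invisible(x)
}

#' 3-D apparent diffusion coefficient map
#'
#' @param values 3-D numeric array of ADC values in mm^2/s (the package's
#'   canonical internal unit; see [adc_to_reporting_units()] for the
#'   conventional um^2/s reporting scale).
#' @param voxel_size length-3 numeric, mm.
#' @return An object of class `adc_map`.
#' @export
adc_map <- function(values, voxel_size) {
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3-D array", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive numbers (mm)", call. = FALSE)
  structure(list(values = values, voxel_size = voxel_size), class = "adc_map")
}

#' 3-D binary mask
#'
#' @param values 3-D logical (or 0/1 numeric) array.
#' @param voxel_size length-3 numeric, mm.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, voxel_size) {
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3-D array", call. = FALSE)
  if (!is.logical(values)) {
    if (!all(values %in% c(0, 1)))
      stop("mask values must be logical or 0/1", call. = FALSE)
    values <- array(as.logical(values), dim = dim(values))
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive numbers (mm)", call. = FALSE)
  structure(list(values = values, voxel_size = voxel_size), class = "binary_mask")
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size, tolerance = 1e-8))
}

#' Read a DWI acquisition from NIfTI + FSL bvec/bval files
#'
#' Reads a 4-D NIfTI volume together with its gradient table in the FSL
#' dialect: `bvec` is a plain-text file of 3 rows by N whitespace-separated
#' columns (x, y, z components per volume) and `bval` holds N b-values.
#' Other bvec dialects (N x 3, comma-separated) are rejected, not guessed.
#'
#' Volumes with b-value below 50 s/mm^2 are treated as b = 0 (accommodating
#' vendor near-zero b-values); all remaining volumes must share a single
#' positive b-value. Direction vectors are renormalized to unit norm; a
#' deviation beyond 1e-3 triggers a warning. Zero b-vectors are only accepted
#' at b = 0 positions.
#'
#' @param nifti_path path to a 4-D `.nii`/`.nii.gz` file.
#' @param bvec_path path to the FSL bvec text file.
#' @param bval_path path to the FSL bval text file.
#' @return A [dwi_volume()].
#' @export
read_dwi <- function(nifti_path, bvec_path, bval_path) {
  img <- RNifti::readNifti(nifti_path)
  arr <- unclass(as.array(img))
  if (length(dim(arr)) != 4L)
    stop("expected a 4-D NIfTI volume, got ", length(dim(arr)), " dimensions",
         call. = FALSE)
  vox <- RNifti::pixdim(img)[1:3]
  n_vol <- dim(arr)[4L]
  bvec <- unname(as.matrix(utils::read.table(bvec_path)))
  if (nrow(bvec) != 3L)
    stop(sprintf("bvec file must have 3 rows (FSL dialect); found %d rows",
                 nrow(bvec)), call. = FALSE)
  bval <- scan(bval_path, quiet = TRUE)
  if (ncol(bvec) != n_vol || length(bval) != n_vol)
    stop(sprintf(
      "gradient table does not match image: %d volumes, %d bvec columns, %d b-values",
      n_vol, ncol(bvec), length(bval)), call. = FALSE)
  is_b0 <- bval < 50
  if (!any(is_b0)) stop("no b0 volume found (b-value < 50 s/mm^2)", call. = FALSE)
  if (all(is_b0)) stop("no diffusion-weighted volume found", call. = FALSE)
  b_dw <- unique(bval[!is_b0])
  if (length(b_dw) != 1L)
    stop("multi-shell data not supported; found b-values ",
         paste(b_dw, collapse = ", "), call. = FALSE)
  dirs <- t(bvec[, !is_b0, drop = FALSE])
  nrm <- sqrt(rowSums(dirs^2))
  if (any(nrm == 0))
    stop("zero b-vector at a diffusion-weighted position", call. = FALSE)
  if (any(abs(nrm - 1) > 1e-3))
    warning(sum(abs(nrm - 1) > 1e-3),
            " b-vector(s) deviate from unit norm by more than 1e-3; renormalizing")
  dirs <- dirs / nrm
  zero_at_b0 <- colSums(bvec[, is_b0, drop = FALSE]^2)
  if (any(zero_at_b0 > 1e-6))
    warning("nonzero b-vector at a b0 position; ignored")
  scheme <- gradient_scheme(dirs, bvalue = b_dw, n_b0 = sum(is_b0))
  dwi_volume(arr, voxel_size = vox, scheme = scheme,
             b0_indices = which(is_b0), direction_indices = which(!is_b0))
}

#' Write a DWI acquisition to NIfTI + FSL bvec/bval files
#'
#' Inverse of [read_dwi()]: the signal is stored as 32-bit float NIfTI and the
#' gradient table in the FSL 3-row dialect with zero columns at b = 0
#' positions. `read_dwi(write_dwi(v))` reproduces the scheme to 1e-6 and the
#' signal to float32 precision.
#'
#' @param volume a [dwi_volume()].
#' @param nifti_path,bvec_path,bval_path output paths.
#' @return Invisibly, a named character vector of the three paths written.
#' @export
write_dwi <- function(volume, nifti_path, bvec_path, bval_path) {
  stopifnot(inherits(volume, "dwi_volume"))
  img <- RNifti::asNifti(volume$signal)
  RNifti::pixdim(img) <- c(volume$voxel_size, 1)   # 4th dim: unit spacing
  RNifti::writeNifti(img, nifti_path, datatype = "float")
  n_vol <- dim(volume$signal)[4L]
  bvec <- matrix(0, 3L, n_vol)
  bvec[, volume$direction_indices] <- t(volume$scheme$directions)
  bval <- numeric(n_vol)
  bval[volume$direction_indices] <- volume$scheme$bvalue
  writeLines(apply(bvec, 1L, function(r) paste(sprintf("%.10f", r), collapse = " ")),
             bvec_path)
  writeLines(paste(sprintf("%g", bval), collapse = " "), bval_path)
  invisible(c(nifti = nifti_path, bvec = bvec_path, bval = bval_path))
}

#' Read / write a binary mask as uint8 NIfTI
#'
#' @param path path to a 3-D NIfTI file; nonzero voxels are TRUE.
#' @return [read_mask()] returns a [binary_mask()].
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- unclass(as.array(img))
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D NIfTI mask", call. = FALSE)
  binary_mask(array(arr != 0, dim = dim(arr)), RNifti::pixdim(img)[1:3])
}

#' @rdname read_mask
#' @param mask a [binary_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$values), dim = dim(mask$values)))
  RNifti::pixdim(img) <- mask$voxel_size
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Average the b = 0 volumes of a DWI acquisition
#'
#' Voxelwise arithmetic mean over the b = 0 repetitions, the reference signal
#' against which diffusion attenuation is measured.
#'
#' @param volume a [dwi_volume()].
#' @return A 3-D array with the volume's spatial shape.
#' @export
average_b0 <- function(volume) {
  stopifnot(inherits(volume, "dwi_volume"))
  d <- dim(volume$signal)
  m <- matrix(volume$signal, prod(d[1:3]), d[4L])
  array(rowMeans(m[, volume$b0_indices, drop = FALSE]), dim = d[1:3])
}
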