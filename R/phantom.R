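#' DEFUSE ischemic-core ADC threshold
#'
#' Single ADC threshold (mm^2/s) below which white-matter tissue is counted
#' as ischemic core. Stored once, in the package's canonical mm^2/s unit
#' (620e-6 mm^2/s, i.e. 620 um^2/s).
#' @export
defuse_threshold <- 620e-6

#' Specification of one synthetic DWI subject
#'
#' A `phantom_spec` fully describes one synthetic subject: a multi-tissue
#' ellipsoidal head (CSF shell, grey-matter shell, white-matter core) with an
#' embedded ischemic lesion, a monoexponential (or tensor) diffusion signal
#' model and Rician magnitude noise. All ADC values are in mm^2/s.
#'
#' Tissue layout: the brain is the ellipsoid inscribed in 95% of the grid
#' extent; normalized ellipsoidal radius > 0.92 is CSF, 0.82--0.92 grey
#' matter, and <= 0.82 white matter. A fraction `anisotropy_fraction` of
#' non-lesion WM voxels carries a diffusion tensor with eigenvalues
#' `tensor_eigenvalues` in a per-voxel random orientation; the rest are
#' isotropic with ADC drawn from N(`wm_adc_mean`, `wm_adc_sd`) truncated at 0.
#'
#' @param grid_shape integer length-3 grid dimensions (default 64 x 64 x 24).
#' @param voxel_size mm, default `c(1.6, 1.6, 3)` (the clinical stroke DWI
#'   resolution).
#' @param wm_adc_mean,wm_adc_sd isotropic WM ADC marginal, mm^2/s. The
#'   defaults (865e-6, 262e-6) follow the white-matter ADC distribution
#'   observed with high-angular-resolution protocols.
#' @param wm_adc_skew skewness of the WM ADC marginal. The default 3.8 gives
#'   the strongly right-skewed, heavy-tailed distribution seen in clinical
#'   white matter (long tail toward partial-volume CSF, a tight left flank
#'   with a small mass near the ischemia threshold — the feature that makes
#'   threshold segmentation protocol-sensitive). Realized as a shifted
#'   lognormal matched to mean/SD/skewness; 0 means Gaussian.
#' @param gm_adc_mean,csf_adc_mean grey matter / CSF mean ADC, mm^2/s (each
#'   drawn per voxel with 10% relative SD, truncated at 0).
#' @param lesion_center voxel coordinates (1-based) of the lesion center;
#'   `NULL` places it at the WM centroid.
#' @param lesion_radius_mm lesion sphere radius in mm (ignored for
#'   `lesion_shape = "box"`).
#' @param lesion_shape `"sphere"` (default) or `"box"` (axis-aligned, for
#'   partial-volume-free recovery checks).
#' @param lesion_halfwidth_mm length-3 half-widths in mm for box lesions.
#' @param lesion_adc_mean,lesion_adc_sd lesion ADC distribution (truncated
#'   normal above 0), mm^2/s; the mean must lie below the DEFUSE threshold.
#' @param anisotropy_fraction share of non-lesion WM voxels given a tensor.
#' @param tensor_eigenvalues length-3 tensor eigenvalues, mm^2/s.
#' @param fiber_coherence_mm correlation length (mm) of the fiber orientation
#'   field and of the anisotropic-region geometry. White-matter tracts are
#'   spatially coherent: neighbouring voxels share a fiber direction. This is
#'   what lets direction-dependent ADC errors form connected clusters rather
#'   than isolated voxels (which morphological cleanup would simply remove).
#'   Set to 0 for independent per-voxel orientations.
#' @param adc_texture_mm correlation length (mm) of the tissue diffusivity
#'   texture. Per-voxel tissue ADC varies around the class mean as a smooth
#'   random field with the class SD as marginal spread: tissue diffusivity is
#'   a slowly varying material property, while voxelwise-independent
#'   fluctuation is measurement noise and is modelled separately through
#'   `noise_sigma`. Set to 0 for independent per-voxel draws.
#' @param s0_mean non-diffusion-weighted signal amplitude (arbitrary units).
#' @param noise_sigma Rician noise sigma in signal units (0 = noise-free);
#'   the default 50 with `s0_mean = 1000` gives SNR 20 at b = 0.
#' @param seed integer seed; the phantom draw is fully reproducible.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 24L),
                         voxel_size = c(1.6, 1.6, 3),
                         wm_adc_mean = 865e-6, wm_adc_sd = 262e-6,
                         wm_adc_skew = 3.8,
                         gm_adc_mean = 950e-6, csf_adc_mean = 3000e-6,
                         lesion_center = NULL, lesion_radius_mm = 12,
                         lesion_shape = c("sphere", "box"),
                         lesion_halfwidth_mm = c(8, 8, 6),
                         lesion_adc_mean = 450e-6, lesion_adc_sd = 80e-6,
                         anisotropy_fraction = 0.5,
                         tensor_eigenvalues = c(1700e-6, 300e-6, 300e-6),
                         fiber_coherence_mm = 10, adc_texture_mm = 6,
                         s0_mean = 1000, noise_sigma = 50, seed = 1L) {
  lesion_shape <- match.arg(lesion_shape)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L),
            length(voxel_size) == 3L, all(voxel_size > 0))
  if (is.null(lesion_center)) lesion_center <- round(grid_shape / 2)
  adcs <- c(wm_adc_mean, gm_adc_mean, csf_adc_mean, lesion_adc_mean)
  if (any(adcs <= 0)) stop("all tissue ADC means must be positive", call. = FALSE)
  if (!(lesion_adc_mean < defuse_threshold && defuse_threshold < wm_adc_mean))
    stop(sprintf(
      "lesion_adc_mean (%g) must lie below and wm_adc_mean (%g) above the DEFUSE threshold (%g mm^2/s)",
      lesion_adc_mean, wm_adc_mean, defuse_threshold), call. = FALSE)
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0", call. = FALSE)
  if (anisotropy_fraction < 0 || anisotropy_fraction > 1)
    stop("'anisotropy_fraction' must be in [0, 1]", call. = FALSE)
  stopifnot(length(tensor_eigenvalues) == 3L, all(tensor_eigenvalues > 0))
  if (wm_adc_skew < 0) stop("'wm_adc_skew' must be >= 0", call. = FALSE)
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 wm_adc_mean = wm_adc_mean, wm_adc_sd = wm_adc_sd,
                 wm_adc_skew = wm_adc_skew,
                 gm_adc_mean = gm_adc_mean, csf_adc_mean = csf_adc_mean,
                 lesion_center = as.numeric(lesion_center),
                 lesion_radius_mm = lesion_radius_mm,
                 lesion_shape = lesion_shape,
                 lesion_halfwidth_mm = as.numeric(lesion_halfwidth_mm),
                 lesion_adc_mean = lesion_adc_mean, lesion_adc_sd = lesion_adc_sd,
                 anisotropy_fraction = anisotropy_fraction,
                 tensor_eigenvalues = as.numeric(tensor_eigenvalues),
                 fiber_coherence_mm = fiber_coherence_mm,
                 adc_texture_mm = adc_texture_mm,
                 s0_mean = s0_mean, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Shifted-lognormal parameters (offset, meanlog, sdlog) matching a target
# mean, SD and skewness; skewness fixes e^(sdlog^2) through the standard
# moment identity skew = (w + 2) sqrt(w - 1).
shifted_lognormal_params <- function(mean, sd, skew) {
  w <- stats::uniroot(function(w) (w + 2) * sqrt(w - 1) - skew,
                      c(1 + 1e-12, 100), tol = 1e-14)$root
  sdlog <- sqrt(log(w))
  m_ln <- sd / sqrt(w - 1)                   # mean of the lognormal part
  list(offset = mean - m_ln, meanlog = log(m_ln) - sdlog^2 / 2, sdlog = sdlog)
}

# voxel-center coordinates (mm) for a grid, per axis
axis_coords <- function(grid_shape, voxel_size)
  lapply(1:3, function(k) (seq_len(grid_shape[k]) - 0.5) * voxel_size[k])

# separable box smoothing of a 3-D numeric array (sum over a
# (2h1+1) x (2h2+1) x (2h3+1) window, zero padding); h in voxels per axis
smooth_box3d <- function(a, h) {
  for (k in 1:3) {
    if (h[k] < 1L) next
    off <- c(0L, 0L, 0L)
    acc <- a
    for (o in seq_len(h[k])) {
      off[k] <- o;  acc <- acc + shift_integer(a, off)
      off[k] <- -o; acc <- acc + shift_integer(a, off)
    }
    a <- acc
  }
  a
}

# smooth random unit-vector field over n selected voxels of a grid:
# three iid Gaussian fields, box-smoothed to the requested coherence
# length, evaluated at `sel` (logical array) and normalized
smooth_orientation_field <- function(grid_shape, sel, h) {
  v <- sapply(1:3, function(k) {
    f <- array(stats::rnorm(prod(grid_shape)), dim = grid_shape)
    smooth_box3d(f, h)[sel]
  })
  v <- matrix(v, ncol = 3L)
  n <- sqrt(rowSums(v^2))
  n[n == 0] <- 1
  v / n
}

#' Generate one synthetic DWI subject
#'
#' Draws a phantom subject from a [phantom_spec()]: builds the tissue and
#' lesion geometry, assigns per-voxel diffusivities, synthesizes the
#' monoexponential diffusion signal `S_i = S0 exp(-b g_i' D g_i)` for every
#' encoding direction of `scheme` plus the b = 0 repetitions, and corrupts
#' all volumes with Rician noise (`|S + sigma (Z1 + i Z2)|`).
#'
#' @param spec a [phantom_spec()].
#' @param scheme acquisition [gradient_scheme()]; default is the 20-direction,
#'   b = 1000 s/mm^2, 10-b0 reference protocol.
#' @return A list with elements `dwi` (a [dwi_volume()]) and `truth`, a
#'   `phantom_truth` list holding `lesion_mask`, `wm_mask`, `brain_mask`
#'   (all [binary_mask()]), `true_adc` (an [adc_map()] of orientation-averaged
#'   diffusivity) and `true_lesion_volume_ml`.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(16, 16, 8),
#'                                     lesion_radius_mm = 5, seed = 7))
#' ph$truth$true_lesion_volume_ml
#' @export
generate_phantom <- function(spec, scheme = make_reference_scheme(20L)) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(scheme, "gradient_scheme"))
  gs <- spec$grid_shape; vx <- spec$voxel_size
  co <- axis_coords(gs, vx)
  ext <- gs * vx
  ctr <- ext / 2
  semi <- 0.95 * ext / 2
  # normalized ellipsoidal radius of every voxel center
  r2 <- outer(outer(((co[[1]] - ctr[1]) / semi[1])^2,
                    ((co[[2]] - ctr[2]) / semi[2])^2, `+`),
              ((co[[3]] - ctr[3]) / semi[3])^2, `+`)
  rho <- sqrt(r2)
  brain <- rho <= 1
  wm <- rho <= 0.82
  gm <- rho > 0.82 & rho <= 0.92
  csf <- rho > 0.92 & brain

  lc_mm <- (spec$lesion_center - 0.5) * vx
  if (spec$lesion_shape == "sphere") {
    r <- spec$lesion_radius_mm
    if (any(lc_mm - r < 0) || any(lc_mm + r > ext))
      stop("lesion sphere exceeds the grid", call. = FALSE)
    d2 <- outer(outer((co[[1]] - lc_mm[1])^2, (co[[2]] - lc_mm[2])^2, `+`),
                (co[[3]] - lc_mm[3])^2, `+`)
    lesion <- d2 <= r^2
  } else {
    hw <- spec$lesion_halfwidth_mm
    if (any(lc_mm - hw < 0) || any(lc_mm + hw > ext))
      stop("lesion box exceeds the grid", call. = FALSE)
    inax <- lapply(1:3, function(k) abs(co[[k]] - lc_mm[k]) <= hw[k])
    lesion <- outer(outer(inax[[1]], inax[[2]], `&`), inax[[3]], `&`)
  }
  lesion <- lesion & wm   # the study's core criterion only looks inside WM

  n_vox <- prod(gs)
  n_dir <- nrow(scheme$directions)
  n_vol <- scheme$n_b0 + n_dir
  out <- with_local_seed(spec$seed, {
    # tissue diffusivity texture: one smooth unit-variance field, scaled by
    # the per-class SD around the per-class mean (floored just above 0)
    ht <- pmax(0L, as.integer(round(spec$adc_texture_mm / (2 * vx))))
    tex <- smooth_box3d(array(stats::rnorm(n_vox), dim = gs), ht)
    tex <- tex / stats::sd(tex)
    mean_map <- sd_map <- numeric(n_vox)
    mean_map[csf] <- spec$csf_adc_mean; sd_map[csf] <- 0.1 * spec$csf_adc_mean
    mean_map[gm] <- spec$gm_adc_mean; sd_map[gm] <- 0.1 * spec$gm_adc_mean
    mean_map[wm] <- spec$wm_adc_mean; sd_map[wm] <- spec$wm_adc_sd
    mean_map[lesion] <- spec$lesion_adc_mean; sd_map[lesion] <- spec$lesion_adc_sd
    adc <- pmax(mean_map + sd_map * as.vector(tex), 1e-8)
    if (spec$wm_adc_skew > 0) {
      # right-skewed heavy-tailed WM marginal: shifted lognormal through the
      # same smooth texture field (lesion voxels keep their Gaussian marginal)
      wm_only <- wm & !lesion
      p <- shifted_lognormal_params(spec$wm_adc_mean, spec$wm_adc_sd,
                                    spec$wm_adc_skew)
      adc[wm_only] <- pmax(p$offset +
                             exp(p$meanlog + p$sdlog * tex[wm_only]), 1e-8)
    }
    adc[!brain] <- 0

    # anisotropic WM: spatially coherent patches with a smoothly varying
    # fiber orientation (tract-like), not iid voxels -- coherence is what
    # allows direction-dependent ADC errors to survive morphological cleanup
    h_vox <- pmax(0L, as.integer(round(spec$fiber_coherence_mm / (2 * vx))))
    if (spec$anisotropy_fraction >= 1) {
      aniso <- wm & !lesion
    } else if (spec$anisotropy_fraction <= 0) {
      aniso <- array(FALSE, dim = gs)
    } else {
      field <- smooth_box3d(array(stats::rnorm(n_vox), dim = gs), h_vox)
      cut <- stats::quantile(field[wm & !lesion], 1 - spec$anisotropy_fraction,
                             names = FALSE)
      aniso <- wm & !lesion & field > cut
    }
    n_a <- sum(aniso)
    ev <- spec$tensor_eigenvalues
    if (n_a > 0L) {
      # coherent orthonormal tensor frame (e1, e2, e3) per anisotropic voxel
      e1 <- smooth_orientation_field(gs, aniso, h_vox)
      h2 <- smooth_orientation_field(gs, aniso, h_vox)
      e2 <- h2 - e1 * rowSums(h2 * e1)
      nrm2 <- sqrt(rowSums(e2^2)); nrm2[nrm2 == 0] <- 1
      e2 <- e2 / nrm2
      e3 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                  e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                  e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
      adc[aniso] <- mean(ev)  # orientation-averaged diffusivity = trace/3
    }

    s0 <- numeric(n_vox)
    s0[brain] <- spec$s0_mean
    sig <- matrix(0, n_vox, n_vol)
    b0_idx <- seq_len(scheme$n_b0)
    dir_idx <- scheme$n_b0 + seq_len(n_dir)
    sig[, b0_idx] <- s0
    iso_att <- exp(-scheme$bvalue * adc) * s0
    for (i in seq_len(n_dir)) {
      g <- scheme$directions[i, ]
      col <- iso_att
      if (n_a > 0L) {
        c1 <- e1 %*% g; c2 <- e2 %*% g; c3 <- e3 %*% g
        adc_dir <- ev[1] * c1^2 + ev[2] * c2^2 + ev[3] * c3^2
        col[aniso] <- spec$s0_mean * exp(-scheme$bvalue * adc_dir)
      }
      sig[, dir_idx[i]] <- col
    }
    if (spec$noise_sigma > 0) {
      # Rician magnitude noise |S + sigma (Z1 + i Z2)|, drawn inside the
      # head only: air voxels stay exactly zero (all downstream analyses
      # are mask-restricted, so the air noise floor is never used)
      hb <- which(as.vector(brain))
      n_h <- length(hb) * n_vol
      sb <- sig[hb, , drop = FALSE]
      sig[hb, ] <- sqrt((sb + spec$noise_sigma * stats::rnorm(n_h))^2 +
                        (spec$noise_sigma * stats::rnorm(n_h))^2)
    }
    list(adc = adc, sig = sig, b0_idx = b0_idx, dir_idx = dir_idx)
  })

  dwi <- dwi_volume(array(out$sig, dim = c(gs, n_vol)), voxel_size = vx,
                    scheme = scheme, b0_indices = out$b0_idx,
                    direction_indices = out$dir_idx)
  vox_ml <- prod(vx) / 1000
  truth <- structure(list(
    lesion_mask = binary_mask(array(lesion, dim = gs), vx),
    wm_mask = binary_mask(array(wm, dim = gs), vx),
    brain_mask = binary_mask(array(brain, dim = gs), vx),
    true_adc = adc_map(array(out$adc, dim = gs), vx),
    true_lesion_volume_ml = sum(lesion) * vox_ml), class = "phantom_truth")
  list(dwi = dwi, truth = truth)
}

#' Serialize / parse a phantom specification as plain text
#'
#' Writes a `phantom_spec` as `key = value` lines (vectors comma-separated)
#' so that phantom draws can be reproduced outside R sessions.
#'
#' @param spec a [phantom_spec()].
#' @param path output text file.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  lines <- vapply(names(spec), function(nm) {
    v <- spec[[nm]]
    val <- if (is.character(v)) v else paste(format(v, digits = 17), collapse = ",")
    paste0(nm, " = ", val)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  args <- stats::setNames(lapply(kv, function(p) {
    parts <- strsplit(p[2], ",")[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (anyNA(num)) trimws(parts) else num
  }), vapply(kv, `[[`, character(1), 1L))
  do.call(phantom_spec, args)
}
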