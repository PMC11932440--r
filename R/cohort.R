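#' Synthetic clinical record
#'
#' Stroke-severity scores generated as monotone noisy functions of the true
#' lesion volume: an admission NIHSS-like score (integer 0-42), a 24-hour
#' NIHSS-like score, a 3-month mRS-like score (ordinal 0-6), and an
#' intervention label.
#'
#' @param nihss_admission,nihss_24h integers in 0-42 (NA allowed for
#'   missingness).
#' @param mrs_3m integer in 0-6 or NA.
#' @param intervention one of `"EVT"`, `"r-tPA"`, `"Bridging"`, `"none"`.
#' @return An object of class `clinical_record`.
#' @export
clinical_record <- function(nihss_admission, nihss_24h, mrs_3m, intervention) {
  chk <- function(x, lo, hi, nm) {
    if (!is.na(x) && (x < lo || x > hi || x != round(x)))
      stop(sprintf("'%s' must be an integer in [%d, %d] or NA", nm, lo, hi),
           call. = FALSE)
    if (is.na(x)) NA_integer_ else as.integer(x)
  }
  intervention <- match.arg(intervention, c("EVT", "r-tPA", "Bridging", "none"))
  structure(list(nihss_admission = chk(nihss_admission, 0L, 42L, "nihss_admission"),
                 nihss_24h = chk(nihss_24h, 0L, 42L, "nihss_24h"),
                 mrs_3m = chk(mrs_3m, 0L, 6L, "mrs_3m"),
                 intervention = intervention),
            class = "clinical_record")
}

#' Default cohort generating distribution
#'
#' Parameters of the cohort generator: the phantom template shared by all
#' subjects, the right-skewed lesion-volume distribution (log-normal, clipped
#' to `[0, vol_max_ml]`, matching the heavy right tail of clinical core
#' volumes), the monotone score models
#' `score = clip(round(alpha * log1p(V_ml) + N(0, sigma)), range)`, per-score
#' missingness probabilities, and intervention label proportions.
#'
#' `vol_max_ml = NULL` caps volumes at 90% of the phantom's maximal inscribed
#' lesion. Pass `base = list(grid_shape = ..., ...)` to override any
#' [phantom_spec()] argument. The cohort default grid is 32 x 32 x 16 — a
#' deliberately desk-scale head that makes multi-hundred-subject simulated
#' cohorts tractable on one CPU; lesion volumes (and the volume cap) scale
#' down with it, while the protocol-degradation mechanisms under study are
#' scale-free. Use `base = list(grid_shape = c(64L, 64L, 24L))` for
#' full-geometry subjects.
#'
#' @param base named list of [phantom_spec()] overrides applied to every
#'   subject.
#' @param vol_meanlog,vol_sdlog log-normal parameters of the true lesion
#'   volume in mL. The default `vol_meanlog = NULL` scales the clinical
#'   median (about 3 mL of core in roughly 480 mL of white matter) to the
#'   phantom's actual white-matter volume, so that lesion size relative to
#'   white matter — the ratio that governs how much protocol-driven spurious
#'   volume matters — is grid-independent.
#' @param vol_max_ml upper clip for true lesion volume, mL (NULL = grid-derived).
#' @param alpha_nihss_adm,alpha_nihss_24h,alpha_mrs slopes on `log1p(V_ml)`.
#' @param sigma_nihss_adm,sigma_nihss_24h,sigma_mrs Gaussian score noise SD.
#' @param miss_prob named numeric: missingness probability per score.
#' @param intervention_probs named numeric summing to 1.
#' @return A list of class `cohort_distribution`.
#' @export
cohort_distribution <- function(base = list(grid_shape = c(32L, 32L, 16L)),
                                vol_meanlog = NULL, vol_sdlog = 1.1,
                                vol_max_ml = NULL,
                                alpha_nihss_adm = 6, sigma_nihss_adm = 3,
                                alpha_nihss_24h = 5.5, sigma_nihss_24h = 3,
                                alpha_mrs = 1.1, sigma_mrs = 0.9,
                                miss_prob = c(nihss_admission = 0,
                                              nihss_24h = 0.02, mrs_3m = 0.05),
                                intervention_probs = c(EVT = 0.14, `r-tPA` = 0.27,
                                                       Bridging = 0.13, none = 0.46)) {
  stopifnot(abs(sum(intervention_probs) - 1) < 1e-8)
  structure(list(base = base, vol_meanlog = vol_meanlog, vol_sdlog = vol_sdlog,
                 vol_max_ml = vol_max_ml,
                 alpha_nihss_adm = alpha_nihss_adm, sigma_nihss_adm = sigma_nihss_adm,
                 alpha_nihss_24h = alpha_nihss_24h, sigma_nihss_24h = sigma_nihss_24h,
                 alpha_mrs = alpha_mrs, sigma_mrs = sigma_mrs,
                 miss_prob = miss_prob, intervention_probs = intervention_probs),
            class = "cohort_distribution")
}

clip_round <- function(x, lo, hi) pmin(hi, pmax(lo, round(x)))

#' Generate a synthetic subject cohort
#'
#' Draws `n_subjects` phantom subjects with lesion volumes from the
#' distribution in `dist`, plus clinical scores monotonically (but noisily)
#' linked to the true lesion volume. Everything is reproducible from `seed`.
#'
#' @param n_subjects number of subjects, >= 1.
#' @param dist a [cohort_distribution()].
#' @param seed integer seed.
#' @param scheme acquisition [gradient_scheme()] shared by all subjects.
#' @param keep_dwi if `FALSE`, drop each subject's DWI array after generation
#'   (manifest-only cohorts for score-model studies).
#' @return A list of class `cohort`: `subjects` (list of
#'   `list(dwi, truth, clinical)`) and `manifest`, a data.frame with one row
#'   per subject (id, true volume mL, scores, intervention).
#' @export
generate_cohort <- function(n_subjects, dist = cohort_distribution(), seed = 1L,
                            scheme = make_reference_scheme(20L),
                            keep_dwi = TRUE) {
  stopifnot(n_subjects >= 1L, inherits(dist, "cohort_distribution"))
  base_spec <- do.call(phantom_spec, dist$base)
  ext <- base_spec$grid_shape * base_spec$voxel_size
  ctr_vox <- round(base_spec$grid_shape / 2)
  r_max <- 0.9 * min(0.82 * 0.95 * ext / 2)   # stay inside the WM ellipsoid
  v_cap <- 4 / 3 * pi * r_max^3 / 1000
  vol_max <- if (is.null(dist$vol_max_ml)) v_cap else min(dist$vol_max_ml, v_cap)
  vol_meanlog <- dist$vol_meanlog
  if (is.null(vol_meanlog)) {
    # scale the clinical median core (~3 mL per ~480 mL of white matter) to
    # this phantom's white-matter volume
    wm_ml <- 4 / 3 * pi * prod(0.82 * 0.95 * ext / 2) / 1000
    vol_meanlog <- log(3 * wm_ml / 480)
  }

  draws <- with_local_seed(seed, {
    v <- pmin(stats::rlnorm(n_subjects, vol_meanlog, dist$vol_sdlog), vol_max)
    list(v = v,
         sub_seeds = sample.int(.Machine$integer.max - 1L, n_subjects),
         e_adm = stats::rnorm(n_subjects, 0, dist$sigma_nihss_adm),
         e_24h = stats::rnorm(n_subjects, 0, dist$sigma_nihss_24h),
         e_mrs = stats::rnorm(n_subjects, 0, dist$sigma_mrs),
         interv = sample(names(dist$intervention_probs), n_subjects,
                         replace = TRUE, prob = dist$intervention_probs),
         miss = matrix(stats::runif(3L * n_subjects), n_subjects, 3L))
  })

  subjects <- vector("list", n_subjects)
  true_v <- numeric(n_subjects)
  for (i in seq_len(n_subjects)) {
    r_mm <- (3 * draws$v[i] * 1000 / (4 * pi))^(1 / 3)
    sp <- base_spec
    sp$lesion_center <- as.numeric(ctr_vox)
    sp$lesion_radius_mm <- r_mm
    sp$seed <- draws$sub_seeds[i]
    ph <- generate_phantom(sp, scheme = scheme)
    true_v[i] <- ph$truth$true_lesion_volume_ml
    if (!keep_dwi) ph$dwi <- NULL
    subjects[[i]] <- ph
  }

  lv <- log1p(true_v)
  adm <- clip_round(dist$alpha_nihss_adm * lv + draws$e_adm, 0, 42)
  h24 <- clip_round(dist$alpha_nihss_24h * lv + draws$e_24h, 0, 42)
  mrs <- clip_round(dist$alpha_mrs * lv + draws$e_mrs, 0, 6)
  adm[draws$miss[, 1] < dist$miss_prob[["nihss_admission"]]] <- NA
  h24[draws$miss[, 2] < dist$miss_prob[["nihss_24h"]]] <- NA
  mrs[draws$miss[, 3] < dist$miss_prob[["mrs_3m"]]] <- NA

  for (i in seq_len(n_subjects))
    subjects[[i]]$clinical <- clinical_record(adm[i], h24[i], mrs[i],
                                              draws$interv[i])
  manifest <- data.frame(subject = seq_len(n_subjects),
                         true_volume_ml = true_v,
                         nihss_admission = adm, nihss_24h = h24, mrs_3m = mrs,
                         intervention = draws$interv,
                         stringsAsFactors = FALSE)
  structure(list(subjects = subjects, manifest = manifest), class = "cohort")
}

#' Write the cohort manifest as CSV
#'
#' @param cohort a [generate_cohort()] result.
#' @param path output CSV path.
#' @export
write_cohort_manifest <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  utils::write.csv(cohort$manifest, path, row.names = FALSE)
  invisible(path)
}
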