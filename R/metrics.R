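#' Jaccard overlap between two binary masks
#'
#' Intersection over union of the foreground voxels. When both masks are
#' empty the convention here is perfect agreement (1): two protocols that
#' both detect no core agree completely. Set `empty_value` to change this
#' (e.g. `NA` to flag the case instead).
#'
#' @param a,b [binary_mask()] objects (or logical arrays) with identical
#'   geometry.
#' @param empty_value value returned when both masks are empty (default 1).
#' @return A scalar in `[0, 1]` (or `empty_value`).
#' @export
jaccard <- function(a, b, empty_value = 1) {
  av <- if (inherits(a, "binary_mask")) a$values else a
  bv <- if (inherits(b, "binary_mask")) b$values else b
  if (!identical(dim(av), dim(bv)))
    stop("masks must share geometry", call. = FALSE)
  if (inherits(a, "binary_mask") && inherits(b, "binary_mask") &&
      !isTRUE(all.equal(a$voxel_size, b$voxel_size, tolerance = 1e-8)))
    stop("masks must share voxel size", call. = FALSE)
  uni <- sum(av | bv)
  if (uni == 0L) return(empty_value)
  sum(av & bv) / uni
}

#' Summary statistics of a set of Jaccard values
#'
#' Median, interquartile range, minimum and maximum, with quartiles by
#' linear interpolation between order statistics (the standard type-7
#' quantile definition).
#'
#' @param values nonempty numeric vector.
#' @return A list with `median`, `iqr_low`, `iqr_high`, `min`, `max`, `n`.
#' @export
jaccard_summary <- function(values) {
  if (length(values) == 0L) stop("'values' must be nonempty", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], iqr_low = q[1], iqr_high = q[3],
       min = min(values), max = max(values), n = length(values))
}

#' Nonparametric Bland-Altman agreement analysis
#'
#' Paired-difference agreement between a reference and an alternative
#' measurement. Differences are `v_alt - v_ref` (alternative minus
#' reference, so a positive bias means the alternative overestimates); the
#' 95% range of agreement is the empirical 2.5th/97.5th percentile of the
#' differences (nonparametric — no normality assumption), with linear
#' interpolation between order statistics.
#'
#' @param v_ref,v_alt paired numeric vectors (mL), length >= 3.
#' @return An object of class `agreement_report`: `bias` (mean difference),
#'   `loa_low`, `loa_high`, and `per_subject_differences`.
#' @export
bland_altman <- function(v_ref, v_alt) {
  if (length(v_ref) != length(v_alt))
    stop(sprintf("paired vectors differ in length (%d vs %d)",
                 length(v_ref), length(v_alt)), call. = FALSE)
  if (length(v_ref) < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- v_alt - v_ref
  loa <- stats::quantile(d, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(bias = mean(d), loa_low = loa[1], loa_high = loa[2],
                 per_subject_differences = d),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> bias %.3f mL, 95%% range of agreement [%.3f, %.3f] mL (n = %d)\n",
              x$bias, x$loa_low, x$loa_high, length(x$per_subject_differences)))
  invisible(x)
}

#' Moments of the white-matter ADC distribution
#'
#' Mean, SD, skewness and kurtosis of the ADC values inside a white-matter
#' mask, reported in um^2/s. Skewness is the third standardized sample
#' moment g1 and kurtosis is Fisher excess g2 (normal = 0); for a constant
#' distribution both are reported as 0 with the `degenerate` flag set.
#'
#' @param adc an [adc_map()] in mm^2/s.
#' @param wm_mask a [binary_mask()] with at least 2 foreground voxels.
#' @param excess if `FALSE`, report Pearson kurtosis (g2 + 3) instead.
#' @return An object of class `distribution_moments`: `mean`, `sd`,
#'   `skewness`, `kurtosis` (um^2/s for the first two), `n_voxels`,
#'   `degenerate`.
#' @export
wm_adc_moments <- function(adc, wm_mask, excess = TRUE) {
  stopifnot(inherits(adc, "adc_map"), inherits(wm_mask, "binary_mask"))
  if (!same_geometry(adc, wm_mask))
    stop("ADC map and WM mask must share geometry", call. = FALSE)
  x <- adc$values[wm_mask$values] * 1e6
  if (length(x) < 2L) stop("need at least 2 WM voxels", call. = FALSE)
  s <- stats::sd(x)
  degenerate <- s == 0
  structure(list(
    mean = mean(x), sd = s,
    skewness = if (degenerate) 0 else e1071::skewness(x, type = 1),
    kurtosis = if (degenerate) 0 else
      e1071::kurtosis(x, type = 1) + if (excess) 0 else 3,
    n_voxels = length(x), degenerate = degenerate),
    class = "distribution_moments")
}

# exact two-sided signed-rank p by enumerating all sign assignments of the
# (average-)ranked absolute differences; valid with ties, used for small n
exact_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  total <- sum(r)
  subsets <- 0:(2^n - 1)
  bits <- vapply(seq_len(n) - 1L, function(b) bitwAnd(subsets, bitwShiftL(1L, b)) > 0L,
                 logical(length(subsets)))
  v_all <- as.vector(bits %*% r)
  p_le <- mean(v_all <= v_obs + 1e-12)
  p_ge <- mean(v_all >= v_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

#' Paired protocol comparison of ADC distribution moments
#'
#' Two-sided Wilcoxon signed-rank tests comparing, across subjects, each
#' moment (mean, SD, kurtosis, skewness) of the white-matter ADC
#' distribution between two protocols. Zero-difference pairs are dropped
#' (the signed-rank convention); if all pairs are zero for a moment the row
#' is flagged degenerate with `p = NA`. For 14 or fewer effective pairs the
#' p-value is computed by exact enumeration of sign assignments (valid in
#' the presence of tied differences); larger samples use the standard
#' normal approximation.
#'
#' @param per_subject_a,per_subject_b equal-length lists (>= 6 subjects) of
#'   [wm_adc_moments()] results, paired by subject.
#' @return A data.frame with one row per moment: `moment`, `statistic`
#'   (the signed-rank V of a vs b), `p_value`, `n_effective`, `degenerate`.
#' @export
paired_moment_test <- function(per_subject_a, per_subject_b) {
  if (length(per_subject_a) != length(per_subject_b))
    stop("paired lists differ in length", call. = FALSE)
  if (length(per_subject_a) < 6L)
    stop("need at least 6 paired subjects", call. = FALSE)
  moments <- c("mean", "sd", "kurtosis", "skewness")
  rows <- lapply(moments, function(mm) {
    a <- vapply(per_subject_a, `[[`, numeric(1), mm)
    b <- vapply(per_subject_b, `[[`, numeric(1), mm)
    nz <- a != b
    if (!any(nz))
      return(data.frame(moment = mm, statistic = NA_real_, p_value = NA_real_,
                        n_effective = 0L, degenerate = TRUE))
    d <- (a - b)[nz]
    v_stat <- sum(rank(abs(d))[d > 0])
    p <- if (sum(nz) <= 14L) exact_signed_rank_p(d) else
      suppressWarnings(stats::wilcox.test(a[nz], b[nz], paired = TRUE))$p.value
    data.frame(moment = mm, statistic = v_stat, p_value = p,
               n_effective = sum(nz), degenerate = FALSE)
  })
  do.call(rbind, rows)
}
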