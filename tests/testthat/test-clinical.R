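test_that("spearman_with_ci matches rank-formula oracles and handles ties", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8)
  s <- c(2, 4, 4, 7, 9, 12, 15, 20)                 # one tie, monotone
  a <- spearman_with_ci(v, s)
  expect_equal(a$rho, oracle_spearman(v, s), tolerance = 1e-12)
  expect_equal(a$n, 8L)
  expect_true(a$ci_low <= a$rho && a$rho <= a$ci_high)
  expect_true(a$ci_low >= -1 && a$ci_high <= 1)

  # strictly increasing scores: rho = 1
  mono <- spearman_with_ci(1:10, (1:10)^2)
  expect_equal(mono$rho, 1)
  expect_equal(mono$ci_high, 1)

  # complete-case handling
  s_na <- s; s_na[3] <- NA
  a2 <- spearman_with_ci(v, s_na)
  expect_equal(a2$n, 7L); expect_equal(a2$n_dropped, 1L)
  expect_equal(a2$rho, oracle_spearman(v[-3], s[-3]), tolerance = 1e-12)

  # constant scores: degenerate
  cons <- spearman_with_ci(1:10, rep(3, 10))
  expect_true(cons$degenerate); expect_true(is.na(cons$rho))
  expect_error(spearman_with_ci(1:4, 1:4), "at least 5")
})

test_that("independent scores give near-zero rho with covering CI", {
  set.seed(12)
  v <- runif(1000); s <- runif(1000)
  a <- spearman_with_ci(v, s)
  expect_lt(abs(a$rho), 0.08)
  expect_true(a$ci_low < 0 && a$ci_high > 0)
  # permutation-null oracle: observed |rho| is unexceptional
  perm <- replicate(200, abs(oracle_spearman(v, sample(s))))
  expect_gt(mean(perm >= abs(a$rho)), 0.01)
})

test_that("rho is invariant to strictly monotone volume transforms", {
  set.seed(5)
  v <- rlnorm(50); s <- round(6 * log1p(v) + rnorm(50, 0, 2))
  a <- spearman_with_ci(v, s)
  b <- spearman_with_ci(log1p(v), s)
  c2 <- spearman_with_ci(v^3, s)
  expect_equal(a$rho, b$rho, tolerance = 1e-12)
  expect_equal(a$rho, c2$rho, tolerance = 1e-12)
})

test_that("bootstrap CIs are seeded and bracket the estimate", {
  set.seed(4)
  v <- runif(60); s <- v + rnorm(60, 0, 0.3)
  b1 <- spearman_with_ci(v, s, n_boot = 300, seed = 9)
  b2 <- spearman_with_ci(v, s, n_boot = 300, seed = 9)
  expect_identical(b1$ci_low, b2$ci_low)
  expect_true(b1$ci_low <= b1$rho && b1$rho <= b1$ci_high)
})

test_that("cohort scores are monotone in volume when score noise vanishes", {
  dist <- cohort_distribution(base = list(grid_shape = c(16L, 16L, 8L)),
                              vol_meanlog = log(0.5),
                              sigma_nihss_adm = 0, sigma_nihss_24h = 0,
                              sigma_mrs = 0,
                              miss_prob = c(nihss_admission = 0, nihss_24h = 0,
                                            mrs_3m = 0))
  coh <- generate_cohort(40, dist, seed = 3, keep_dwi = FALSE)
  man <- coh$manifest
  # up to rounding ties (few distinct score levels at this scale) the rank
  # correlation is 1
  expect_gt(cor(man$true_volume_ml, man$nihss_admission, method = "spearman"),
            0.9)
  ord <- order(man$true_volume_ml)
  expect_true(all(diff(man$nihss_admission[ord]) >= 0))
})

test_that("cohorts are reproducible and structurally sound", {
  dist <- cohort_distribution(base = list(grid_shape = c(16L, 16L, 8L)),
                              vol_meanlog = log(0.5))
  a <- generate_cohort(12, dist, seed = 8, keep_dwi = FALSE)
  b <- generate_cohort(12, dist, seed = 8, keep_dwi = FALSE)
  expect_identical(a$manifest, b$manifest)
  man <- a$manifest
  expect_true(all(man$nihss_admission >= 0 & man$nihss_admission <= 42,
                  na.rm = TRUE))
  expect_true(all(man$mrs_3m >= 0 & man$mrs_3m <= 6, na.rm = TRUE))
  expect_true(all(man$intervention %in% c("EVT", "r-tPA", "Bridging", "none")))
  expect_true(all(man$true_volume_ml >= 0))
  # lesion truth matches the manifest
  expect_equal(vapply(a$subjects, function(s) s$truth$true_lesion_volume_ml,
                      numeric(1)), man$true_volume_ml)

  p <- tempfile(fileext = ".csv")
  write_cohort_manifest(a, p)
  expect_equal(read.csv(p)$true_volume_ml, man$true_volume_ml, tolerance = 1e-6)
  unlink(p)
})

test_that("very noisy scores decorrelate from volume", {
  dist <- cohort_distribution(base = list(grid_shape = c(16L, 16L, 8L)),
                              vol_meanlog = log(0.5),
                              sigma_nihss_adm = 500)
  coh <- generate_cohort(100, dist, seed = 13, keep_dwi = FALSE)
  man <- coh$manifest
  a <- spearman_with_ci(man$true_volume_ml, man$nihss_admission)
  # permutation null: the observed rho is within the null spread
  set.seed(1)
  perm <- replicate(400, oracle_spearman(man$true_volume_ml,
                                         sample(man$nihss_admission)))
  expect_lt(abs(a$rho), quantile(abs(perm), 0.999))
})

test_that("attenuation vanishes without noise and nulls under shuffling", {
  dist <- cohort_distribution(base = list(grid_shape = c(16L, 16L, 8L),
                                          noise_sigma = 0,
                                          anisotropy_fraction = 0),
                              vol_meanlog = log(0.5))
  coh <- generate_cohort(10, dist, seed = 21)
  res <- suppressWarnings(attenuation_experiment(coh, seed = 2))
  v <- res$volumes
  v20 <- v$volume_ml[v$scheme == "20dir"]
  v4 <- v$volume_ml[v$scheme == "4dir"]
  expect_equal(v4, v20, tolerance = 1e-12)          # schemes agree exactly
  expect_equal(res$attenuation$delta, rep(0, 3), tolerance = 1e-12)

  # shuffled scores: all rho CIs cover 0
  coh_shuf <- coh
  set.seed(6)
  coh_shuf$manifest$nihss_admission <-
    sample(coh_shuf$manifest$nihss_admission)
  coh_shuf$manifest$nihss_24h <- sample(coh_shuf$manifest$nihss_24h)
  coh_shuf$manifest$mrs_3m <- sample(coh_shuf$manifest$mrs_3m)
  res2 <- suppressWarnings(attenuation_experiment(coh_shuf, seed = 2))
  overall <- res2$associations[res2$associations$stratum == "all", ]
  expect_true(all(overall$ci_low < 0 & overall$ci_high > 0))
})

test_that("clinical_record validates ranges", {
  expect_error(clinical_record(50, 3, 2, "EVT"), "0, 42")
  expect_error(clinical_record(10, 3, 9, "none"), "0, 6")
  r <- clinical_record(10, NA, 3, "Bridging")
  expect_true(is.na(r$nihss_24h))
})
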