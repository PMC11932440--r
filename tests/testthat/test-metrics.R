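mk_mask <- function(idx, d = c(10L, 10L, 5L)) {
  m <- array(FALSE, d); m[idx] <- TRUE
  binary_mask(m, c(1, 1, 1))
}

test_that("jaccard matches set counting and its conventions", {
  a <- mk_mask(1:100); b <- mk_mask(51:150)
  expect_equal(jaccard(a, b), 50 / 150)             # |a|=|b|=100, overlap 50
  expect_equal(jaccard(a, a), 1)
  expect_equal(jaccard(mk_mask(1:10), mk_mask(11:20)), 0)
  expect_equal(jaccard(a, b), jaccard(b, a))        # symmetry

  empty <- mk_mask(integer(0))
  expect_equal(jaccard(empty, empty), 1)            # both-empty convention
  expect_true(is.na(jaccard(empty, empty, empty_value = NA)))
  expect_equal(jaccard(empty, a), 0)

  expect_error(jaccard(a, mk_mask(1:5, d = c(5L, 5L, 5L))), "geometry")

  # 1 iff identical (nonempty case)
  expect_lt(jaccard(a, mk_mask(1:99)), 1)
})

test_that("jaccard_summary reproduces the sort-based quantile oracle", {
  x <- seq(0.01, 1, by = 0.01)
  s <- jaccard_summary(x)
  expect_equal(s$median, oracle_percentile_type7(x, 0.5))
  expect_equal(s$iqr_low, oracle_percentile_type7(x, 0.25))
  expect_equal(s$iqr_high, oracle_percentile_type7(x, 0.75))
  expect_equal(s$min, 0.01); expect_equal(s$max, 1)

  same <- jaccard_summary(rep(0.22, 5))
  expect_equal(same$median, 0.22)
  expect_equal(same$iqr_low, 0.22); expect_equal(same$iqr_high, 0.22)

  set.seed(2)
  for (k in 1:5) {
    y <- runif(sample(5:50, 1))
    s2 <- jaccard_summary(y)
    expect_true(s2$min <= s2$median && s2$median <= s2$max)
  }
  expect_error(jaccard_summary(numeric(0)), "nonempty")
})

test_that("bland_altman uses alt-minus-ref differences and empirical limits", {
  v <- runif(20, 0, 10)
  ba0 <- bland_altman(v, v)
  expect_equal(ba0$bias, 0); expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)

  ref <- rep(0, 100); alt <- 1:100                  # differences 1..100
  ba <- bland_altman(ref, alt)
  expect_equal(ba$bias, 50.5)
  expect_equal(ba$loa_low, oracle_percentile_type7(1:100, 0.025))
  expect_equal(ba$loa_high, oracle_percentile_type7(1:100, 0.975))

  shifted <- bland_altman(ref, alt + 7)             # translation equivariance
  expect_equal(shifted$bias, ba$bias + 7)
  expect_equal(shifted$loa_low, ba$loa_low + 7)
  expect_equal(shifted$loa_high, ba$loa_high + 7)

  expect_error(bland_altman(1:4, 1:5), "differ in length")
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("agreement limits bracket at least 95% of the differences", {
  set.seed(31)
  for (k in 1:10) {
    n <- sample(10:500, 1)
    ref <- rnorm(n); alt <- ref + rcauchy(n)        # heavy tails on purpose
    ba <- bland_altman(ref, alt)
    d <- ba$per_subject_differences
    # interpolated percentiles leave at most 0.025(n-1)+1 points outside
    # each limit, so coverage is at least 0.95 - 2/n
    expect_gte(mean(d >= ba$loa_low & d <= ba$loa_high), 0.95 - 2 / n)
    expect_lte(ba$loa_low, ba$loa_high)
  }
})

test_that("wm_adc_moments agrees with the explicit-formula oracle", {
  d <- c(5L, 2L, 1L)
  x <- c(812, 743, 901, 655, 990, 870, 731, 624, 843, 779)  # um^2/s
  adc <- adc_map(array(x * 1e-6, d), c(1, 1, 1))
  wm <- binary_mask(array(TRUE, d), c(1, 1, 1))
  m <- wm_adc_moments(adc, wm)
  o <- oracle_moments(x)
  expect_equal(m$mean, o$mean, tolerance = 1e-9)
  expect_equal(m$sd, o$sd, tolerance = 1e-9)
  expect_equal(m$skewness, o$skewness, tolerance = 1e-9)
  expect_equal(m$kurtosis, o$kurtosis, tolerance = 1e-9)
  expect_equal(m$n_voxels, 10L)
  expect_false(m$degenerate)

  # Pearson convention is the excess value plus 3
  m_pearson <- wm_adc_moments(adc, wm, excess = FALSE)
  expect_equal(m_pearson$kurtosis, m$kurtosis + 3, tolerance = 1e-12)

  const <- wm_adc_moments(adc_map(array(7e-4, d), c(1, 1, 1)), wm)
  expect_true(const$degenerate)
  expect_equal(const$sd, 0); expect_equal(const$skewness, 0)
  expect_equal(const$kurtosis, 0)
  expect_equal(const$mean, 700)
})

test_that("large normal samples have near-zero skewness and excess kurtosis", {
  set.seed(8)
  n <- 40000
  d <- c(200L, 200L, 1L)
  adc <- adc_map(array(rnorm(n, 850e-6, 80e-6), d), c(1, 1, 1))
  wm <- binary_mask(array(TRUE, d), c(1, 1, 1))
  m <- wm_adc_moments(adc, wm)
  expect_lt(abs(m$skewness), 4 / sqrt(n) * 4)
  expect_lt(abs(m$kurtosis), 4 / sqrt(n) * 8)
})

test_that("paired moment tests behave like the exact signed-rank tail", {
  base <- lapply(1:8, function(i)
    list(mean = 800 + i, sd = 100 + i, kurtosis = 3 + 0.1 * i,
         skewness = 0.5 + 0.01 * i))
  same <- paired_moment_test(base, base)
  expect_true(all(same$degenerate))
  expect_true(all(is.na(same$p_value)))

  shifted <- lapply(base, function(m) { m$sd <- m$sd + 10; m })
  res <- paired_moment_test(base, shifted)
  sd_row <- res[res$moment == "sd", ]
  expect_false(sd_row$degenerate)
  # all 8 differences share one sign: exact two-sided p = 2 / 2^8
  expect_equal(sd_row$p_value, 2 / 2^8, tolerance = 1e-12)
  # unshifted moments remain degenerate rows
  expect_true(res[res$moment == "mean", "degenerate"])

  # swapping the arguments preserves the two-sided p-value
  res_swap <- paired_moment_test(shifted, base)
  expect_equal(res_swap[res_swap$moment == "sd", "p_value"], sd_row$p_value)
  expect_error(paired_moment_test(base[1:4], shifted[1:4]), "at least 6")
})
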