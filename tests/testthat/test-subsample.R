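test_that("cosine_match honors self-match, antipodes and the greedy oracle", {
  parent <- make_reference_scheme(20, seed = 2)

  # self-match: identity selection, all similarities 1
  self <- cosine_match(parent, parent)
  expect_identical(self$selected_indices, 1:20)
  expect_equal(self$similarity_scores, rep(1, 20), tolerance = 1e-12)

  # antipodal symmetry: -x matches target x with similarity 1
  cand <- gradient_scheme(rbind(c(0, 1, 0), c(-1, 0, 0)), 1000, 1)
  r <- cosine_match(cand, matrix(c(1, 0, 0), 1))
  expect_identical(r$selected_indices, 2L)
  expect_equal(r$similarity_scores, 1)

  # brute-force greedy oracle on random instances
  set.seed(42)
  for (k in 1:25) {
    cd <- normalize_directions(matrix(rnorm(60), 20, 3))
    tg <- normalize_directions(matrix(rnorm(12), 4, 3))
    cs <- gradient_scheme(cd, 1000, 1)
    expect_identical(cosine_match(cs, tg)$selected_indices,
                     oracle_greedy_match(cd, tg))
  }
  expect_error(cosine_match(gradient_scheme(diag(3), 1000, 1), parent),
               "at least 20 candidate")
})

test_that("similarity scores live in [0, 1] under the |cos| convention", {
  set.seed(7)
  for (k in 1:10) {
    cd <- gradient_scheme(normalize_directions(matrix(rnorm(45), 15, 3)), 1000, 1)
    tg <- normalize_directions(matrix(rnorm(9), 3, 3))
    s <- cosine_match(cd, tg)$similarity_scores
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("an exactly orthonormal candidate triplet is found by the search", {
  # parent holds the canonical axes among distractors kept away from them
  set.seed(5)
  distract <- normalize_directions(matrix(rnorm(51), 17, 3) +
                                     matrix(3 * c(1, 1, 1), 17, 3, byrow = TRUE))
  cand <- rbind(diag(3), distract)
  parent <- gradient_scheme(cand, 1000, 1)
  r <- cosine_match(parent, dwicore:::four_direction_target(diag(3)))
  expect_identical(sort(r$selected_indices[1:3]), 1:3)

  # exhaustive search over all C(20,3) triplets: none is more orthogonal
  best <- min(apply(combn(20, 3), 2, function(tr) {
    m <- abs(cand[tr, ] %*% t(cand[tr, ])); diag(m) <- 0; max(m)
  }))
  sel <- cand[r$selected_indices[1:3], ]
  m <- abs(sel %*% t(sel)); diag(m) <- 0
  expect_equal(max(m), best, tolerance = 1e-12)
})

test_that("4-direction repetitions are distinct, seeded and triplet-quality bounded", {
  parent <- make_reference_scheme(20, seed = 1)
  reps <- subsample_4dir(parent, n_repetitions = 14, seed = 5)
  expect_length(reps, 14)
  keys <- vapply(reps, function(r) paste(sort(r$selected_indices), collapse = "-"),
                 character(1))
  expect_equal(length(unique(keys)), 14)
  expect_true(all(vapply(reps, function(r)
    !anyDuplicated(r$selected_indices), logical(1))))

  reps2 <- subsample_4dir(parent, n_repetitions = 14, seed = 5)
  expect_identical(lapply(reps, `[[`, "selected_indices"),
                   lapply(reps2, `[[`, "selected_indices"))

  # triplet orthogonality: matched triplets are far more orthogonal than the
  # sampling density bound allows random triplets to be, and some tilts
  # achieve near-orthogonality outright
  mx <- vapply(reps, function(r) {
    g <- r$scheme$directions[1:3, ]
    m <- abs(g %*% t(g)); diag(m) <- 0; max(m)
  }, numeric(1))
  expect_true(all(mx < 0.9))
  expect_true(min(mx) <= 0.35)
  expect_lt(median(mx), 0.6)
})

test_that("12-direction subsampling is deterministic and beats random subsets", {
  parent <- make_reference_scheme(20, seed = 1)
  r <- subsample_12dir(parent)
  expect_length(unique(r$selected_indices), 12)
  expect_identical(r$selected_indices, subsample_12dir(parent)$selected_indices)

  # identity when the parent is the 12-direction target itself
  target <- make_reference_scheme(12, bvalue = parent$bvalue,
                                  n_b0 = parent$n_b0, seed = 42)
  expect_identical(subsample_12dir(target)$selected_indices, 1:12)

  # achieved mean |cos| at least matches greedy matching against random
  # 12-subsets of the same parent
  set.seed(99)
  rand_means <- replicate(1000, {
    sub <- sort(sample(20, 12))
    subsch <- gradient_scheme(parent$directions[sub, ], parent$bvalue, parent$n_b0)
    mean(cosine_match(subsch, target)$similarity_scores)
  })
  expect_gte(mean(r$similarity_scores), max(rand_means) - 1e-12)
  expect_error(subsample_12dir(make_reference_scheme(8)), "at least 12")
})

test_that("extract_subsampled_dwi keeps b0s and selected volumes only", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(12L, 12L, 6L),
                                      lesion_radius_mm = 4, seed = 3))
  full <- cosine_match(ph$dwi$scheme, ph$dwi$scheme)
  same <- extract_subsampled_dwi(ph$dwi, full)
  expect_equal(same$signal, ph$dwi$signal)

  r4 <- subsample_4dir(ph$dwi$scheme, 1, seed = 2)[[1]]
  sub <- extract_subsampled_dwi(ph$dwi, r4)
  expect_equal(dim(sub$signal)[4], length(ph$dwi$b0_indices) + 4L)
  expect_equal(sub$scheme$directions, ph$dwi$scheme$directions[r4$selected_indices, ])

  bad <- r4; bad$selected_indices <- c(1L, 2L, 3L, 25L)
  expect_error(extract_subsampled_dwi(ph$dwi, bad), "out of range")
})

test_that("the full-scheme ADC decomposes over disjoint 4-subsets (noise-free)", {
  # on noise-free isotropic data the log-mean over all 20 directions equals
  # the average of the log-means of the five disjoint 4-subsets
  ph <- generate_phantom(phantom_spec(grid_shape = c(12L, 12L, 6L),
                                      lesion_radius_mm = 4,
                                      noise_sigma = 0, anisotropy_fraction = 0,
                                      seed = 8))
  adc20 <- compute_adc(ph$dwi, mask = ph$truth$brain_mask)
  parts <- split(1:20, rep(1:5, each = 4))
  part_maps <- lapply(parts, function(ix) {
    res <- structure(list(selected_indices = as.integer(ix),
                          scheme = gradient_scheme(
                            ph$dwi$scheme$directions[ix, ],
                            ph$dwi$scheme$bvalue, ph$dwi$scheme$n_b0),
                          similarity_scores = rep(1, 4), repetition_id = 1L),
                     class = "subsample_result")
    compute_adc(extract_subsampled_dwi(ph$dwi, res),
                mask = ph$truth$brain_mask)$values
  })
  mean_of_parts <- Reduce(`+`, part_maps) / 5
  inb <- ph$truth$brain_mask$values
  expect_equal(mean_of_parts[inb], adc20$values[inb], tolerance = 1e-12)

  # and all three protocol depths agree exactly without noise or anisotropy
  a12 <- compute_adc(extract_subsampled_dwi(ph$dwi, subsample_12dir(ph$dwi$scheme)),
                     mask = ph$truth$brain_mask)
  a4 <- compute_adc(extract_subsampled_dwi(
    ph$dwi, subsample_4dir(ph$dwi$scheme, 1, seed = 1)[[1]]),
    mask = ph$truth$brain_mask)
  expect_equal(a12$values[inb], adc20$values[inb], tolerance = 1e-12)
  expect_equal(a4$values[inb], adc20$values[inb], tolerance = 1e-12)
})
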