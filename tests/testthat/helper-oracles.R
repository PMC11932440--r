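# Independent brute-force oracles used to pin down expected values.
# Everything here is deliberately written with explicit loops / set
# operations, NOT via the package's own code paths.

# --- greedy cosine matching, exhaustive per-step search --------------------
oracle_greedy_match <- function(cand, targ, absolute = TRUE) {
  used <- rep(FALSE, nrow(cand))
  sel <- integer(nrow(targ))
  for (i in seq_len(nrow(targ))) {
    best_j <- 0L; best_s <- -Inf
    for (j in seq_len(nrow(cand))) {
      if (used[j]) next
      s <- sum(cand[j, ] * targ[i, ])
      if (absolute) s <- abs(s)
      if (s > best_s + 1e-15) { best_s <- s; best_j <- j }
    }
    sel[i] <- best_j; used[best_j] <- TRUE
  }
  sel
}

# --- set-based 3-D morphology ---------------------------------------------
# masks represented as sets of linear indices; coordinates recovered on the
# fly; out-of-bounds handled by explicit coordinate checks
lin_of <- function(xyz, d) xyz[, 1] + d[1] * (xyz[, 2] - 1L) + d[1] * d[2] * (xyz[, 3] - 1L)
xyz_of <- function(lin, d) {
  lin0 <- lin - 1L
  cbind(lin0 %% d[1] + 1L,
        (lin0 %/% d[1]) %% d[2] + 1L,
        lin0 %/% (d[1] * d[2]) + 1L)
}

oracle_translate <- function(set, off, d) {
  if (length(set) == 0L) return(integer(0))
  xyz <- xyz_of(set, d)
  xyz[, 1] <- xyz[, 1] + off[1]; xyz[, 2] <- xyz[, 2] + off[2]
  xyz[, 3] <- xyz[, 3] + off[3]
  ok <- xyz[, 1] >= 1L & xyz[, 1] <= d[1] & xyz[, 2] >= 1L & xyz[, 2] <= d[2] &
    xyz[, 3] >= 1L & xyz[, 3] <= d[3]
  sort(lin_of(xyz[ok, , drop = FALSE], d))
}

oracle_erode <- function(set, offsets, d) {
  # v survives iff v + b is in the set for every offset b
  keep <- rep(TRUE, length(set))
  for (i in seq_len(nrow(offsets))) {
    shifted_back <- oracle_translate(set, -offsets[i, ], d)  # {v : v + b in set}
    keep <- keep & (set %in% shifted_back)
  }
  set[keep]
}

oracle_dilate <- function(set, offsets, d) {
  out <- integer(0)
  for (i in seq_len(nrow(offsets)))
    out <- union(out, oracle_translate(set, offsets[i, ], d))
  sort(out)
}

oracle_open <- function(set, offsets, d) oracle_dilate(oracle_erode(set, offsets, d), offsets, d)
oracle_close <- function(set, offsets, d) oracle_erode(oracle_dilate(set, offsets, d), offsets, d)

# --- BFS connected components, 26-neighborhood ----------------------------
oracle_components_26 <- function(set, d) {
  if (length(set) == 0L) return(integer(0))
  set <- sort(set)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, ]
  pos <- new.env(hash = TRUE, parent = emptyenv())  # linear index -> position
  for (k in seq_along(set)) assign(as.character(set[k]), k, envir = pos)
  label <- integer(length(set))
  cur <- 0L
  for (s0 in seq_along(set)) {
    if (label[s0] != 0L) next
    cur <- cur + 1L
    queue <- s0
    label[s0] <- cur
    while (length(queue) > 0L) {
      k <- queue[1L]; queue <- queue[-1L]
      xyz <- xyz_of(set[k], d)
      for (i in seq_len(nrow(offs))) {
        nb <- xyz + offs[i, ]
        if (any(nb < 1L) || any(nb > d)) next
        kk <- pos[[as.character(lin_of(matrix(nb, 1L), d))]]
        if (!is.null(kk) && label[kk] == 0L) {
          label[kk] <- cur
          queue <- c(queue, kk)
        }
      }
    }
  }
  stats::setNames(label, as.character(set))  # component id in BFS discovery order
}

# full segmentation oracle: threshold -> open -> close -> components -> filter
oracle_segment <- function(adc_values, wm, voxel_size, threshold, min_mm3) {
  d <- dim(adc_values)
  offsets <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  set <- which(adc_values < threshold & adc_values > 0 & wm)
  set <- oracle_close(oracle_open(sort(set), offsets, d), offsets, d)
  lab <- oracle_components_26(set, d)
  vox_mm3 <- prod(voxel_size)
  out <- array(0L, dim = d)
  if (length(lab) > 0L) {
    vox <- sort(as.integer(names(lab)))          # sorted voxel order
    ids <- as.integer(lab[as.character(vox)])
    sizes <- table(ids)
    keep_ids <- as.integer(names(sizes))[as.vector(sizes) * vox_mm3 >= min_mm3]
    nxt <- 0L; relab <- integer(max(ids))
    # renumber kept components in order of each component's first voxel
    for (k in seq_along(vox)) {
      id <- ids[k]
      if (id %in% keep_ids) {
        if (relab[id] == 0L) { nxt <- nxt + 1L; relab[id] <- nxt }
        out[vox[k]] <- relab[id]
      }
    }
  }
  out
}

# --- scalar statistics -----------------------------------------------------
oracle_percentile_type7 <- function(x, p) {
  # linear interpolation between order statistics, h = (n-1)p + 1
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_moments <- function(x) {
  n <- length(x); m <- sum(x) / n
  m2 <- sum((x - m)^2) / n; m3 <- sum((x - m)^3) / n; m4 <- sum((x - m)^4) / n
  list(mean = m, sd = sqrt(sum((x - m)^2) / (n - 1)),
       skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# closed-form Rician mean by numerical integration of r * f_Rice(r)
oracle_rician_mean <- function(s, sigma) {
  f <- function(r) {
    # exp-scaled Bessel keeps the integrand finite at high SNR
    (r / sigma^2) * exp(-(r - s)^2 / (2 * sigma^2)) *
      besselI(r * s / sigma^2, 0, expon.scaled = TRUE) * r
  }
  stats::integrate(f, 0, s + 12 * sigma, rel.tol = 1e-10)$value
}

# smooth random ADC field fixture (blob-like sub-threshold regions)
random_adc_fixture <- function(d, seed, mean = 680e-6, sd = 120e-6) {
  set.seed(seed)
  a <- array(stats::rnorm(prod(d), mean, sd), dim = d)
  # one crude 6-neighbor smoothing pass (test-local, index-slice based)
  s <- a
  s[-1, , ] <- s[-1, , ] + a[-d[1], , ]
  s[-d[1], , ] <- s[-d[1], , ] + a[-1, , ]
  s[, -1, ] <- s[, -1, ] + a[, -d[2], ]
  s[, -d[2], ] <- s[, -d[2], ] + a[, -1, ]
  s[, , -1] <- s[, , -1] + a[, , -d[3]]
  s[, , -d[3]] <- s[, , -d[3]] + a[, , -1]
  s / 7
}
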