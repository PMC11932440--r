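#' Diffusion gradient scheme
#'
#' A gradient scheme bundles the unit diffusion-encoding directions
#' (b-vectors), the diffusion weighting (b-value) and the number of
#' unweighted (b = 0) acquisitions of one protocol.
#'
#' @param directions numeric matrix with one row per encoding direction and
#'   three columns (x, y, z). Rows must have unit Euclidean norm; rows whose
#'   norm deviates by more than `1e-6` are rejected (use
#'   [normalize_directions()] first if needed).
#' @param bvalue diffusion weighting in s/mm^2; must be positive.
#' @param n_b0 number of b = 0 volumes in the protocol; at least 1.
#'
#' @return An object of class `gradient_scheme`: a list with elements
#'   `directions` (n x 3 matrix), `bvalue` and `n_b0`.
#' @examples
#' gradient_scheme(diag(3), bvalue = 1000, n_b0 = 1)
#' @export
gradient_scheme <- function(directions, bvalue, n_b0) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L || nrow(directions) < 1L)
    stop("'directions' must be an n x 3 matrix with n >= 1", call. = FALSE)
  storage.mode(directions) <- "double"
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("all directions must have unit norm (tolerance 1e-6); found norms ",
         paste(signif(nrm[abs(nrm - 1) > 1e-6], 6), collapse = ", "),
         call. = FALSE)
  bvalue <- as.numeric(bvalue)
  if (length(bvalue) != 1L || !is.finite(bvalue) || bvalue <= 0)
    stop("'bvalue' must be a single positive number (s/mm^2)", call. = FALSE)
  n_b0 <- as.integer(n_b0)
  if (length(n_b0) != 1L || is.na(n_b0) || n_b0 < 1L)
    stop("'n_b0' must be an integer >= 1", call. = FALSE)
  structure(list(directions = directions, bvalue = bvalue, n_b0 = n_b0),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("<gradient_scheme> %d directions, b = %g s/mm^2, %d b0 volume(s)\n",
              nrow(x$directions), x$bvalue, x$n_b0))
  invisible(x)
}

#' Renormalize direction vectors to unit length
#'
#' @param directions n x 3 numeric matrix of nonzero vectors.
#' @return The matrix with every row scaled to unit Euclidean norm.
#' @export
normalize_directions <- function(directions) {
  directions <- as.matrix(directions)
  nrm <- sqrt(rowSums(directions^2))
  if (any(nrm == 0))
    stop("cannot normalize zero-length direction vectors", call. = FALSE)
  directions / nrm
}

#' Generate an approximately uniform gradient scheme
#'
#' Builds a set of diffusion-encoding directions spread over the unit sphere
#' by iterative electrostatic repulsion of antipodally symmetric point pairs,
#' the standard construction for "equispaced" clinical schemes. The result is
#' deterministic for a given seed.
#'
#' @param n_directions number of directions, at least 4.
#' @param bvalue diffusion weighting in s/mm^2 (default 1000, the single-shell
#'   stroke protocol value).
#' @param n_b0 number of b = 0 volumes (default 10).
#' @param seed integer seed for the random initialization.
#' @param n_iter number of repulsion iterations (default 600).
#'
#' @return A [gradient_scheme()] whose `min_angle_deg` attribute reports the
#'   minimum pairwise angular separation (in degrees, antipodally folded).
#' @examples
#' sch <- make_reference_scheme(20, seed = 1)
#' attr(sch, "min_angle_deg")
#' @export
make_reference_scheme <- function(n_directions, bvalue = 1000, n_b0 = 10,
                                  seed = 1L, n_iter = 600L) {
  if (n_directions < 4L)
    stop("'n_directions' must be at least 4", call. = FALSE)
  key <- paste(n_directions, bvalue, n_b0, seed, n_iter, sep = "|")
  cached <- .scheme_cache[[key]]
  if (!is.null(cached)) return(cached)
  x <- with_local_seed(seed, {
    matrix(stats::rnorm(3L * n_directions), ncol = 3L)
  })
  x <- normalize_directions(x)
  n <- n_directions
  energy <- function(x) {
    # Coulomb energy over all point pairs and point-antipode pairs
    e <- 0
    for (i in seq_len(n - 1)) {
      d_min <- x[(i + 1):n, , drop = FALSE] -
        matrix(x[i, ], n - i, 3L, byrow = TRUE)
      d_pls <- x[(i + 1):n, , drop = FALSE] +
        matrix(x[i, ], n - i, 3L, byrow = TRUE)
      e <- e + sum(1 / sqrt(rowSums(d_min^2))) + sum(1 / sqrt(rowSums(d_pls^2)))
    }
    e
  }
  forces <- function(x) {
    frc <- matrix(0, n, 3L)
    for (i in seq_len(n)) {
      d_min <- x - matrix(x[i, ], n, 3L, byrow = TRUE)   # x_j - x_i
      d_pls <- x + matrix(x[i, ], n, 3L, byrow = TRUE)   # x_j + x_i
      r_min <- sqrt(rowSums(d_min^2)); r_min[i] <- Inf
      r_pls <- sqrt(rowSums(d_pls^2))
      frc[i, ] <- -colSums(d_min / r_min^3) + colSums(d_pls / r_pls^3)
    }
    frc - x * rowSums(frc * x)                           # tangential part
  }
  # energy-guarded descent with adaptive step (capped displacement)
  step <- 0.1
  e_cur <- energy(x)
  for (it in seq_len(n_iter)) {
    frc <- forces(x)
    scale <- max(sqrt(rowSums(frc^2)))
    if (scale == 0) break
    x_new <- normalize_directions(x + (step / scale) * frc)
    e_new <- energy(x_new)
    if (e_new < e_cur) {
      x <- x_new; e_cur <- e_new; step <- step * 1.05
    } else {
      step <- step * 0.5
    }
    if (step < 1e-8) break
  }
  sch <- gradient_scheme(x, bvalue = bvalue, n_b0 = n_b0)
  cosab <- abs(tcrossprod(x))
  diag(cosab) <- 0
  # antipodally folded minimum separation = acos of the largest |cos|
  attr(sch, "min_angle_deg") <- acos(min(1, max(cosab))) * 180 / pi
  .scheme_cache[[key]] <- sch
  sch
}

#' Uniformly random 3-D rotation matrix
#'
#' Draws a rotation matrix approximately Haar-uniform on SO(3) via QR
#' decomposition of a Gaussian matrix, used to model head tilt between
#' acquisitions.
#'
#' @param seed optional integer seed; if `NULL` the current RNG stream is used.
#' @return A 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation <- function(seed = NULL) {
  draw <- function() {
    m <- matrix(stats::rnorm(9L), 3L, 3L)
    qr_ <- qr(m)
    q <- qr.Q(qr_)
    q <- q %*% diag(sign(diag(qr.R(qr_))))
    if (det(q) < 0) q[, 3L] <- -q[, 3L]
    q
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

# deterministic construction cache: the same arguments always give the same
# scheme, so repeated calls (one per phantom subject) are free
.scheme_cache <- new.env(hash = TRUE, parent = emptyenv())

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
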