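#' Greedy cosine-similarity matching of gradient directions
#'
#' Emulates a target acquisition protocol by picking, for each target
#' b-vector in order, the not-yet-used candidate b-vector with the highest
#' cosine similarity. Because diffusion encoding is antipodally symmetric
#' (g and -g measure the same attenuation), the absolute cosine is used by
#' default; ties are broken by the lowest candidate index, making the
#' assignment deterministic.
#'
#' @param candidates [gradient_scheme()] providing the candidate b-vectors.
#' @param targets [gradient_scheme()] (or n x 3 unit-row matrix) of target
#'   b-vectors; there must be at least as many candidates as targets.
#' @param absolute use `|cos|` (default, physically correct for diffusion
#'   encoding); `FALSE` uses the signed cosine.
#' @param repetition_id integer tag carried through to the result.
#' @return An object of class `subsample_result`: `selected_indices` (into
#'   the candidate scheme, in target order), `scheme` (the selected
#'   directions as a [gradient_scheme()] inheriting the candidates' b-value
#'   and b0 count), `similarity_scores` (achieved per-target similarity) and
#'   `repetition_id`.
#' @examples
#' parent <- make_reference_scheme(20, seed = 2)
#' cosine_match(parent, diag(3))
#' @export
cosine_match <- function(candidates, targets, absolute = TRUE,
                         repetition_id = 1L) {
  stopifnot(inherits(candidates, "gradient_scheme"))
  tdir <- if (inherits(targets, "gradient_scheme")) targets$directions
          else as.matrix(targets)
  cdir <- candidates$directions
  n_t <- nrow(tdir); n_c <- nrow(cdir)
  if (n_c < n_t)
    stop(sprintf("need at least %d candidate directions, have %d", n_t, n_c),
         call. = FALSE)
  cosm <- tcrossprod(tdir, cdir)            # n_t x n_c: cos(target, candidate)
  if (absolute) cosm <- abs(cosm)
  sel <- integer(n_t); score <- numeric(n_t)
  used <- rep(FALSE, n_c)
  for (i in seq_len(n_t)) {
    s <- cosm[i, ]
    s[used] <- -Inf
    j <- which.max(s)                       # which.max takes the first maximum
    sel[i] <- j; score[i] <- s[j]; used[j] <- TRUE
  }
  structure(list(selected_indices = sel,
                 scheme = gradient_scheme(cdir[sel, , drop = FALSE],
                                          bvalue = candidates$bvalue,
                                          n_b0 = candidates$n_b0),
                 similarity_scores = score,
                 repetition_id = as.integer(repetition_id)),
            class = "subsample_result")
}

#' @export
print.subsample_result <- function(x, ...) {
  cat(sprintf("<subsample_result> repetition %d: indices [%s], mean |cos| = %.4f\n",
              x$repetition_id, paste(x$selected_indices, collapse = ", "),
              mean(x$similarity_scores)))
  invisible(x)
}

# target frame of the emergency-room style 4-direction protocol:
# three orthonormal axes plus one oblique direction, optionally rotated
four_direction_target <- function(rotation = diag(3)) {
  t(rotation %*% t(rbind(diag(3), rep(1, 3) / sqrt(3))))
}

#' Simulate heterogeneous 4-direction acquisitions
#'
#' Draws `n_repetitions` low-angular-resolution protocols from a parent
#' scheme. Each repetition matches the parent directions (greedy
#' [cosine_match()]) against a target of 3 orthonormal axes plus one oblique
#' `(1,1,1)/sqrt(3)` direction, the whole frame rotated by an independent
#' uniformly random 3-D rotation that models head tilt and calibration
#' differences between acquisitions. Repetitions are forced to have distinct
#' index sets (a colliding rotation is redrawn); selected index sets may
#' overlap across repetitions.
#'
#' @param parent [gradient_scheme()] with at least 4 directions.
#' @param n_repetitions number of heterogeneous sets (default 14).
#' @param seed integer seed.
#' @param max_retries redraw budget per repetition before giving up.
#' @return A list of `n_repetitions` [cosine_match()] results with
#'   `repetition_id` 1..n.
#' @export
subsample_4dir <- function(parent, n_repetitions = 14L, seed = 1L,
                           max_retries = 200L) {
  stopifnot(inherits(parent, "gradient_scheme"))
  if (nrow(parent$directions) < 4L)
    stop("parent scheme must have at least 4 directions", call. = FALSE)
  if (n_repetitions < 1L) stop("'n_repetitions' must be >= 1", call. = FALSE)
  with_local_seed(seed, {
    out <- vector("list", n_repetitions)
    seen <- character(0)
    for (r in seq_len(n_repetitions)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        res <- cosine_match(parent, four_direction_target(random_rotation()),
                            repetition_id = r)
        key <- paste(sort(res$selected_indices), collapse = "-")
        if (!key %in% seen) { seen <- c(seen, key); out[[r]] <- res; ok <- TRUE; break }
      }
      if (!ok)
        stop(sprintf(
          "could only produce %d distinct 4-direction sets of the %d requested (retry budget %d)",
          r - 1L, n_repetitions, max_retries), call. = FALSE)
    }
    out
  })
}

#' Simulate a 12-direction equispaced acquisition
#'
#' Matches the parent scheme against a fixed 12-direction equispaced target
#' (electrostatic-repulsion construction with a fixed internal seed), giving
#' a deterministic medium-angular-resolution protocol.
#'
#' @param parent [gradient_scheme()] with at least 12 directions.
#' @return A [cosine_match()] result.
#' @export
subsample_12dir <- function(parent) {
  stopifnot(inherits(parent, "gradient_scheme"))
  if (nrow(parent$directions) < 12L)
    stop("parent scheme must have at least 12 directions", call. = FALSE)
  target <- make_reference_scheme(12L, bvalue = parent$bvalue,
                                  n_b0 = parent$n_b0, seed = 42L)
  cosine_match(parent, target, repetition_id = 1L)
}

#' Extract the sub-protocol volumes from a DWI acquisition
#'
#' Builds a new [dwi_volume()] keeping all b = 0 volumes and only the
#' diffusion-weighted volumes selected by a subsampling result; signal values
#' are copied, never resampled.
#'
#' @param volume a [dwi_volume()].
#' @param result a [cosine_match()] / [subsample_4dir()] element whose
#'   `selected_indices` refer to `volume$scheme` direction rows.
#' @return A [dwi_volume()] with `n_b0 + length(selected_indices)` volumes.
#' @export
extract_subsampled_dwi <- function(volume, result) {
  stopifnot(inherits(volume, "dwi_volume"), inherits(result, "subsample_result"))
  sel <- result$selected_indices
  n_dir <- length(volume$direction_indices)
  if (any(sel < 1L | sel > n_dir))
    stop("selected index out of range for this volume's scheme", call. = FALSE)
  keep4 <- c(volume$b0_indices, volume$direction_indices[sel])
  sig <- volume$signal[, , , keep4, drop = FALSE]
  scheme <- gradient_scheme(volume$scheme$directions[sel, , drop = FALSE],
                            bvalue = volume$scheme$bvalue,
                            n_b0 = volume$scheme$n_b0)
  dwi_volume(sig, voxel_size = volume$voxel_size, scheme = scheme,
             b0_indices = seq_along(volume$b0_indices),
             direction_indices = length(volume$b0_indices) + seq_along(sel))
}
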