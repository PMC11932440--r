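# --- 3-D binary morphology -------------------------------------------------
#
# Structuring elements are given as integer offset sets B (rows = offsets).
# Erosion  (M %minus% B): E(v) = AND_{b in B} M(v + b), outside = FALSE.
# Dilation (M %plus%  B): D(v) = OR_{b in B}  M(v - b).
# Opening = dilate(erode(M)), closing = erode(dilate(M)) with the same B;
# both are idempotent, and opening equals the union of the translates of B
# contained in M. The default element is the 2x2x2 cube anchored at its
# (0,0,0) corner, offsets {0,1}^3 — the even-sized element has no natural
# center, so the corner anchor is the documented convention.

cube2_offsets <- function() as.matrix(expand.grid(dx = 0:1, dy = 0:1, dz = 0:1))

# a(v + off) with FALSE padding
shift_logical <- function(a, off) {
  d <- dim(a)
  out <- array(FALSE, dim = d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- off[k]
    dst[[k]] <- seq.int(max(1L, 1L - o), min(d[k], d[k] - o))
    if (length(dst[[k]]) == 0L) return(out)
    src[[k]] <- dst[[k]] + o
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' 3-D binary erosion, dilation, opening and closing
#'
#' Morphology on 3-D logical arrays with an explicit offset-set structuring
#' element (default: the 2x2x2 cube anchored at its corner). Out-of-volume
#' voxels count as background.
#'
#' @param a 3-D logical array.
#' @param offsets integer matrix of structuring-element offsets (one row per
#'   member voxel, columns dx, dy, dz).
#' @return A 3-D logical array of the same shape.
#' @export
erode3d <- function(a, offsets = cube2_offsets()) {
  out <- NULL
  for (i in seq_len(nrow(offsets))) {
    s <- shift_logical(a, offsets[i, ])
    out <- if (is.null(out)) s else out & s
  }
  out
}

#' @rdname erode3d
#' @export
dilate3d <- function(a, offsets = cube2_offsets()) {
  out <- NULL
  for (i in seq_len(nrow(offsets))) {
    s <- shift_logical(a, -offsets[i, ])
    out <- if (is.null(out)) s else out | s
  }
  out
}

#' @rdname erode3d
#' @export
open3d <- function(a, offsets = cube2_offsets())
  dilate3d(erode3d(a, offsets), offsets)

#' @rdname erode3d
#' @export
close3d <- function(a, offsets = cube2_offsets())
  erode3d(dilate3d(a, offsets), offsets)

# 26-connectivity forward neighbor offsets (half of the 3x3x3 neighborhood)
conn26_forward <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  g[keep, , drop = FALSE]
}

#' Label 26-connected components of a 3-D mask
#'
#' Decomposes a binary volume into components connected through the full
#' 3x3x3 voxel neighborhood (26-connectivity). Component ids are assigned in
#' order of each component's first voxel in column-major order.
#'
#' @param a 3-D logical array.
#' @return A 3-D integer array; 0 is background, components are 1..k.
#' @export
label_components_26 <- function(a) {
  d <- dim(a)
  labels <- array(0L, dim = d)
  fg <- which(a)
  n_fg <- length(fg)
  if (n_fg == 0L) return(labels)
  idx <- array(0L, dim = d)
  idx[fg] <- seq_len(n_fg)
  edges <- list()
  offs <- conn26_forward()
  for (i in seq_len(nrow(offs))) {
    nb <- shift_integer(idx, offs[i, ])
    both <- idx > 0L & nb > 0L
    if (any(both)) edges[[length(edges) + 1L]] <- cbind(idx[both], nb[both])
  }
  memb <- if (length(edges) > 0L) {
    e <- do.call(rbind, edges)
    g <- igraph::make_graph(t(e), n = n_fg, directed = FALSE)
    igraph::components(g)$membership
  } else seq_len(n_fg)
  # renumber by first occurrence in column-major voxel order
  relab <- integer(max(memb))
  nxt <- 0L
  for (m in memb) if (relab[m] == 0L) { nxt <- nxt + 1L; relab[m] <- nxt }
  labels[fg] <- relab[memb]
  labels
}

# integer/numeric analogue of shift_logical with 0 padding
shift_integer <- function(a, off) {
  d <- dim(a)
  out <- array(0L, dim = d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- off[k]
    dst[[k]] <- seq.int(max(1L, 1L - o), min(d[k], d[k] - o))
    if (length(dst[[k]]) == 0L) return(out)
    src[[k]] <- dst[[k]] + o
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' DEFUSE-criterion ischemic core segmentation
#'
#' Segments the ischemic core from an ADC map restricted to white matter:
#' 1. threshold: voxels with `0 < ADC < threshold` inside the WM mask;
#' 2. morphological opening then closing with a 2x2x2 cube structuring
#'    element (removes spurious specks, then fills small gaps);
#' 3. 26-connected component decomposition (full 3x3x3 neighborhood);
#' 4. removal of components with physical volume below `min_component_mm3`.
#'
#' The `ADC > 0` guard excludes voxels zeroed by [compute_adc()] (failed or
#' out-of-head voxels), which would otherwise fall spuriously below the
#' threshold. At the clinical 1.6 x 1.6 x 3 mm resolution a single voxel is
#' 7.68 mm^3, so the default 1 mm^3 filter removes nothing — it matters for
#' higher-resolution grids.
#'
#' @param adc an [adc_map()] in mm^2/s.
#' @param wm_mask a [binary_mask()] of white matter, same geometry.
#' @param threshold core ADC threshold in mm^2/s (default [defuse_threshold]).
#' @param min_component_mm3 minimum component volume kept, mm^3.
#' @return An object of class `core_segmentation`: `mask` (a
#'   [binary_mask()]), `component_labels` (3-D integer array),
#'   `component_volumes_mm3` (named per retained label) and
#'   `total_volume_ml`.
#' @export
segment_core <- function(adc, wm_mask, threshold = defuse_threshold,
                         min_component_mm3 = 1.0) {
  stopifnot(inherits(adc, "adc_map"), inherits(wm_mask, "binary_mask"))
  if (!same_geometry(adc, wm_mask))
    stop("ADC map and WM mask must share shape and voxel size", call. = FALSE)
  binary <- adc$values < threshold & adc$values > 0 & wm_mask$values
  cleaned <- close3d(open3d(binary))
  labels <- label_components_26(cleaned)
  vox_mm3 <- prod(adc$voxel_size)
  n_comp <- max(labels)
  if (n_comp > 0L) {
    sizes <- tabulate(labels[labels > 0L], nbins = n_comp)
    vols <- sizes * vox_mm3
    keep <- which(vols >= min_component_mm3)
    relab <- integer(n_comp)
    relab[keep] <- seq_along(keep)
    fg <- labels > 0L
    labels[fg] <- relab[labels[fg]]
    vols <- vols[keep]
    if (length(vols)) names(vols) <- seq_along(vols)
  } else {
    vols <- numeric(0)
  }
  mask <- labels > 0L
  structure(list(mask = binary_mask(array(mask, dim = dim(adc$values)),
                                    adc$voxel_size),
                 component_labels = labels,
                 component_volumes_mm3 = vols,
                 total_volume_ml = sum(vols) / 1000),
            class = "core_segmentation")
}

#' @export
print.core_segmentation <- function(x, ...) {
  cat(sprintf("<core_segmentation> %d component(s), total volume %.3f mL\n",
              length(x$component_volumes_mm3), x$total_volume_ml))
  invisible(x)
}

#' Voxelwise consensus probability across core segmentations
#'
#' Averages the binary core masks of several protocol variants into a
#' consensus map: the per-voxel fraction of variants that call the voxel
#' ischemic core.
#'
#' @param segs nonempty list of [segment_core()] results sharing geometry.
#' @return A 3-D numeric array with values in `[0, 1]`.
#' @export
consensus_probability_mask <- function(segs) {
  if (length(segs) == 0L) stop("need at least one segmentation", call. = FALSE)
  stopifnot(all(vapply(segs, inherits, logical(1), "core_segmentation")))
  for (s in segs[-1])
    if (!same_geometry(s$mask, segs[[1]]$mask))
      stop("segmentations do not share geometry", call. = FALSE)
  acc <- Reduce(`+`, lapply(segs, function(s) s$mask$values + 0))
  acc / length(segs)
}
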