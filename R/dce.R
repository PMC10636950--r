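#' Percent enhancement (PE) map
#'
#' Voxel-wise early contrast enhancement: `(S1 - S0) / S0`, where `S0` is the
#' pre-contrast and `S1` the early (2 min) post-contrast signal. Voxels with
#' `S0 <= 0` cannot be normalized and are masked (`NaN`), never raised as
#' errors.
#'
#' @param s0,s1 pre-contrast and early post-contrast [image_volume()]s on the
#'   same grid.
#' @return an [image_volume()] of dimensionless PE fractions (0.5 = 50%
#'   enhancement), `NaN` where undefined.
#' @export
compute_pe_map <- function(s0, s1) {
  stopifnot(is_image_volume(s0), is_image_volume(s1))
  stop_if_grid_mismatch(s0, s1, "DCE phases")
  pe <- (s1$voxels - s0$voxels) / s0$voxels
  pe[s0$voxels <= 0] <- NaN
  image_volume(pe, s0$spacing, allow_na = TRUE)
}

#' Signal enhancement ratio (SER) map
#'
#' Voxel-wise washout kinetics: `(S1 - S0) / (S2 - S0)` with `S2` the delayed
#' (8 min) post-contrast signal. SER > 1 indicates signal washout between the
#' early and delayed phases. The ratio is undefined where the delayed-phase
#' enhancement vanishes; voxels with `|S2 - S0| <= epsilon * max(S0, 1)` are
#' masked (`NaN`).
#'
#' @param s0,s1,s2 DCE phases on the same grid.
#' @param epsilon relative degeneracy guard for the denominator.
#' @return an [image_volume()], `NaN` where undefined.
#' @export
compute_ser_map <- function(s0, s1, s2, epsilon = 1e-6) {
  stopifnot(is_image_volume(s0), is_image_volume(s1), is_image_volume(s2))
  stop_if_grid_mismatch(s0, s1, "DCE phases")
  stop_if_grid_mismatch(s0, s2, "DCE phases")
  den <- s2$voxels - s0$voxels
  bad <- abs(den) <= epsilon * pmax(s0$voxels, 1)
  ser <- (s1$voxels - s0$voxels) / den
  ser[bad] <- NaN
  image_volume(ser, s0$spacing, allow_na = TRUE)
}

# 26-connected component labeling of a logical 3D array.
# Breadth-first with a vectorized frontier; fine for lesion-scale masks.
label_components <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, dim = d)
  if (!any(mask)) return(labels)
  offs <- as.matrix(expand.grid(dr = -1:1, dc = -1:1, ds = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nr <- d[1]; nc <- d[2]; ns <- d[3]
  lin <- function(co) co[, 1] + (co[, 2] - 1L) * nr + (co[, 3] - 1L) * nr * nc
  unvisited <- mask
  lab <- 0L
  while (any(unvisited)) {
    lab <- lab + 1L
    seed <- which(unvisited)[1]
    frontier <- arrayInd(seed, d)
    unvisited[seed] <- FALSE
    labels[seed] <- lab
    while (nrow(frontier)) {
      n <- nrow(frontier)
      nb <- frontier[rep(seq_len(n), each = nrow(offs)), , drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), n), , drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= nr & nb[, 2] >= 1 & nb[, 2] <= nc &
        nb[, 3] >= 1 & nb[, 3] <= ns
      nb <- nb[ok, , drop = FALSE]
      if (!nrow(nb)) break
      li <- unique(lin(nb))
      li <- li[unvisited[li]]
      if (!length(li)) break
      unvisited[li] <- FALSE
      labels[li] <- lab
      frontier <- arrayInd(li, d)
    }
  }
  labels
}

#' Segment an enhancing tumor from a PE map
#'
#' Thresholds the PE map in 3D (default: percent enhancement of 50% or
#' greater at 2 min post contrast) and labels 26-connected components. When a
#' `seed_point` is supplied, its component is the lesion; otherwise the
#' largest component is kept — a deterministic surrogate for manual lesion
#' identification. An empty threshold result is an explicit "no enhancing
#' lesion" outcome, not an error.
#'
#' @param pe_map PE [image_volume()] (from [compute_pe_map()]).
#' @param threshold PE segmentation threshold (default 0.50).
#' @param seed_point optional integer (row, col, slice) index inside the
#'   lesion.
#' @return object of class `tumor_mask`: `mask` (logical array of the
#'   selected lesion), `labels` (all components), `spacing`, `lesion_found`.
#' @export
segment_tumor <- function(pe_map, threshold = 0.50, seed_point = NULL) {
  stopifnot(is_image_volume(pe_map))
  above <- is.finite(pe_map$voxels) & pe_map$voxels >= threshold
  if (!any(above)) {
    return(structure(list(mask = above, labels = array(0L, dim(above)),
                          spacing = pe_map$spacing, lesion_found = FALSE),
                     class = "tumor_mask"))
  }
  labels <- label_components(above)
  if (!is.null(seed_point)) {
    seed_point <- as.integer(seed_point)
    stopifnot(length(seed_point) == 3L)
    lab <- labels[seed_point[1], seed_point[2], seed_point[3]]
    if (lab == 0L)
      stop("seed_point is not inside any enhancing component", call. = FALSE)
  } else {
    sizes <- tabulate(labels[labels > 0L])
    lab <- which.max(sizes)
  }
  structure(list(mask = labels == lab, labels = labels,
                 spacing = pe_map$spacing, lesion_found = TRUE),
            class = "tumor_mask")
}

#' @export
print.tumor_mask <- function(x, ...) {
  if (!x$lesion_found) cat("<tumor_mask> no enhancing lesion\n")
  else cat(sprintf("<tumor_mask> %d voxels (%.3f cc), %d component(s) found\n",
                   sum(x$mask), sum(x$mask) * prod(x$spacing) / 1000,
                   max(x$labels)))
  invisible(x)
}

#' Hotspot peak of a parameter map within a tumor
#'
#' The peak is the highest mean over an in-plane `window x window` (default
#' 3 x 3) tumor subregion: windows lie within one axial slice and every voxel
#' of the window must belong to the mask and carry a valid (finite) map
#' value. For lesions too small to contain any full window, the maximum
#' single-voxel value is returned with a warning.
#'
#' @param map an [image_volume()] parameter map (PE or SER).
#' @param mask a `tumor_mask` (or logical array on the same grid).
#' @param window odd in-plane window edge, voxels.
#' @return scalar peak value.
#' @export
hotspot_peak <- function(map, mask, window = 3L) {
  stopifnot(is_image_volume(map))
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  stopifnot(identical(dim(m), dim(map$voxels)))
  window <- as.integer(window)
  if (window %% 2L != 1L || window < 1L) stop("window must be odd >= 1")
  valid <- m & is.finite(map$voxels)
  if (!any(valid)) stop("empty mask: no valid voxels for hotspot analysis",
                        call. = FALSE)
  d <- dim(m); h <- window %/% 2L
  vals <- map$voxels
  vals[!valid] <- 0
  best <- -Inf
  if (d[1] >= window && d[2] >= window) {
    rs <- seq.int(1L + h, d[1] - h); cs <- seq.int(1L + h, d[2] - h)
    sums <- array(0, c(length(rs), length(cs), d[3]))
    cnts <- array(0L, c(length(rs), length(cs), d[3]))
    for (dr in -h:h) for (dc in -h:h) {
      sums <- sums + vals[rs + dr, cs + dc, , drop = FALSE]
      cnts <- cnts + valid[rs + dr, cs + dc, , drop = FALSE]
    }
    full <- cnts == window^2
    if (any(full)) best <- max(sums[full]) / window^2
  }
  if (!is.finite(best)) {
    warning("no full ", window, "x", window,
            " window fits inside the mask; falling back to single-voxel max",
            call. = FALSE)
    best <- max(map$voxels[valid])
  }
  best
}

#' Functional tumor volume (FTV)
#'
#' Total volume, in cc, of in-mask voxels with PE at or above the threshold
#' (default 50% enhancement).
#'
#' @param pe_map PE [image_volume()].
#' @param mask `tumor_mask` or logical array.
#' @param threshold PE threshold.
#' @return volume in cc.
#' @export
functional_tumor_volume <- function(pe_map, mask, threshold = 0.50) {
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  stopifnot(identical(dim(m), dim(pe_map$voxels)))
  n <- sum(m & is.finite(pe_map$voxels) & pe_map$voxels >= threshold)
  n * voxel_volume_cc(pe_map)
}

#' Washout volume
#'
#' Total volume, in cc, of tumor voxels with SER at or above the washout
#' threshold (default 1.1). Evaluated within the segmented tumor mask, so
#' washout volume can never exceed the functional tumor volume.
#'
#' @param ser_map SER [image_volume()].
#' @param mask `tumor_mask` or logical array.
#' @param threshold SER washout threshold.
#' @return volume in cc.
#' @export
washout_volume <- function(ser_map, mask, threshold = 1.1) {
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  stopifnot(identical(dim(m), dim(ser_map$voxels)))
  n <- sum(m & is.finite(ser_map$voxels) & ser_map$voxels >= threshold)
  n * voxel_volume_cc(ser_map)
}

#' Longest tumor dimension
#'
#' Maximum pairwise physical distance between mask-voxel centers, in mm.
#' Candidates are reduced to the mask's 6-connected boundary voxels before
#' the pairwise search; the result equals brute force over all voxels.
#'
#' @param mask `tumor_mask` or logical array with a `spacing` attribute
#'   supplied via `spacing`.
#' @param spacing voxel spacing in mm (taken from a `tumor_mask`
#'   automatically).
#' @return longest dimension in mm (0 for a single voxel).
#' @export
longest_dimension <- function(mask, spacing = NULL) {
  if (inherits(mask, "tumor_mask")) {
    spacing <- mask$spacing
    m <- mask$mask
  } else m <- mask
  if (is.null(spacing)) stop("spacing required for a bare logical mask")
  if (!any(m)) stop("empty mask", call. = FALSE)
  d <- dim(m)
  # boundary voxels: at least one 6-neighbor outside the mask (or the grid)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  interior <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  cand <- m & !interior
  co <- arrayInd(which(cand), d)
  xyz <- sweep(co, 2, spacing, `*`)
  if (nrow(xyz) == 1L) return(0)
  max(stats::dist(xyz))
}
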