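#' Summed SUV image from a dynamic PET series
#'
#' Builds the static standardized-uptake-value image by duration-weighted
#' averaging of the dynamic frames inside the summation window (default
#' 30-60 min post injection), then normalizing by injected dose per body
#' weight: `SUV = C[kBq/mL] * weight[kg] / dose[MBq]` (tissue density taken
#' as 1 g/mL). Frames partially overlapping the window contribute their
#' overlap duration.
#'
#' @param series a [dynamic_pet_series()].
#' @param phys a [patient_physiology()].
#' @param window numeric length 2, minutes post injection; must lie within
#'   the acquisition.
#' @return an [image_volume()] of dimensionless SUV.
#' @export
summed_suv_image <- function(series, phys, window = c(30, 60)) {
  stopifnot(inherits(series, "dynamic_pet_series"),
            inherits(phys, "patient_physiology"))
  window <- as.numeric(window)
  if (length(window) != 2L || window[2] <= window[1])
    stop("window must be (start, end) with end > start", call. = FALSE)
  if (window[1] < min(series$frame_start) - 1e-9 ||
      window[2] > max(series$frame_end) + 1e-9)
    stop("SUV window outside acquisition", call. = FALSE)
  ov <- pmin(series$frame_end, window[2]) - pmax(series$frame_start, window[1])
  ov <- pmax(ov, 0)
  if (sum(ov) <= 0) stop("no frames overlap the SUV window", call. = FALSE)
  d <- dim(series$frames[[1]]$voxels)
  acc <- array(0, d)
  for (i in which(ov > 0)) acc <- acc + ov[i] * series$frames[[i]]$voxels
  mean_act <- acc / sum(ov)
  image_volume(mean_act * phys$body_weight_kg / phys$injected_dose_mbq,
               series$frames[[1]]$spacing, allow_na = TRUE)
}

#' Spherical volume of interest
#'
#' Logical membership array for a sphere of a given volume centered on a
#' voxel; the radius is `(3 V / 4 pi)^(1/3)` and membership is by physical
#' distance between voxel centers.
#'
#' @param dims integer grid dimensions.
#' @param spacing voxel spacing, mm.
#' @param center integer (row, col, slice) voxel index of the sphere center.
#' @param volume_cc sphere volume, cc (default 1, the lesion VOI size).
#' @return logical array.
#' @export
spherical_voi <- function(dims, spacing, center, volume_cc = 1) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3L)
  if (any(center < 1) || any(center > dims))
    stop("VOI center outside image", call. = FALSE)
  r <- (3 * volume_cc * 1000 / (4 * pi))^(1 / 3)  # mm
  co <- arrayInd(seq_len(prod(dims)), dims)
  d2 <- ((co[, 1] - center[1]) * spacing[1])^2 +
    ((co[, 2] - center[2]) * spacing[2])^2 +
    ((co[, 3] - center[3]) * spacing[3])^2
  array(d2 <= r^2, dims)
}

#' SUVmax within a lesion VOI
#'
#' Maximum voxel SUV within an approximately 1 cc sphere centered on the
#' lesion — the "pixel with the most uptake" convention.
#'
#' @param suv_image SUV [image_volume()] (from [summed_suv_image()]).
#' @param voi_center integer (row, col, slice) voxel index.
#' @param voi_volume_cc VOI volume, cc.
#' @return list of class `suv_result`: `suvmax`, `voi_center`,
#'   `voi_volume_cc`, `n_voxels`.
#' @export
suvmax_in_voi <- function(suv_image, voi_center, voi_volume_cc = 1) {
  stopifnot(is_image_volume(suv_image))
  voi <- spherical_voi(dim(suv_image$voxels), suv_image$spacing,
                       voi_center, voi_volume_cc)
  vals <- suv_image$voxels[voi]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("VOI contains no valid voxels", call. = FALSE)
  structure(list(suvmax = max(vals), voi_center = voi_center,
                 voi_volume_cc = voi_volume_cc, n_voxels = sum(voi)),
            class = "suv_result")
}

#' @export
print.suv_result <- function(x, ...) {
  cat(sprintf("<suv_result> SUVmax = %.3f in %.2g cc VOI (%d voxels)\n",
              x$suvmax, x$voi_volume_cc, x$n_voxels))
  invisible(x)
}

#' Extract a time-activity curve from a dynamic series
#'
#' Per-frame VOI-mean activity, reported at frame midtimes. The frame timing
#' is attached as attributes so the curve can be passed directly to
#' [fit_two_tissue()].
#'
#' @param series a [dynamic_pet_series()].
#' @param voi logical array on the series grid (e.g. from
#'   [spherical_voi()]).
#' @param label curve label, `"tumor"` or `"blood"`.
#' @return a [tac()].
#' @export
extract_tac <- function(series, voi, label = "tumor") {
  stopifnot(inherits(series, "dynamic_pet_series"))
  stopifnot(identical(dim(voi), dim(series$frames[[1]]$voxels)))
  if (!any(voi)) stop("empty VOI", call. = FALSE)
  act <- vapply(series$frames, function(f) mean(f$voxels[voi]), numeric(1))
  out <- tac((series$frame_start + series$frame_end) / 2, act, label = label,
             clip_negative = TRUE)
  attr(out, "frame_start") <- series$frame_start
  attr(out, "frame_end") <- series$frame_end
  out
}
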