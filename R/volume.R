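#' 3D image volume with physical spacing
#'
#' The basic voxel container used throughout the package: a 3D numeric array
#' plus per-axis physical voxel size in millimetres. Arrays are indexed
#' `[row, col, slice]`; the first two dimensions are in-plane (axial), the
#' third is the slice direction. All "3 x 3" neighborhood operations are
#' in-plane because clinical breast acquisitions are axial with anisotropic
#' slice thickness.
#'
#' `NaN`/`NA` voxels are only permitted inside an explicitly declared mask
#' (see [compute_ser_map()] for an example of masked output); plain input
#' volumes must be finite.
#'
#' @param voxels 3D numeric array.
#' @param spacing numeric length-3, voxel size in mm per axis (row, col,
#'   slice). All entries must be strictly positive.
#' @param allow_na logical; permit non-finite voxels (used by map outputs
#'   that carry an explicit validity mask).
#' @return An object of class `image_volume`: a list with elements `voxels`,
#'   `spacing` and `axes` (fixed tag `"RCS"` for row/col/slice ordering).
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), allow_na = FALSE) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("non-3D payload: `voxels` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)", call. = FALSE)
  if (!allow_na && any(!is.finite(voxels)))
    stop("voxel array contains non-finite values outside a declared mask",
         call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, axes = "RCS"),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  v <- x$voxels[is.finite(x$voxels)]
  if (length(v))
    cat(sprintf("  range: [%g, %g], %d non-finite\n", min(v), max(v),
                sum(!is.finite(x$voxels))))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

is_image_volume <- function(x) inherits(x, "image_volume")

#' Voxel volume in cc
#'
#' @param vol an `image_volume` (or anything with a `spacing` element in mm).
#' @return voxel volume in cubic centimetres.
#' @export
voxel_volume_cc <- function(vol) prod(vol$spacing) / 1000

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop(sprintf("grid mismatch: %s have different dimensions", what),
         call. = FALSE)
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop(sprintf("grid mismatch: %s have different spacing", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' Wraps [RNifti::readNifti()]; enforces a 3D payload and positive spacing,
#' and returns the package's [image_volume()] container. NIfTI stores voxels
#' in (i, j, k) order, which maps directly onto the package's
#' row/col/slice convention (k = axial slice).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return an [image_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.numeric(img), dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("non-3D payload in ", path, call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in ", path, call. = FALSE)
  image_volume(array(as.numeric(img), dim = d), spacing = sp)
}

#' Write an [image_volume()] to a NIfTI-1 file
#'
#' @param vol an `image_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_image_volume(vol))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Dynamic PET frame series
#'
#' An ordered series of 3D activity volumes with per-frame start/end times in
#' minutes post injection. Frames must be strictly ordered and
#' non-overlapping. Activity units are kBq/mL throughout; volumes are assumed
#' decay-corrected to injection time unless flagged otherwise.
#'
#' @param frames list of [image_volume()] on a common grid.
#' @param frame_start,frame_end numeric vectors, minutes post injection.
#' @param decay_corrected logical flag carried as metadata.
#' @return an object of class `dynamic_pet_series`.
#' @export
dynamic_pet_series <- function(frames, frame_start, frame_end,
                               decay_corrected = TRUE) {
  if (!length(frames) || !all(vapply(frames, is_image_volume, logical(1))))
    stop("`frames` must be a non-empty list of image_volume", call. = FALSE)
  n <- length(frames)
  frame_start <- as.numeric(frame_start); frame_end <- as.numeric(frame_end)
  if (length(frame_start) != n || length(frame_end) != n)
    stop("frame timing length must match number of frames", call. = FALSE)
  if (any(frame_end <= frame_start))
    stop("frame_end must exceed frame_start for every frame", call. = FALSE)
  if (n > 1 && any(frame_start[-1] < frame_end[-n] - 1e-9))
    stop("frames must be strictly ordered and non-overlapping", call. = FALSE)
  for (i in seq_len(n)[-1]) stop_if_grid_mismatch(frames[[1]], frames[[i]],
                                                  "PET frames")
  structure(list(frames = frames, frame_start = frame_start,
                 frame_end = frame_end, decay_corrected = decay_corrected),
            class = "dynamic_pet_series")
}

#' @export
print.dynamic_pet_series <- function(x, ...) {
  cat(sprintf("<dynamic_pet_series> %d frames, %.1f-%.1f min%s\n",
              length(x$frames), min(x$frame_start), max(x$frame_end),
              if (x$decay_corrected) ", decay-corrected" else ""))
  invisible(x)
}

#' Time-activity curve
#'
#' Region-mean tracer activity versus time. The blood (left-ventricle) curve
#' serves as the model input function for kinetic fitting.
#'
#' @param midtimes minutes post injection, strictly increasing.
#' @param activity kBq/mL. Small negative excursions can be clipped to zero
#'   with `clip_negative = TRUE` (a declared option, never silent).
#' @param label `"tumor"` or `"blood"`.
#' @param clip_negative logical; clip negative activities to 0.
#' @return object of class `tac`: data.frame-like list with `midtimes`,
#'   `activity`, `label`.
#' @export
tac <- function(midtimes, activity, label = c("tumor", "blood"),
                clip_negative = FALSE) {
  label <- match.arg(label)
  midtimes <- as.numeric(midtimes); activity <- as.numeric(activity)
  if (length(midtimes) != length(activity))
    stop("midtimes and activity must have equal length", call. = FALSE)
  if (length(midtimes) > 1 && any(diff(midtimes) <= 0))
    stop("midtimes must be strictly increasing", call. = FALSE)
  if (clip_negative) activity <- pmax(activity, 0)
  if (any(activity < 0))
    stop("negative activity; pass clip_negative = TRUE to clip noise",
         call. = FALSE)
  structure(list(midtimes = midtimes, activity = activity, label = label),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac:%s> %d samples, %.2f-%.2f min, peak %.3g kBq/mL\n",
              x$label, length(x$midtimes),
              min(x$midtimes), max(x$midtimes), max(x$activity)))
  invisible(x)
}

#' Patient physiology needed for SUV and MRFDG
#'
#' @param injected_dose_mbq injected FDG dose, MBq (> 0).
#' @param body_weight_kg body weight, kg (> 0).
#' @param plasma_glucose plasma glucose concentration (> 0), in
#'   `glucose_unit`; may be `NA` when PET kinetics are not quantified.
#' @param glucose_unit `"mmol/L"` or `"mg/dL"`; carried as declared metadata,
#'   never converted silently.
#' @return object of class `patient_physiology`.
#' @export
patient_physiology <- function(injected_dose_mbq, body_weight_kg,
                               plasma_glucose = NA_real_,
                               glucose_unit = c("mmol/L", "mg/dL")) {
  glucose_unit <- match.arg(glucose_unit)
  if (!is.finite(injected_dose_mbq) || injected_dose_mbq <= 0)
    stop("injected_dose_mbq must be > 0", call. = FALSE)
  if (!is.finite(body_weight_kg) || body_weight_kg <= 0)
    stop("body_weight_kg must be > 0", call. = FALSE)
  if (is.finite(plasma_glucose) && plasma_glucose <= 0)
    stop("plasma_glucose must be > 0 when present", call. = FALSE)
  structure(list(injected_dose_mbq = injected_dose_mbq,
                 body_weight_kg = body_weight_kg,
                 plasma_glucose = plasma_glucose,
                 glucose_unit = glucose_unit),
            class = "patient_physiology")
}

rcb_levels <- c("0", "I", "II", "III", "metastasis_pre_surgery")

#' Pathological response and survival outcome for one patient
#'
#' Residual cancer burden (RCB) class after surgery, and recurrence-free
#' survival (RFS): time from chemotherapy initiation to recurrence or death.
#' Patients with RCB 0/I are "responders"; patients who developed metastases
#' before surgery are grouped with RCB II/III.
#'
#' @param rcb_class one of `"0"`, `"I"`, `"II"`, `"III"`,
#'   `"metastasis_pre_surgery"`.
#' @param rfs_time years, > 0.
#' @param rfs_event logical; `TRUE` = recurrence or death observed.
#' @return object of class `patient_outcome`.
#' @export
patient_outcome <- function(rcb_class, rfs_time, rfs_event) {
  rcb_class <- as.character(rcb_class)
  if (!rcb_class %in% rcb_levels)
    stop("unknown RCB class: ", rcb_class, call. = FALSE)
  if (!is.finite(rfs_time) || rfs_time <= 0)
    stop("rfs_time must be > 0 (years)", call. = FALSE)
  structure(list(rcb_class = rcb_class, rfs_time = as.numeric(rfs_time),
                 rfs_event = isTRUE(as.logical(rfs_event))),
            class = "patient_outcome")
}

#' Responder flag from RCB class
#'
#' @param rcb_class character vector of RCB classes.
#' @return logical: `TRUE` for RCB 0/I, `FALSE` for II/III and metastases
#'   before surgery, `NA` for missing.
#' @export
is_responder <- function(rcb_class) {
  rcb_class <- as.character(rcb_class)
  out <- rep(NA, length(rcb_class))
  known <- !is.na(rcb_class) & rcb_class %in% rcb_levels
  out[known] <- rcb_class[known] %in% c("0", "I")
  out
}
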