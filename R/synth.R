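#' Digital phantom specification
#'
#' Describes a tumor-bearing digital phantom: a rectangular grid with a
#' spherical "tumor" of prescribed enhancement kinetics, diffusion, and FDG
#' kinetics against a uniform background. The phantom is the ground truth
#' for every quantification stage: constructed noiselessly, the downstream
#' PE/SER/ADC/kinetic estimators invert it exactly.
#'
#' Voxel membership in the tumor is by physical distance from the center
#' voxel: `<= radius_mm`. On the default 1 mm isotropic grid with a 5 mm
#' radius this gives the 515-voxel digital sphere.
#'
#' @param dims grid dimensions (row, col, slice), voxels.
#' @param spacing voxel spacing, mm.
#' @param center tumor center voxel index; default the grid midpoint.
#' @param radius_mm tumor radius, mm.
#' @param pe_tumor,pe_background true percent enhancement (fraction).
#' @param ser_tumor,ser_background true signal enhancement ratio.
#' @param adc_tumor,adc_background true ADC, mm^2/s.
#' @param kinetics_tumor,kinetics_background [two_tissue_params()].
#' @param s0_dce,s0_dwi baseline signal levels (a.u.).
#' @param noise_sd Gaussian noise SD relative to the baseline signal
#'   (0 = noiseless).
#' @param dwi_noise `"gaussian"` or `"rician"` noise model for DWI.
#' @param seed RNG seed fixing all randomness of the phantom.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(32, 32, 16), spacing = c(1, 1, 1),
                         center = NULL, radius_mm = 5,
                         pe_tumor = 0.8, pe_background = 0.1,
                         ser_tumor = 1.3, ser_background = 0.5,
                         adc_tumor = 1.0e-3, adc_background = 2.0e-3,
                         kinetics_tumor = two_tissue_params(0.1, 0.2, 0.05),
                         kinetics_background = two_tissue_params(0.02, 0.3,
                                                                 0.005),
                         s0_dce = 100, s0_dwi = 1000,
                         noise_sd = 0, dwi_noise = c("gaussian", "rician"),
                         seed = 1L) {
  dwi_noise <- match.arg(dwi_noise)
  dims <- as.integer(dims); spacing <- as.numeric(spacing)
  if (is.null(center)) center <- ceiling(dims / 2)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  ext <- (dims - 1) * spacing
  if (any((center - 1) * spacing < radius_mm - 1e-9) ||
      any((dims - center) * spacing < radius_mm - 1e-9))
    stop("tumor sphere does not fit inside the grid", call. = FALSE)
  structure(list(dims = dims, spacing = spacing, center = center,
                 radius_mm = radius_mm, pe_tumor = pe_tumor,
                 pe_background = pe_background, ser_tumor = ser_tumor,
                 ser_background = ser_background, adc_tumor = adc_tumor,
                 adc_background = adc_background,
                 kinetics_tumor = kinetics_tumor,
                 kinetics_background = kinetics_background,
                 s0_dce = s0_dce, s0_dwi = s0_dwi, noise_sd = noise_sd,
                 dwi_noise = dwi_noise, seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_mask <- function(spec) {
  co <- arrayInd(seq_len(prod(spec$dims)), spec$dims)
  d2 <- ((co[, 1] - spec$center[1]) * spec$spacing[1])^2 +
    ((co[, 2] - spec$center[2]) * spec$spacing[2])^2 +
    ((co[, 3] - spec$center[3]) * spec$spacing[3])^2
  array(d2 <= spec$radius_mm^2, spec$dims)
}

region_array <- function(spec, tumor_value, background_value) {
  m <- phantom_mask(spec)
  arr <- array(background_value, spec$dims)
  arr[m] <- tumor_value
  arr
}

#' DCE-MRI phantom: pre-contrast and two post-contrast phases
#'
#' Constructs S0 (pre-contrast), S1 (2 min) and S2 (8 min) volumes whose
#' noiseless voxel-wise PE and SER equal the prescribed regional truths by
#' inverting the definitions: `S1 = S0 (1 + PE)`,
#' `S2 = S0 + (S1 - S0)/SER`. A prescribed SER of 0 would require infinite
#' delayed signal and is rejected as degenerate.
#'
#' @param spec a [phantom_spec()].
#' @return list: `s0`, `s1`, `s2` ([image_volume()]s) and `truth_mask`
#'   (logical array of the true tumor).
#' @export
make_dce_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$ser_tumor == 0 || spec$ser_background == 0)
    stop("prescribed SER of 0 is degenerate (requires S2 = S0 exactly)",
         call. = FALSE)
  mask <- phantom_mask(spec)
  s0 <- array(spec$s0_dce, spec$dims)
  pe <- region_array(spec, spec$pe_tumor, spec$pe_background)
  ser <- region_array(spec, spec$ser_tumor, spec$ser_background)
  s1 <- s0 * (1 + pe)
  s2 <- s0 + (s1 - s0) / ser
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    n <- prod(spec$dims)
    sd <- spec$noise_sd * spec$s0_dce
    s0 <- s0 + array(stats::rnorm(n, 0, sd), spec$dims)
    s1 <- s1 + array(stats::rnorm(n, 0, sd), spec$dims)
    s2 <- s2 + array(stats::rnorm(n, 0, sd), spec$dims)
  }
  list(s0 = image_volume(s0, spec$spacing),
       s1 = image_volume(s1, spec$spacing),
       s2 = image_volume(s2, spec$spacing),
       truth_mask = mask)
}

#' DW-MRI phantom across b-values
#'
#' Noiseless signals follow the monoexponential model
#' `S(b) = S(0) exp(-b * ADC)` with the regional true ADC. Optional Gaussian
#' or Rician noise (the magnitude-image noise model,
#' `sqrt((S + n1)^2 + n2^2)`).
#'
#' @param spec a [phantom_spec()].
#' @param b_values s/mm^2.
#' @return list: `volumes` (list of [image_volume()], one per b),
#'   `b_values`, `truth_mask`.
#' @export
make_dwi_phantom <- function(spec, b_values = c(0, 100, 800)) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$adc_tumor < 0 || spec$adc_background < 0)
    stop("prescribed ADC must be >= 0", call. = FALSE)
  adc <- region_array(spec, spec$adc_tumor, spec$adc_background)
  set.seed(spec$seed + 1L)
  n <- prod(spec$dims)
  sd <- spec$noise_sd * spec$s0_dwi
  vols <- lapply(b_values, function(b) {
    s <- spec$s0_dwi * exp(-b * adc)
    if (spec$noise_sd > 0) {
      if (spec$dwi_noise == "rician") {
        s <- sqrt((s + stats::rnorm(n, 0, sd))^2 + stats::rnorm(n, 0, sd)^2)
      } else {
        s <- s + stats::rnorm(n, 0, sd)
      }
      s <- array(s, spec$dims)
    }
    image_volume(s, spec$spacing)
  })
  list(volumes = vols, b_values = b_values, truth_mask = phantom_mask(spec))
}

#' Parametric arterial input function specification
#'
#' A tri-exponential Feng-type model of the blood time-activity curve:
#' `Cp(t) = (A1 t - A2 - A3) exp(-l1 t) + A2 exp(-l2 t) + A3 exp(-l3 t)`
#' for `t` past the arrival delay, 0 before. Smooth, non-negative for the
#' default coefficients, and peaking within the first two minutes —
#' the shape of a left-ventricle FDG input. The default coefficients are
#' configuration choices of this generator, not claims about any patient.
#'
#' @param A numeric length 3: amplitudes (kBq/mL/min, kBq/mL, kBq/mL).
#' @param lambda numeric length 3: decay constants, 1/min.
#' @param delay tracer arrival delay, min.
#' @param times sampling midtimes, min (non-empty).
#' @return list of class `input_function_spec`.
#' @export
input_function_spec <- function(A = c(851.1, 21.9, 20.8),
                                lambda = c(4.1339, 0.1191, 0.0104),
                                delay = 0.25,
                                times = seq(0.05, 62, by = 0.05)) {
  if (!length(times)) stop("empty time grid", call. = FALSE)
  stopifnot(length(A) == 3L, length(lambda) == 3L)
  structure(list(A = as.numeric(A), lambda = as.numeric(lambda),
                 delay = delay, times = as.numeric(times)),
            class = "input_function_spec")
}

feng_curve <- function(t, A, lambda, delay) {
  tt <- t - delay
  out <- numeric(length(t))
  on <- tt > 0
  out[on] <- (A[1] * tt[on] - A[2] - A[3]) * exp(-lambda[1] * tt[on]) +
    A[2] * exp(-lambda[2] * tt[on]) + A[3] * exp(-lambda[3] * tt[on])
  out
}

#' Simulate a blood input function
#'
#' Evaluates the [input_function_spec()] model on its sampling grid. Small
#' negative excursions (possible for extreme coefficient choices) are
#' clipped to zero, which the returned [tac()] declares.
#'
#' @param spec an [input_function_spec()].
#' @return a [tac()] with label `"blood"`.
#' @export
simulate_input_function <- function(spec) {
  stopifnot(inherits(spec, "input_function_spec"))
  act <- feng_curve(spec$times, spec$A, spec$lambda, spec$delay)
  tac(spec$times, act, label = "blood", clip_negative = TRUE)
}

#' Default dynamic PET frame timing
#'
#' A 60-min dynamic acquisition binned as 4 x 0.5, 4 x 1, 2 x 2, 4 x 5 and
#' 3 x 10 min frames (17 frames) — fine early sampling for the input-function
#' peak, coarse late frames for count statistics.
#'
#' @return list with `start` and `end` vectors, minutes.
#' @export
default_frame_timing <- function() {
  dur <- c(rep(0.5, 4), rep(1, 4), rep(2, 2), rep(5, 4), rep(10, 3))
  end <- cumsum(dur)
  list(start = end - dur, end = end)
}

#' Dynamic PET phantom
#'
#' Builds a dynamic frame series in which tumor voxels follow the
#' frame-averaged two-tissue tissue curve of `spec$kinetics_tumor` and
#' background voxels that of `spec$kinetics_background`, both driven by the
#' supplied blood input function. Optional Gaussian noise with variance
#' proportional to activity over frame duration (a standard
#' reconstruction-domain approximation): the noise SD at the curve peak for
#' a mean-duration frame equals `spec$noise_sd` times the peak activity.
#'
#' @param spec a [phantom_spec()].
#' @param cp blood input [tac()]; default the standard
#'   [simulate_input_function()] curve.
#' @param timing frame timing list as from [default_frame_timing()].
#' @return list: `series` ([dynamic_pet_series()]), `cp`, `truth_mask`,
#'   `tumor_tac` (the noiseless frame-averaged truth).
#' @export
make_pet_phantom <- function(spec,
                             cp = simulate_input_function(input_function_spec()),
                             timing = default_frame_timing()) {
  stopifnot(inherits(spec, "phantom_spec"))
  tum <- simulate_tumor_tac(spec$kinetics_tumor, cp, timing$start, timing$end)
  bg <- simulate_tumor_tac(spec$kinetics_background, cp, timing$start,
                           timing$end)
  mask <- phantom_mask(spec)
  dur <- timing$end - timing$start
  peak <- max(tum$activity)
  set.seed(spec$seed + 2L)
  frames <- lapply(seq_along(timing$start), function(i) {
    arr <- array(bg$activity[i], spec$dims)
    arr[mask] <- tum$activity[i]
    if (spec$noise_sd > 0 && peak > 0) {
      sd <- spec$noise_sd * sqrt(pmax(arr, 0) * peak * mean(dur) / dur[i])
      arr <- arr + array(stats::rnorm(length(arr), 0, as.vector(sd)),
                         spec$dims)
    }
    image_volume(arr, spec$spacing)
  })
  list(series = dynamic_pet_series(frames, timing$start, timing$end),
       cp = cp, truth_mask = mask, tumor_tac = tum)
}

#' Add measurement noise to a simulated time-activity curve
#'
#' Gaussian noise at the TAC level with per-frame-relative SD: each frame's
#' activity receives noise with SD equal to `noise_frac` times that frame's
#' activity ("5% noise" = every measurement has 5% error). The image-domain
#' phantom ([make_pet_phantom()]) uses the count-statistics-like model
#' (variance proportional to activity/frame-duration) instead; this
#' curve-level model is the conventional one for kinetic parameter-recovery
#' studies.
#'
#' @param curve a [tac()] with frame timing attributes.
#' @param noise_frac relative noise level per frame.
#' @param seed RNG seed.
#' @return a [tac()] with noisy (clipped non-negative) activities.
#' @export
noisy_tac <- function(curve, noise_frac, seed) {
  stopifnot(inherits(curve, "tac"))
  fs <- attr(curve, "frame_start"); fe <- attr(curve, "frame_end")
  if (is.null(fs) || is.null(fe))
    stop("curve lacks frame timing attributes", call. = FALSE)
  set.seed(seed)
  act <- curve$activity *
    (1 + stats::rnorm(length(curve$activity), 0, noise_frac))
  out <- tac(curve$midtimes, pmax(act, 0), label = curve$label)
  attr(out, "frame_start") <- fs
  attr(out, "frame_end") <- fe
  out
}
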