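# shared fixtures built in code; no binary data anywhere

vol3 <- function(values, dims = c(4, 4, 2), spacing = c(1, 1, 1)) {
  image_volume(array(values, dim = dims), spacing = spacing)
}

# standard blood input function and frame timing used across kinetic tests
shared_cp <- simulate_input_function(input_function_spec())
shared_timing <- default_frame_timing()

# independent fine-grid numerical convolution oracle for the two-tissue
# forward model (discrete convolution + trapezoid frame averaging)
oracle_tumor_tac <- function(params, cp, frame_start, frame_end,
                             dt = 0.005) {
  tg <- seq(0, max(frame_end), by = dt)
  cpg <- stats::approx(c(0, cp$midtimes), c(0, cp$activity), tg,
                       rule = 2)$y
  a <- params$k2 + params$k3
  h <- if (a == 0) rep(params$k1, length(tg))
       else params$k1 * (params$k3 + params$k2 * exp(-a * tg)) / a
  ct <- stats::convolve(cpg, rev(h), type = "open")[seq_along(tg)] * dt
  ct <- ct + params$vb * cpg
  vapply(seq_along(frame_start), function(i) {
    sel <- tg >= frame_start[i] - 1e-12 & tg <= frame_end[i] + 1e-12
    xs <- tg[sel]; ys <- ct[sel]
    sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2) /
      (xs[length(xs)] - xs[1])
  }, numeric(1))
}

# exhaustive in-plane window enumeration oracle for hotspot peaks
oracle_hotspot <- function(map, mask, window = 3L) {
  d <- dim(mask); h <- window %/% 2L
  valid <- mask & is.finite(map)
  best <- -Inf
  for (s in seq_len(d[3]))
    for (r in seq_len(d[1] - window + 1L))
      for (cc in seq_len(d[2] - window + 1L)) {
        rows <- r:(r + window - 1L); cols <- cc:(cc + window - 1L)
        if (all(valid[rows, cols, s]))
          best <- max(best, mean(map[rows, cols, s]))
      }
  if (!is.finite(best)) best <- max(map[valid])
  best
}

# a null cohort specification: identical change distributions in both RCB
# groups and no hazard linkage
null_cohort_spec <- function(n_per_group = 25, n_metrics = 1,
                             baseline_hazard = 0.15) {
  eff <- data.frame(metric = paste0("m", seq_len(n_metrics)),
                    timepoint = "mid",
                    mean_responder = 0, sd_responder = 10,
                    mean_nonresponder = 0, sd_nonresponder = 10)
  cohort_effect_spec(n_responders = n_per_group,
                     n_nonresponders = n_per_group, effects = eff,
                     hazard_metric = "m1", log_hr_per_unit = 0,
                     baseline_hazard = baseline_hazard)
}

# in-memory synthetic study: 3 responders and 3 non-responders imaged at
# baseline/mid/post with treatment effect applied to all modalities
make_study_fixture <- function(seed = 7L) {
  shrink <- list(baseline = c(1, 1), mid = c(0.5, 0.85),
                 post = c(0.2, 0.6))  # responders, non-responders
  phys <- patient_physiology(370, 70, 5.0)
  outcomes <- list(
    list(rcb_class = "0", rfs_time = 8, rfs_event = 0),
    list(rcb_class = "I", rfs_time = 9, rfs_event = 0),
    list(rcb_class = "0", rfs_time = 7, rfs_event = 0),
    list(rcb_class = "II", rfs_time = 3, rfs_event = 1),
    list(rcb_class = "III", rfs_time = 2, rfs_event = 1),
    list(rcb_class = "II", rfs_time = 5, rfs_event = 0))
  patients <- list()
  for (i in 1:6) {
    resp <- i <= 3
    tps <- list()
    for (tp in c("baseline", "mid", "post")) {
      f <- shrink[[tp]][if (resp) 1 else 2] + 0.02 * i
      sd_seed <- seed + 100L * i + match(tp, c("baseline", "mid", "post"))
      spc <- phantom_spec(dims = c(24, 24, 12), spacing = c(1, 1, 2),
                          center = c(12, 12, 6),
                          radius_mm = 3 + 2 * min(f, 1),
                          pe_tumor = 0.55 + 0.35 * f, pe_background = 0.1,
                          ser_tumor = 1.0 + 0.4 * f, ser_background = 0.5,
                          adc_tumor = 1.0e-3 * (1 + 0.5 * (1 - f)),
                          noise_sd = 0.01, seed = sd_seed)
      dce <- make_dce_phantom(spc)
      dwi <- make_dwi_phantom(spc)
      pet_spec <- phantom_spec(dims = c(12, 12, 9), spacing = c(2, 2, 2),
                               center = c(6, 6, 5), radius_mm = 6.5,
                               kinetics_tumor = two_tissue_params(
                                 0.12 * (0.3 + 0.7 * f), 0.25,
                                 0.06 * (0.2 + 0.8 * f)),
                               noise_sd = 0.01, seed = sd_seed + 50L)
      pet <- make_pet_phantom(pet_spec)
      tps[[tp]] <- list(
        dce = list(s0 = dce$s0, s1 = dce$s1, s2 = dce$s2),
        dwi = list(volumes = dwi$volumes, b_values = dwi$b_values),
        pet = list(series = pet$series, cp = pet$cp, phys = phys,
                   voi_center = pet_spec$center))
    }
    patients[[sprintf("P%02d", i)]] <-
      list(outcome = outcomes[[i]], timepoints = tps)
  }
  list(patients = patients)
}
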