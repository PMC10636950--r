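#' Quantify one patient at one timepoint
#'
#' Runs every applicable quantification stage on the imaging available for
#' one visit and assembles a single row of lesion metrics. Modalities are
#' independent: a failure in one stage (e.g. a corrupt PET timing file)
#' is logged into the row's `errors` attribute and its metrics left
#' missing, while the other modalities still produce results — mirroring
#' real cohorts, where per-metric sample sizes differ.
#'
#' @param inputs list with any of:
#'   \describe{
#'     \item{dce}{list `s0`, `s1`, `s2`: [image_volume()]s or NIfTI paths;
#'       optional `seed_point` (row, col, slice).}
#'     \item{dwi}{list `volumes` (list of volumes/paths), `b_values`,
#'       optional `roi` (logical array; default: the DCE tumor mask).}
#'     \item{pet}{list `series` ([dynamic_pet_series()]), `cp` (blood
#'       [tac()]), `phys` ([patient_physiology()]), optional `voi_center`
#'       (default: the hottest voxel of the summed SUV image).}
#'   }
#' @param config an [mpq_config()].
#' @return one-row data.frame of lesion metrics (`peak_pe`, `peak_ser`,
#'   `ftv`, `washout_volume`, `longest_dimension`, `mean_adc`, `suvmax`,
#'   `k1`, `k2`, `k3`, `ki`, `mrfdg` and the five mismatch ratios), `NA`
#'   where unavailable; stage errors in `attr(, "errors")`.
#' @export
quantify_patient <- function(inputs, config = mpq_config()) {
  if (!any(c("dce", "dwi", "pet") %in% names(inputs)))
    stop("no usable modality: supply at least one of dce, dwi, pet",
         call. = FALSE)
  met <- list(peak_pe = NA_real_, peak_ser = NA_real_, ftv = NA_real_,
              washout_volume = NA_real_, longest_dimension = NA_real_,
              mean_adc = NA_real_, suvmax = NA_real_, k1 = NA_real_,
              k2 = NA_real_, k3 = NA_real_, ki = NA_real_,
              mrfdg = NA_real_)
  errors <- character()
  as_vol <- function(x) if (is.character(x)) read_volume(x) else x
  tumor_mask <- NULL

  if (!is.null(inputs$dce)) {
    res <- tryCatch({
      d <- inputs$dce
      s0 <- as_vol(d$s0); s1 <- as_vol(d$s1); s2 <- as_vol(d$s2)
      pe <- compute_pe_map(s0, s1)
      ser <- compute_ser_map(s0, s1, s2, epsilon = config$ser_epsilon)
      mask <- segment_tumor(pe, threshold = config$pe_threshold,
                            seed_point = d$seed_point)
      if (mask$lesion_found) {
        tumor_mask <- mask
        met$peak_pe <- hotspot_peak(pe, mask, config$hotspot_window)
        met$peak_ser <- tryCatch(
          hotspot_peak(ser, mask, config$hotspot_window),
          error = function(e) NA_real_)
        met$ftv <- functional_tumor_volume(pe, mask, config$pe_threshold)
        met$washout_volume <- washout_volume(ser, mask,
                                             config$ser_threshold)
        met$longest_dimension <- longest_dimension(mask)
      }
      NULL
    }, error = function(e) paste0("dce: ", conditionMessage(e)))
    if (!is.null(res)) errors <- c(errors, res)
  }

  if (!is.null(inputs$dwi)) {
    res <- tryCatch({
      d <- inputs$dwi
      vols <- lapply(d$volumes, as_vol)
      fit <- fit_adc(vols, d$b_values %||% config$adc_b_values)
      roi <- d$roi %||% (if (!is.null(tumor_mask)) tumor_mask$mask)
      if (is.null(roi)) stop("no ROI for ADC and no DCE mask available")
      met$mean_adc <- roi_mean_adc(fit, roi)$mean_adc
      NULL
    }, error = function(e) paste0("dwi: ", conditionMessage(e)))
    if (!is.null(res)) errors <- c(errors, res)
  }

  if (!is.null(inputs$pet)) {
    res <- tryCatch({
      p <- inputs$pet
      suv <- summed_suv_image(p$series, p$phys, window = config$suv_window)
      ctr <- p$voi_center %||% arrayInd(which.max(suv$voxels),
                                        dim(suv$voxels))[1, ]
      met$suvmax <- suvmax_in_voi(suv, ctr, config$voi_volume_cc)$suvmax
      voi <- spherical_voi(dim(suv$voxels), suv$spacing, ctr,
                           config$voi_volume_cc)
      tt <- extract_tac(p$series, voi)
      fit <- fit_two_tissue(tt, p$cp, fit_vb = config$fit_vb,
                            upper = config$kinetic_upper,
                            dt = config$kinetic_dt)
      cf <- coef(fit)
      if (!fit$degenerate && all(is.finite(cf))) {
        met$k1 <- cf[["k1"]]; met$k2 <- cf[["k2"]]
        met$k3 <- cf[["k3"]]; met$ki <- cf[["ki"]]
        if (is.finite(p$phys$plasma_glucose))
          met$mrfdg <- metabolic_rate_fdg(fit, p$phys,
                                          expected_unit =
                                            config$glucose_unit)
      }
      NULL
    }, error = function(e) paste0("pet: ", conditionMessage(e)))
    if (!is.null(res)) errors <- c(errors, res)
  }

  out <- as.data.frame(c(met, mismatch_ratios(met)))
  attr(out, "errors") <- errors
  for (e in errors) mpq_log("quantify_patient", "%s", e)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full imaging study end to end
#'
#' Per-patient, per-timepoint quantification, percent changes from baseline,
#' mismatch ratios, and the full cohort statistics — with per-patient
#' failure isolation and a run manifest for provenance. Rerunning with the
#' same inputs and configuration produces bit-identical output files (all
#' numeric output is written with a pinned float format).
#'
#' @param study list with element `patients`: a named list, one entry per
#'   patient, each a list with `outcome` (list `rcb_class`, `rfs_time`,
#'   `rfs_event`) and `timepoints` (named list `baseline` / `mid` / `post`
#'   of [quantify_patient()] input lists).
#' @param out_dir optional output directory; writes `metrics.csv`,
#'   `cohort.csv`, `stats.csv` and `manifest.yaml`.
#' @param config an [mpq_config()].
#' @return list of class `mpq_study`: `metrics` (long per-visit table),
#'   `cohort` (wide per-patient table with percent changes), `report`
#'   ([run_full_analysis()] result), `manifest`.
#' @export
run_study <- function(study, out_dir = NULL, config = mpq_config()) {
  if (is.null(study$patients) || !length(study$patients))
    stop("no patients in study manifest", call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  metric_names <- c("peak_pe", "peak_ser", "ftv", "washout_volume",
                    "longest_dimension", "mean_adc", "suvmax", "k1", "k2",
                    "k3", "ki", "mrfdg", "mrfdg_peak_pe", "mrfdg_peak_ser",
                    "mrfdg_k1", "suvmax_peak_pe", "suvmax_peak_ser")
  rows <- list(); errs <- list()
  for (pid in names(study$patients)) {
    pat <- study$patients[[pid]]
    for (tp in names(pat$timepoints)) {
      row <- tryCatch(quantify_patient(pat$timepoints[[tp]], config),
                      error = function(e) {
                        errs[[length(errs) + 1L]] <<-
                          sprintf("%s/%s: %s", pid, tp, conditionMessage(e))
                        NULL
                      })
      if (is.null(row)) next
      ev <- attr(row, "errors")
      if (length(ev))
        errs <- c(errs, as.list(sprintf("%s/%s: %s", pid, tp, ev)))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(patient_id = pid, timepoint = tp,
                   stringsAsFactors = FALSE), row)
    }
  }
  if (!length(rows)) stop("no patient/timepoint produced metrics",
                          call. = FALSE)
  metrics <- do.call(rbind, rows)

  # wide per-patient cohort table with percent changes
  cohort <- data.frame(patient_id = names(study$patients),
                       stringsAsFactors = FALSE)
  cohort$rcb_class <- vapply(study$patients, function(p)
    as.character(p$outcome$rcb_class %||% NA_character_), character(1))
  cohort$rfs_time <- vapply(study$patients, function(p)
    as.numeric(p$outcome$rfs_time %||% NA_real_), numeric(1))
  cohort$rfs_event <- vapply(study$patients, function(p)
    as.numeric(p$outcome$rfs_event %||% NA_real_), numeric(1))
  for (m in metric_names) for (tp in c("baseline", "mid", "post")) {
    v <- metrics[[m]][match(paste(cohort$patient_id, tp),
                            paste(metrics$patient_id, metrics$timepoint))]
    if (all(is.na(v))) next
    cohort[[paste0(m, "_", tp)]] <- v
  }
  for (m in metric_names) for (tp in c("mid", "post")) {
    bcol <- paste0(m, "_baseline"); fcol <- paste0(m, "_", tp)
    if (all(c(bcol, fcol) %in% names(cohort)))
      cohort[[paste0("chg_", tp, "_", m)]] <-
        percent_change(cohort[[bcol]], cohort[[fcol]])
  }
  cohort <- validate_cohort(cohort)
  report <- run_full_analysis(cohort, config)

  manifest <- list(
    package_version = as.character(utils::packageVersion("mpq")),
    n_patients = length(study$patients),
    config = unclass(config),
    errors = unlist(errs),
    elapsed_sec = round(proc.time()[["elapsed"]] - t0, 3))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_table(metrics, file.path(out_dir, "metrics.csv"))
    write_cohort_table(cohort, file.path(out_dir, "cohort.csv"))
    write_cohort_table(report$stats, file.path(out_dir, "stats.csv"))
    man <- manifest; man$elapsed_sec <- NULL  # timings vary run to run
    yaml::write_yaml(man, file.path(out_dir, "manifest.yaml"))
  }
  structure(list(metrics = metrics, cohort = cohort, report = report,
                 manifest = manifest),
            class = "mpq_study")
}

#' @export
print.mpq_study <- function(x, ...) {
  cat(sprintf("<mpq_study> %d patients, %d visit rows, %d stage error(s)\n",
              x$manifest$n_patients, nrow(x$metrics),
              length(x$manifest$errors)))
  print(x$report)
  invisible(x)
}
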