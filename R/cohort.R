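#' Read a per-patient cohort table from CSV
#'
#' The cohort table has one row per patient: an id, outcome columns
#' (`rcb_class`, `rfs_time` in years, `rfs_event` 0/1), and any number of
#' metric columns. Metric columns follow the naming scheme
#' `<metric>_<timepoint>` for raw values (timepoints `baseline`, `mid`,
#' `post`) and `chg_<timepoint>_<metric>` for percent changes from baseline.
#' Missing cells are kept as `NA`, never dropped: per-metric analysis sample
#' sizes follow from missingness, mirroring real cohorts where not every
#' patient has every modality at every visit.
#'
#' @param path CSV file path.
#' @return a `data.frame` with a `responder` logical column derived from
#'   `rcb_class` (RCB 0/I = responder; metastases before surgery grouped
#'   with II/III).
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  validate_cohort(df)
}

#' Validate (and annotate) a cohort data.frame
#'
#' @param df data.frame with at least `patient_id`, `rcb_class`, `rfs_time`,
#'   `rfs_event` columns.
#' @return the validated data.frame with a derived `responder` column.
#' @export
validate_cohort <- function(df) {
  req <- c("patient_id", "rcb_class", "rfs_time", "rfs_event")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("cohort table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$rcb_class <- as.character(df$rcb_class)
  bad <- !is.na(df$rcb_class) & !df$rcb_class %in% rcb_levels
  if (any(bad))
    stop("unknown RCB label(s): ",
         paste(unique(df$rcb_class[bad]), collapse = ", "), call. = FALSE)
  if (any(!is.na(df$rfs_time) & df$rfs_time <= 0))
    stop("rfs_time must be > 0 (years)", call. = FALSE)
  if (any(!is.na(df$rfs_event) & !df$rfs_event %in% c(0, 1, TRUE, FALSE)))
    stop("rfs_event must be 0/1", call. = FALSE)
  df$rfs_event <- as.integer(df$rfs_event)
  df$responder <- is_responder(df$rcb_class)
  df
}

#' Write a cohort table to CSV
#'
#' Numeric columns are written with a pinned format (`%.10g`) so that reruns
#' of a deterministic pipeline produce bit-identical files.
#'
#' @param df cohort data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.10g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
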