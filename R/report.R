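#' Run the full cohort analysis
#'
#' Reproduces the study's analysis grid on a cohort table:
#' \itemize{
#'   \item pairwise Spearman correlations between baseline metrics;
#'   \item per-metric Wilcoxon rank-sum comparison of percent change in
#'     responders (RCB 0/I) versus non-responders (RCB II/III, including
#'     patients with metastases before surgery), at mid and post treatment;
#'   \item per-metric univariate Cox proportional-hazards fits of RFS on
#'     percent change (HR per `cox_unit`% change), at mid and post;
#'   \item Benjamini-Hochberg adjustment within each
#'     (analysis type x timepoint) family;
#'   \item third-quartile-dichotomized Kaplan-Meier curves with log-rank
#'     tests for the configured metrics at mid treatment;
#'   \item group summary tables reporting both mean (SD) and median (IQR).
#' }
#' The run is fully deterministic given the cohort table. A cohort too small
#' to analyze yields a flagged "insufficient data" report, not an error.
#'
#' @param cohort cohort data.frame (see [read_cohort_table()]).
#' @param config an [mpq_config()].
#' @return object of class `mpq_report`: `stats` (tidy stat-result table),
#'   `summary_table` (group summaries per metric/timepoint), `km` (list of
#'   [km_logrank_q3()] results), `spearman` (baseline correlation rows),
#'   `n`, `insufficient`.
#' @export
run_full_analysis <- function(cohort, config = mpq_config()) {
  cohort <- validate_cohort(cohort)
  n <- nrow(cohort)
  chg_cols <- grep("^chg_(mid|post)_", names(cohort), value = TRUE)
  metrics <- unique(sub("^chg_(mid|post)_", "", chg_cols))
  timepoints <- intersect(c("mid", "post"),
                          unique(sub("^chg_(mid|post)_.*$", "\\1", chg_cols)))
  insufficient <- n < 3 || sum(cohort$responder, na.rm = TRUE) < 1 ||
    sum(!cohort$responder, na.rm = TRUE) < 1
  empty <- stat_result("x", "x")[0, ]

  # baseline Spearman grid
  base_cols <- grep("_baseline$", names(cohort), value = TRUE)
  sp_rows <- empty
  if (length(base_cols) >= 2 && !insufficient) {
    prs <- utils::combn(base_cols, 2)
    sp <- lapply(seq_len(ncol(prs)), function(j) {
      a <- prs[1, j]; b <- prs[2, j]
      spearman_assoc(cohort[[a]], cohort[[b]],
                     metric = paste(sub("_baseline$", "", a),
                                    sub("_baseline$", "", b), sep = "~"))
    })
    sp_rows <- do.call(rbind, sp)
  }

  wil_rows <- empty; cox_rows <- empty
  if (!insufficient) {
    for (tp in timepoints) {
      wt <- lapply(metrics, function(m) {
        col <- paste0("chg_", tp, "_", m)
        if (!col %in% names(cohort)) return(NULL)
        wilcoxon_rank_sum(cohort[[col]][cohort$responder %in% TRUE],
                          cohort[[col]][cohort$responder %in% FALSE],
                          metric = m, timepoint = tp)
      })
      wt <- do.call(rbind, wt)
      if (!is.null(wt) && nrow(wt)) {
        wt$family <- paste0("wilcoxon_", tp)
        wt$p_adj <- bh_adjust(wt$p_raw)
        wil_rows <- rbind(wil_rows, wt)
      }
      cx <- lapply(metrics, function(m) {
        col <- paste0("chg_", tp, "_", m)
        if (!col %in% names(cohort)) return(NULL)
        cox_univariate(cohort[[col]], cohort$rfs_time, cohort$rfs_event,
                       unit = config$cox_unit, metric = m, timepoint = tp)
      })
      cx <- do.call(rbind, cx)
      if (!is.null(cx) && nrow(cx)) {
        cx$family <- paste0("cox_", tp)
        cx$p_adj <- bh_adjust(cx$p_raw)
        cox_rows <- rbind(cox_rows, cx)
      }
    }
  }

  # Q3-dichotomized KM at mid treatment for the configured metrics
  km <- list()
  if (!insufficient && "mid" %in% timepoints) {
    for (m in intersect(config$km_metrics, metrics)) {
      col <- paste0("chg_mid_", m)
      km[[m]] <- km_logrank_q3(cohort[[col]], cohort$rfs_time,
                               cohort$rfs_event, metric = m,
                               timepoint = "mid")
    }
  }
  km_rows <- if (length(km)) do.call(rbind, lapply(km, `[[`, "result"))
             else empty

  # group summaries: mean (SD) and median (IQR) per metric/timepoint
  summ <- list()
  for (tp in timepoints) for (m in metrics) {
    col <- paste0("chg_", tp, "_", m)
    if (!col %in% names(cohort)) next
    for (grp in c(TRUE, FALSE)) {
      v <- cohort[[col]][cohort$responder %in% grp]
      v <- v[!is.na(v)]
      summ[[length(summ) + 1L]] <- data.frame(
        metric = m, timepoint = tp,
        group = if (grp) "RCB 0/I" else "RCB II/III",
        n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        median = if (length(v)) stats::median(v) else NA_real_,
        q1 = if (length(v)) unname(stats::quantile(v, 0.25, type = 7))
             else NA_real_,
        q3 = if (length(v)) unname(stats::quantile(v, 0.75, type = 7))
             else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  summary_table <- if (length(summ)) do.call(rbind, summ) else NULL

  structure(list(stats = rbind(wil_rows, cox_rows, km_rows),
                 spearman = sp_rows, summary_table = summary_table,
                 km = km, n = n, metrics = metrics,
                 timepoints = timepoints, insufficient = insufficient,
                 config = config),
            class = "mpq_report")
}

#' @export
print.mpq_report <- function(x, ...) {
  cat(sprintf("Multimodal response analysis: %d patients\n", x$n))
  if (x$insufficient) {
    cat("  insufficient data: need >= 3 patients and both RCB groups\n")
    return(invisible(x))
  }
  cat(sprintf("  metrics: %s\n", paste(x$metrics, collapse = ", ")))
  st <- x$stats
  for (fam in unique(st$family[!is.na(st$family)])) {
    rows <- st[st$family %in% fam & !is.na(st$p_raw), ]
    sig <- rows$metric[rows$p_raw < x$config$alpha]
    adj <- rows$metric[rows$p_adj < x$config$alpha]
    cat(sprintf("  %s: %d/%d p < %.2f (%s)%s\n", fam, length(sig),
                nrow(rows), x$config$alpha,
                if (length(sig)) paste(sig, collapse = ", ") else "none",
                if (length(adj)) paste0("; BH-significant: ",
                                        paste(adj, collapse = ", "))
                else ""))
  }
  lr <- st[st$analysis == "logrank" & !is.na(st$p_raw), ]
  if (nrow(lr))
    cat(sprintf("  log-rank (Q3 split, mid): %s\n",
                paste(sprintf("%s p=%.3f", lr$metric, lr$p_raw),
                      collapse = "; ")))
  invisible(x)
}
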