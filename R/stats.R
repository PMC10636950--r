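#' Percent change from baseline
#'
#' `100 * (followup - baseline) / baseline`; a decrease is negative. Missing
#' or zero baseline makes the change undefined and returns `NA`, never an
#' error — per-metric sample sizes follow from missingness.
#'
#' @param baseline,followup numeric vectors (recycled to common length).
#' @return percent change, `NA` where undefined.
#' @export
percent_change <- function(baseline, followup) {
  out <- 100 * (followup - baseline) / baseline
  out[is.na(baseline) | is.na(followup) | baseline == 0] <- NA_real_
  out
}

#' Metabolism/perfusion mismatch ratios
#'
#' The five ratios of a metabolic measure to a perfusion/vascularity
#' surrogate: MRFDG/peak PE, MRFDG/peak SER, MRFDG/K1, SUVmax/peak PE,
#' SUVmax/peak SER. A ratio is `NA` whenever its numerator is missing or its
#' denominator is missing or zero; the others are still computed.
#'
#' @param metrics named list or one-row data.frame containing (any of)
#'   `mrfdg`, `suvmax`, `k1`, `peak_pe`, `peak_ser`.
#' @return named list of the five ratios.
#' @export
mismatch_ratios <- function(metrics) {
  g <- function(nm) {
    v <- metrics[[nm]]
    if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v[1])
  }
  safe_div <- function(num, den) {
    if (is.na(num) || is.na(den) || den == 0) NA_real_ else num / den
  }
  list(mrfdg_peak_pe = safe_div(g("mrfdg"), g("peak_pe")),
       mrfdg_peak_ser = safe_div(g("mrfdg"), g("peak_ser")),
       mrfdg_k1 = safe_div(g("mrfdg"), g("k1")),
       suvmax_peak_pe = safe_div(g("suvmax"), g("peak_pe")),
       suvmax_peak_ser = safe_div(g("suvmax"), g("peak_ser")))
}

stat_result <- function(metric, analysis, timepoint = NA_character_,
                        estimate = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, statistic = NA_real_,
                        p_raw = NA_real_, n = NA_integer_,
                        family = NA_character_, note = NA_character_) {
  data.frame(metric = metric, analysis = analysis, timepoint = timepoint,
             estimate = estimate, ci_lo = ci_lo, ci_hi = ci_hi,
             statistic = statistic, p_raw = p_raw, p_adj = NA_real_,
             n = as.integer(n), family = family, note = note,
             stringsAsFactors = FALSE)
}

#' Spearman rank-order correlation
#'
#' Rank correlation with average ranks for ties and a two-sided p-value from
#' the t-approximation, on pairwise-complete observations. Constant input
#' makes the coefficient undefined; the result is flagged, not an error.
#'
#' @param x,y numeric vectors.
#' @param metric,timepoint labels carried into the result row.
#' @return one-row stat-result data.frame (`estimate` = rho).
#' @export
spearman_assoc <- function(x, y, metric = "x_vs_y",
                           timepoint = "baseline") {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    return(stat_result(metric, "spearman", timepoint, n = n,
                       note = "fewer than 3 complete pairs"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(stat_result(metric, "spearman", timepoint, n = n,
                       note = "constant input: rho undefined"))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  stat_result(metric, "spearman", timepoint,
              estimate = unname(ct$estimate),
              statistic = unname(ct$statistic), p_raw = ct$p.value, n = n)
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided Mann-Whitney/Wilcoxon test: exact when the combined sample size
#' is at most 20 and there are no ties, otherwise the normal approximation
#' with continuity and tie correction. Identical values across both groups
#' give p = 1.
#'
#' @param group_a,group_b numeric vectors (NAs dropped).
#' @param metric,timepoint labels carried into the result row.
#' @return one-row stat-result data.frame (`statistic` = rank-sum W).
#' @export
wilcoxon_rank_sum <- function(group_a, group_b, metric = "metric",
                              timepoint = NA_character_) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (!length(a) || !length(b))
    return(stat_result(metric, "wilcoxon", timepoint,
                       n = length(a) + length(b), note = "empty group"))
  n <- length(a) + length(b)
  if (length(unique(c(a, b))) == 1L)
    return(stat_result(metric, "wilcoxon", timepoint, statistic = NA_real_,
                       p_raw = 1, n = n, note = "all values identical"))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = n <= 20, correct = TRUE))
  stat_result(metric, "wilcoxon", timepoint,
              statistic = unname(wt$statistic), p_raw = wt$p.value, n = n)
}

#' Benjamini-Hochberg adjustment within a family
#'
#' Step-up adjusted p-values controlling the false discovery rate;
#' monotone in rank and capped at 1. Idempotent up to that cap.
#'
#' @param p raw p-values in `[0, 1]` (NAs passed through).
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Univariate Cox proportional-hazards fit for a percent change
#'
#' Partial-likelihood fit (Efron tie handling) of recurrence-free survival
#' on a single percent-change covariate scaled to `unit`-percent steps, so
#' the hazard ratio reads "per `unit`% change". Wald 95% CI and p. Monotone
#' likelihood (perfect separation) is reported as a flagged
#' non-convergence, not an exception.
#'
#' @param change percent change from baseline, %.
#' @param rfs_time survival/censoring time, years.
#' @param rfs_event event indicator (1 = recurrence or death).
#' @param unit percent-change unit (default 5: HR per 5% change).
#' @param metric,timepoint labels carried into the result row.
#' @return one-row stat-result data.frame (`estimate` = HR per unit change).
#' @export
cox_univariate <- function(change, rfs_time, rfs_event, unit = 5,
                           metric = "metric", timepoint = NA_character_) {
  ok <- stats::complete.cases(change, rfs_time, rfs_event)
  change <- change[ok]; rfs_time <- rfs_time[ok]
  rfs_event <- rfs_event[ok]
  n <- length(change)
  if (sum(rfs_event) < 1)
    return(stat_result(metric, "cox", timepoint, n = n, note = "no events"))
  if (n < 2 || stats::sd(change) == 0)
    return(stat_result(metric, "cox", timepoint, n = n,
                       note = "constant covariate"))
  x <- change / unit
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(rfs_time, rfs_event) ~ x,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        monotone <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  zst <- beta / se
  stat_result(metric, "cox", timepoint,
              estimate = exp(beta),
              ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se),
              statistic = zst^2,  # Wald chi-square
              p_raw = 2 * stats::pnorm(-abs(zst)), n = n,
              note = if (monotone) "monotone likelihood: not converged"
                     else NA_character_)
}

#' Kaplan-Meier comparison dichotomized at the third quartile
#'
#' Splits patients at the 75th percentile (Q3, linear interpolation of order
#' statistics) of a metric's percent change, estimates product-limit
#' survival in each group and compares them with a two-group log-rank test.
#' Since most treatment changes are negative, the `change <= Q3` group is
#' labelled `"larger_decrease"` and `change > Q3` `"smaller_decrease"`; both
#' groupings are explicit in the output. Degenerate splits (all values
#' equal, or fewer than 2 patients in a group) and event-free cohorts are
#' flagged, never raised.
#'
#' @param change percent change from baseline, %.
#' @param rfs_time,rfs_event survival outcome (years, 1 = event).
#' @param metric,timepoint labels carried into the result row.
#' @return list of class `km_q3`: `q3`, `group` (factor per patient),
#'   `survfit` (the fitted curves, or NULL), `result` (stat-result row with
#'   the log-rank chi-square).
#' @export
km_logrank_q3 <- function(change, rfs_time, rfs_event, metric = "metric",
                          timepoint = NA_character_) {
  ok <- stats::complete.cases(change, rfs_time, rfs_event)
  change <- change[ok]; rfs_time <- rfs_time[ok]; rfs_event <- rfs_event[ok]
  n <- length(change)
  q3 <- if (n) unname(stats::quantile(change, 0.75, type = 7)) else NA_real_
  group <- factor(ifelse(change <= q3, "larger_decrease",
                         "smaller_decrease"),
                  levels = c("larger_decrease", "smaller_decrease"))
  flag <- function(note)
    structure(list(q3 = q3, group = group, survfit = NULL,
                   result = stat_result(metric, "logrank", timepoint, n = n,
                                        note = note)),
              class = "km_q3")
  if (n < 4 || length(unique(change)) == 1L || min(table(group)) < 2)
    return(flag("degenerate Q3 split"))
  if (sum(rfs_event) == 0) return(flag("no events: log-rank undefined"))
  sf <- survival::survfit(survival::Surv(rfs_time, rfs_event) ~ group)
  sd_ <- survival::survdiff(survival::Surv(rfs_time, rfs_event) ~ group)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  structure(list(q3 = q3, group = group, survfit = sf,
                 result = stat_result(metric, "logrank", timepoint,
                                      statistic = unname(sd_$chisq),
                                      p_raw = p, n = n)),
            class = "km_q3")
}

#' @export
print.km_q3 <- function(x, ...) {
  cat(sprintf("<km_q3> Q3 = %.2f%%; groups: %s\n", x$q3,
              paste(sprintf("%s n=%d", levels(x$group), table(x$group)),
                    collapse = ", ")))
  r <- x$result
  if (!is.na(r$p_raw))
    cat(sprintf("  log-rank chi-square = %.3f, p = %.4f\n", r$statistic,
                r$p_raw))
  else cat("  ", r$note, "\n")
  invisible(x)
}

#' @export
plot.km_q3 <- function(x, ...) {
  if (is.null(x$survfit)) stop("no curves to plot: ", x$result$note)
  plot(x$survfit, col = c("blue", "red"), xlab = "Years",
       ylab = "Recurrence-free survival", ...)
  graphics::legend("bottomleft", levels(x$group), col = c("blue", "red"),
                   lty = 1, bty = "n")
  invisible(x)
}
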