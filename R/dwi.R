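#' Voxel-wise apparent diffusion coefficient (ADC) fit
#'
#' Fits the conventional monoexponential decay model
#' `S(b) = S(0) * exp(-b * ADC)` at every voxel. The default fit is ordinary
#' least squares on the log signal, `ln S(b) = ln S(0) - b * ADC`, which is
#' deterministic and reduces to the exact two-point solution when only two
#' b-values are supplied. A nonlinear refinement (Levenberg-style via
#' [stats::nls()] started from the log-linear solution, per-voxel) is
#' available behind `method = "nonlinear"` for ROI-scale use.
#'
#' Voxels with any non-positive signal cannot be log-transformed and are
#' flagged invalid — never silently zeroed.
#'
#' @param volumes list of [image_volume()]s, one per b-value, common grid.
#' @param b_values numeric, s/mm^2; at least two distinct values.
#' @param method `"loglinear"` (default) or `"nonlinear"`.
#' @return object of class `adc_fit`: `adc_map` (mm^2/s, `NaN` where
#'   invalid), `s0_map`, `valid` (logical array), `b_values`, `method`.
#' @export
fit_adc <- function(volumes, b_values, method = c("loglinear", "nonlinear")) {
  method <- match.arg(method)
  if (!is.list(volumes) || !all(vapply(volumes, is_image_volume, logical(1))))
    stop("`volumes` must be a list of image_volume", call. = FALSE)
  b_values <- as.numeric(b_values)
  if (length(volumes) != length(b_values))
    stop("one volume per b-value required", call. = FALSE)
  if (length(unique(b_values)) < 2L)
    stop("at least two distinct b-values required", call. = FALSE)
  for (i in seq_along(volumes)[-1])
    stop_if_grid_mismatch(volumes[[1]], volumes[[i]], "DWI volumes")
  d <- dim(volumes[[1]]$voxels)
  sig <- vapply(volumes, function(v) as.vector(v$voxels),
                numeric(prod(d)))                      # nvox x nb
  valid <- rowSums(sig <= 0 | !is.finite(sig)) == 0L
  nb <- length(b_values)
  bbar <- mean(b_values)
  bc <- b_values - bbar
  sxx <- sum(bc^2)
  adc <- rep(NaN, nrow(sig)); s0 <- rep(NaN, nrow(sig))
  if (any(valid)) {
    ls <- log(sig[valid, , drop = FALSE])
    slope <- (ls %*% bc) / sxx
    inter <- rowMeans(ls) - slope * bbar
    adc[valid] <- -slope
    s0[valid] <- exp(inter)
    if (method == "nonlinear") {
      idx <- which(valid)
      for (k in seq_along(idx)) {
        i <- idx[k]
        df <- data.frame(b = b_values, s = sig[i, ])
        fit <- tryCatch(
          stats::nls(s ~ s0 * exp(-b * adc), data = df,
                     start = list(s0 = s0[i], adc = max(adc[i], 1e-6))),
          error = function(e) NULL)
        if (!is.null(fit)) {
          cf <- stats::coef(fit)
          s0[i] <- cf[["s0"]]; adc[i] <- cf[["adc"]]
        }
      }
    }
  }
  structure(list(
    adc_map = image_volume(array(adc, d), volumes[[1]]$spacing,
                           allow_na = TRUE),
    s0_map = image_volume(array(s0, d), volumes[[1]]$spacing,
                          allow_na = TRUE),
    valid = array(valid, d), b_values = b_values, method = method),
    class = "adc_fit")
}

#' @export
print.adc_fit <- function(x, ...) {
  cat(sprintf(
    "<adc_fit> %s fit at b = %s s/mm^2; %d/%d voxels valid\n",
    x$method, paste(x$b_values, collapse = ", "),
    sum(x$valid), length(x$valid)))
  invisible(x)
}

#' @export
coef.adc_fit <- function(object, ...) {
  list(adc = object$adc_map, s0 = object$s0_map)
}

#' @export
fitted.adc_fit <- function(object, ...) {
  lapply(object$b_values, function(b) {
    image_volume(object$s0_map$voxels * exp(-b * object$adc_map$voxels),
                 object$adc_map$spacing, allow_na = TRUE)
  })
}

#' Mean ADC over a lesion ROI
#'
#' Averages valid ADC voxels within the region of interest and reports how
#' many ROI voxels were excluded as invalid. Erroring (rather than returning
#' `NaN`) when no ROI voxel has a valid fit keeps missing data explicit.
#'
#' @param fit an `adc_fit`.
#' @param roi a `tumor_mask` or logical array on the ADC grid.
#' @return list: `mean_adc` (mm^2/s), `n_used`, `n_excluded`.
#' @export
roi_mean_adc <- function(fit, roi) {
  stopifnot(inherits(fit, "adc_fit"))
  m <- if (inherits(roi, "tumor_mask")) roi$mask else roi
  stopifnot(identical(dim(m), dim(fit$valid)))
  if (!any(m)) stop("empty ROI", call. = FALSE)
  ok <- m & fit$valid
  if (!any(ok)) stop("no valid ADC voxels in ROI", call. = FALSE)
  list(mean_adc = mean(fit$adc_map$voxels[ok]),
       n_used = sum(ok), n_excluded = sum(m) - sum(ok))
}
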