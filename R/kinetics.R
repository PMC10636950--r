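#' Two-tissue compartment parameters for FDG
#'
#' Irreversible (k4 = 0) FDG kinetics: `K1` (mL/min/g) transfer from blood to
#' tissue, `k2` (1/min) transport back to blood, `k3` (1/min) metabolic
#' trapping by phosphorylation, optional fractional blood volume `vb`. The
#' metabolic flux is the macro-parameter `Ki = K1 * k3 / (k2 + k3)`
#' (mL/min/g), always recomputed from the rates, never stored independently;
#' `Ki <= K1` holds for any non-negative rates.
#'
#' @param k1,k2,k3 non-negative rates; units as above.
#' @param vb fractional blood volume in `[0, 1)`, default 0.
#' @return object of class `two_tissue_params` with element `ki` derived.
#' @export
two_tissue_params <- function(k1, k2, k3, vb = 0) {
  k1 <- unname(k1); k2 <- unname(k2); k3 <- unname(k3); vb <- unname(vb)
  if (any(!is.finite(c(k1, k2, k3, vb))) || any(c(k1, k2, k3, vb) < 0))
    stop("rates must be finite and >= 0", call. = FALSE)
  if (vb >= 1) stop("vb must be < 1", call. = FALSE)
  structure(list(k1 = k1, k2 = k2, k3 = k3, vb = vb,
                 ki = flux_ki(k1, k2, k3)),
            class = "two_tissue_params")
}

#' Metabolic flux Ki from micro-parameters
#'
#' `Ki = (K1 * k3) / (k2 + k3)`; 0 when `k2 + k3 = 0` and `k3 = 0`, and `K1`
#' when both efflux and trapping vanish jointly is undefined — the package
#' uses the trapping-free limit `Ki = 0` when `k3 = 0`.
#'
#' @param k1,k2,k3 non-negative rates.
#' @return Ki in mL/min/g.
#' @export
flux_ki <- function(k1, k2, k3) {
  ifelse(k3 <= 0, 0, k1 * k3 / (k2 + k3))
}

# exact convolution of a piecewise-linear curve with exp(-a t) on a uniform
# grid: y(t) = int_0^t exp(-a (t-s)) c(s) ds, via a linear recurrence
# evaluated with stats::filter (C speed).
expconv_uniform <- function(cvals, dt, a) {
  n <- length(cvals)
  if (n < 2L) return(rep(0, n))
  if (a * dt < 1e-12) {  # a -> 0: plain cumulative integral
    return(cumtrapz_uniform(cvals, dt))
  }
  E <- exp(-a * dt)
  i0 <- (1 - E) / a
  i1 <- dt * (1 - E) / a - (1 - E * (1 + a * dt)) / a^2
  c0 <- cvals[-n]; m <- (cvals[-1] - c0) / dt
  g <- c0 * i0 + m * i1
  y <- stats::filter(g, E, method = "recursive")
  c(0, as.numeric(y))
}

cumtrapz_uniform <- function(cvals, dt) {
  n <- length(cvals)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((cvals[-1] + cvals[-n]) / 2 * dt))
}

# sample an input-function tac onto a uniform grid starting at 0; zero before
# the first sample (tracer absent pre-arrival), constant after the last.
cp_on_grid <- function(cp, tgrid) {
  x <- cp$midtimes; y <- cp$activity
  if (min(x) > 0) { x <- c(0, x); y <- c(0, y) }
  stats::approx(x, y, xout = tgrid, rule = 2)$y
}

#' Forward two-tissue compartment model: tissue time-activity curve
#'
#' Simulates the frame-averaged tissue activity of the irreversible
#' two-tissue compartment model,
#' `C_T(t) = K1 * [(k3 + k2 exp(-(k2+k3) t)) / (k2+k3)] (*) Cp(t) + vb Cp(t)`,
#' where `(*)` is convolution with the blood input function `Cp`. The
#' convolution is evaluated exactly for a piecewise-linear `Cp` on a uniform
#' fine grid (default 0.05 min) and then averaged over each acquisition
#' frame.
#'
#' @param params a [two_tissue_params()].
#' @param cp blood input function, a [tac()].
#' @param frame_start,frame_end frame boundaries, minutes; must lie within
#'   the support of `cp` (its last sample time).
#' @param dt fine-grid step, minutes.
#' @return a [tac()] (label `"tumor"`) at frame midtimes; the frame timing is
#'   attached as attributes `frame_start`, `frame_end`.
#' @export
simulate_tumor_tac <- function(params, cp, frame_start, frame_end,
                               dt = 0.05) {
  stopifnot(inherits(params, "two_tissue_params"), inherits(cp, "tac"))
  frame_start <- as.numeric(frame_start); frame_end <- as.numeric(frame_end)
  if (any(frame_end <= frame_start)) stop("frame_end must exceed frame_start")
  if (max(frame_end) > max(cp$midtimes) + 1e-9)
    stop("frames extend beyond the input-function support", call. = FALSE)
  fwd <- make_forward_model(cp, frame_start, frame_end, dt)
  out <- tac((frame_start + frame_end) / 2, fwd(params), label = "tumor")
  attr(out, "frame_start") <- frame_start
  attr(out, "frame_end") <- frame_end
  out
}

# builds the frame-averaged forward model with all input-independent work
# (fine grid, input-function samples, cumulative integral, frame-averaging
# weights) precomputed once; the returned closure costs one exponential
# convolution per evaluation, which makes the multistart fit tractable.
make_forward_model <- function(cp, frame_start, frame_end, dt) {
  tgrid <- seq(0, max(frame_end) + dt, by = dt)
  cpg <- cp_on_grid(cp, tgrid)
  cum <- cumtrapz_uniform(cpg, dt)
  n <- length(tgrid)
  W <- matrix(0, length(frame_start), n)
  for (i in seq_along(frame_start)) {
    xs <- seq(frame_start[i], frame_end[i], by = dt)
    if (xs[length(xs)] < frame_end[i]) xs <- c(xs, frame_end[i])
    dxs <- diff(xs)
    tw <- (c(dxs, 0) + c(0, dxs)) / 2 / (frame_end[i] - frame_start[i])
    idx <- pmin(floor(xs / dt) + 1L, n - 1L)
    frac <- xs / dt - (idx - 1L)
    for (j in seq_along(xs)) {
      W[i, idx[j]] <- W[i, idx[j]] + tw[j] * (1 - frac[j])
      W[i, idx[j] + 1L] <- W[i, idx[j] + 1L] + tw[j] * frac[j]
    }
  }
  function(params) {
    a <- params$k2 + params$k3
    ct <- if (a * dt < 1e-12) params$k1 * cum
          else params$k1 * (params$k3 * cum +
                            params$k2 * expconv_uniform(cpg, dt, a)) / a
    ct <- ct + params$vb * cpg
    pmax(drop(W %*% ct), 0)
  }
}

# returns a linear interpolator of C_T on [0, tmax]
tissue_curve_fun <- function(params, cp, tmax, dt) {
  tgrid <- seq(0, tmax + dt, by = dt)
  cpg <- cp_on_grid(cp, tgrid)
  a <- params$k2 + params$k3
  cum <- cumtrapz_uniform(cpg, dt)
  if (a * dt < 1e-12) {
    ct <- params$k1 * cum
  } else {
    ec <- expconv_uniform(cpg, dt, a)
    ct <- params$k1 * (params$k3 * cum + params$k2 * ec) / a
  }
  ct <- ct + params$vb * cpg
  function(t) stats::approx(tgrid, ct, xout = t, rule = 2)$y
}

frame_average <- function(ct_fun, frame_start, frame_end, dt) {
  vapply(seq_along(frame_start), function(i) {
    xs <- seq(frame_start[i], frame_end[i], by = dt)
    if (xs[length(xs)] < frame_end[i]) xs <- c(xs, frame_end[i])
    ys <- ct_fun(xs)
    sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2) /
      (frame_end[i] - frame_start[i])
  }, numeric(1))
}

#' Fit the two-tissue compartment model to a tissue time-activity curve
#'
#' Weighted nonlinear least squares of the irreversible two-tissue forward
#' model (the same model as [simulate_tumor_tac()]) against a measured tumor
#' TAC, given a blood input function. Optimization is bounded
#' (`0 <= rate <= upper`) and fully deterministic: 8 multistarts from a fixed
#' lattice of plausible rate values, best weighted residual sum of squares
#' wins, ties broken by the first start. Weights approximate count
#' statistics: `frame duration / max(activity, floor)`.
#'
#' @param tumor_tac measured tumor [tac()].
#' @param cp blood input function [tac()].
#' @param frame_start,frame_end frame boundaries (minutes); default taken
#'   from attributes of `tumor_tac` when present, otherwise inferred as
#'   contiguous frames around the midtimes.
#' @param fit_vb also fit a fractional blood-volume term (default FALSE).
#' @param upper named upper bounds `c(k1=, k2=, k3=, vb=)`.
#' @param weights `"duration_activity"` (default) or `"uniform"`.
#' @param dt fine-grid step for the forward model, minutes.
#' @return object of class `two_tissue_fit`; see [coef.two_tissue_fit()],
#'   `print`, `summary`, `fitted`, `residuals`, [predict.two_tissue_fit()].
#'   A TAC that is identically zero yields a flagged degenerate fit with
#'   `K1 = 0`; failure of every start yields `converged = FALSE`, never an
#'   exception.
#' @export
fit_two_tissue <- function(tumor_tac, cp, frame_start = NULL,
                           frame_end = NULL, fit_vb = FALSE,
                           upper = c(k1 = 2, k2 = 5, k3 = 2, vb = 0.5),
                           weights = c("duration_activity", "uniform"),
                           dt = 0.05) {
  stopifnot(inherits(tumor_tac, "tac"), inherits(cp, "tac"))
  weights <- match.arg(weights)
  if (is.null(frame_start)) frame_start <- attr(tumor_tac, "frame_start")
  if (is.null(frame_end)) frame_end <- attr(tumor_tac, "frame_end")
  if (is.null(frame_start) || is.null(frame_end)) {
    mt <- tumor_tac$midtimes
    bounds <- c(max(0, mt[1] - (mt[2] - mt[1]) / 2),
                (mt[-length(mt)] + mt[-1]) / 2,
                mt[length(mt)] + (mt[length(mt)] - mt[length(mt) - 1]) / 2)
    frame_start <- bounds[-length(bounds)]
    frame_end <- bounds[-1]
  }
  y <- tumor_tac$activity
  if (length(y) < 4L)
    stop("at least 4 frames required for a two-tissue fit", call. = FALSE)
  dur <- frame_end - frame_start
  ymax <- max(y)
  if (ymax <= 0) {
    params <- two_tissue_params(0, 0, 0, 0)
    return(new_two_tissue_fit(params, tumor_tac, cp, frame_start, frame_end,
                              rep(1, length(y)), objective = 0,
                              converged = TRUE, degenerate = TRUE, dt = dt))
  }
  w <- if (weights == "uniform") rep(1, length(y))
       else dur / pmax(y, 0.05 * ymax)
  w <- w / mean(w)

  free <- if (fit_vb) c("k1", "k2", "k3", "vb") else c("k1", "k2", "k3")
  up <- upper[free]
  lo <- rep(0, length(free))
  fwd <- make_forward_model(cp, frame_start, frame_end, dt)
  obj <- function(theta) {
    mu <- fwd(list(k1 = theta[1], k2 = theta[2], k3 = theta[3],
                   vb = if (fit_vb) theta[4] else 0))
    sum(w * (y - mu)^2)
  }
  starts <- as.matrix(expand.grid(k1 = c(0.02, 0.2), k2 = c(0.1, 0.8),
                                  k3 = c(0.01, 0.1)))
  if (fit_vb) starts <- cbind(starts, vb = 0.05)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::nlminb(pmin(starts[s, ], up), obj, lower = lo, upper = up,
                    control = list(eval.max = 2000, iter.max = 1000,
                                   rel.tol = 1e-14, x.tol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$objective < best$objective))
      best <- res
  }
  if (is.null(best)) {
    params <- two_tissue_params(NA_real_, NA_real_, NA_real_, 0)
    params$k1 <- params$k2 <- params$k3 <- params$ki <- NA_real_
    return(new_two_tissue_fit(params, tumor_tac, cp, frame_start, frame_end,
                              w, objective = NA_real_, converged = FALSE,
                              degenerate = FALSE, dt = dt))
  }
  th <- best$par
  params <- two_tissue_params(th[1], th[2], th[3], if (fit_vb) th[4] else 0)
  new_two_tissue_fit(params, tumor_tac, cp, frame_start, frame_end, w,
                     objective = best$objective,
                     converged = is.finite(best$objective),
                     degenerate = FALSE, dt = dt)
}

new_two_tissue_fit <- function(params, tumor_tac, cp, frame_start, frame_end,
                               w, objective, converged, degenerate, dt) {
  fitted <- if (all(is.finite(unlist(params[c("k1", "k2", "k3", "vb")]))))
    simulate_tumor_tac(params, cp, frame_start, frame_end, dt)$activity
  else rep(NA_real_, length(tumor_tac$activity))
  structure(list(params = params, tac = tumor_tac, cp = cp,
                 frame_start = frame_start, frame_end = frame_end,
                 weights = w, fitted = fitted,
                 residuals = tumor_tac$activity - fitted,
                 objective = objective, converged = converged,
                 degenerate = degenerate, dt = dt),
            class = "two_tissue_fit")
}

#' @export
print.two_tissue_fit <- function(x, ...) {
  cat("<two_tissue_fit>",
      if (x$degenerate) "(degenerate: zero activity)"
      else if (!x$converged) "(NOT converged)" else "", "\n")
  print(round(coef(x), 6))
  invisible(x)
}

#' Extract fitted kinetic parameters
#'
#' @param object a `two_tissue_fit`.
#' @param ... unused.
#' @return named vector `k1, k2, k3, vb, ki`.
#' @export
coef.two_tissue_fit <- function(object, ...) {
  p <- object$params
  c(k1 = p$k1, k2 = p$k2, k3 = p$k3, vb = p$vb, ki = p$ki)
}

#' @export
fitted.two_tissue_fit <- function(object, ...) object$fitted

#' @export
residuals.two_tissue_fit <- function(object, ...) object$residuals

#' Predict the model tissue curve at arbitrary times
#'
#' @param object a `two_tissue_fit`.
#' @param times minutes post injection (instantaneous values, not
#'   frame-averaged). Default: the fitted frame midtimes.
#' @param ... unused.
#' @return numeric activity (kBq/mL).
#' @export
predict.two_tissue_fit <- function(object, times = object$tac$midtimes, ...) {
  f <- tissue_curve_fun(object$params, object$cp,
                        tmax = max(times, object$frame_end), dt = object$dt)
  f(times)
}

#' @export
summary.two_tissue_fit <- function(object, ...) {
  out <- list(coef = coef(object), converged = object$converged,
              degenerate = object$degenerate,
              wrss = object$objective,
              rmse_rel = sqrt(mean(object$residuals^2)) /
                max(max(object$tac$activity), .Machine$double.eps),
              n_frames = length(object$tac$activity))
  class(out) <- "summary.two_tissue_fit"
  out
}

#' @export
print.summary.two_tissue_fit <- function(x, ...) {
  cat("Two-tissue compartment fit (irreversible, k4 = 0)\n")
  print(round(x$coef, 6))
  cat(sprintf("frames: %d, weighted RSS: %.4g, relative RMSE: %.3g%s\n",
              x$n_frames, x$wrss, x$rmse_rel,
              if (!x$converged) "  [NOT converged]" else ""))
  invisible(x)
}

#' Metabolic rate of FDG (MRFDG)
#'
#' `MRFDG = Ki * [Glucose]`: the metabolic flux scaled by the plasma glucose
#' concentration. No lumped-constant correction is applied; units are
#' `(glucose concentration unit) * mL/min/g` in whatever glucose unit the
#' physiology record declares.
#'
#' @param params a [two_tissue_params()] or [fit_two_tissue()] result.
#' @param phys a [patient_physiology()] with `plasma_glucose` set.
#' @param expected_unit optionally assert the glucose unit (e.g. from the
#'   analysis config); a mismatch is an error, never a silent conversion.
#' @return MRFDG (numeric scalar).
#' @export
metabolic_rate_fdg <- function(params, phys, expected_unit = NULL) {
  if (inherits(params, "two_tissue_fit")) params <- params$params
  stopifnot(inherits(params, "two_tissue_params"),
            inherits(phys, "patient_physiology"))
  if (!is.finite(phys$plasma_glucose))
    stop("plasma_glucose missing: cannot compute MRFDG", call. = FALSE)
  if (!is.null(expected_unit) && !identical(phys$glucose_unit, expected_unit))
    stop(sprintf("glucose unit mismatch: physiology declares %s, expected %s",
                 phys$glucose_unit, expected_unit), call. = FALSE)
  params$ki * phys$plasma_glucose
}
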