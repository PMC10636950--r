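test_that("simulated input function peaks early and handles edge specs", {
  spec <- input_function_spec()
  cp <- simulate_input_function(spec)
  expect_true(all(cp$activity >= 0))
  expect_lt(cp$midtimes[which.max(cp$activity)], 2)  # peak within 2 min
  zero <- simulate_input_function(input_function_spec(A = c(0, 0, 0)))
  expect_true(all(zero$activity == 0))
  one <- simulate_input_function(input_function_spec(times = 5))
  expect_equal(length(one$activity), 1L)
  expect_error(input_function_spec(times = numeric(0)), "empty time grid")
})

test_that("forward model matches an independent fine-grid convolution", {
  p <- two_tissue_params(0.1, 0.2, 0.05)
  sim <- simulate_tumor_tac(p, shared_cp, shared_timing$start,
                            shared_timing$end)
  orc <- oracle_tumor_tac(p, shared_cp, shared_timing$start,
                          shared_timing$end)
  expect_lt(max(abs(sim$activity - orc)) / max(orc), 0.005)
  # boxcar input function
  box <- tac(seq(0.25, 60, by = 0.25),
             ifelse(seq(0.25, 60, by = 0.25) <= 2, 50, 0), label = "blood")
  simb <- simulate_tumor_tac(p, box, shared_timing$start, shared_timing$end,
                             dt = 0.01)
  orcb <- oracle_tumor_tac(p, box, shared_timing$start, shared_timing$end,
                           dt = 0.001)
  expect_lt(max(abs(simb$activity - orcb)) / max(orcb), 0.005)
})

test_that("forward model limits behave physiologically", {
  ft <- shared_timing
  # K1 = 0: identically zero tissue curve
  z <- simulate_tumor_tac(two_tissue_params(0, 0.2, 0.05), shared_cp,
                          ft$start, ft$end)
  expect_true(all(z$activity == 0))
  # k3 = 0, k2 > 0: no trapping, Ki = 0, late tissue tracks K1/k2 * Cp
  p0 <- two_tissue_params(0.1, 0.5, 0)
  expect_equal(p0$ki, 0)
  s <- simulate_tumor_tac(p0, shared_cp, ft$start, ft$end)
  cp_late <- mean(shared_cp$activity[shared_cp$midtimes >= 50])
  expect_equal(s$activity[length(s$activity)], 0.1 / 0.5 * cp_late,
               tolerance = 0.05)
  # k3 -> infinity approaches flow-limited trapping K1 * int Cp
  pinf <- two_tissue_params(0.1, 1, 50)
  sinf <- simulate_tumor_tac(pinf, shared_cp, ft$start, ft$end)
  cum_cp <- cumsum(c(0, diff(shared_cp$midtimes)) * shared_cp$activity)
  icp <- stats::approx(shared_cp$midtimes, cum_cp,
                       (ft$start + ft$end) / 2, rule = 2)$y
  late <- length(sinf$activity)
  expect_equal(sinf$activity[late], 0.1 * icp[late], tolerance = 0.03)
  # blood-volume term adds vb * Cp
  pv <- two_tissue_params(0, 0, 0, vb = 0.1)
  sv <- simulate_tumor_tac(pv, shared_cp, ft$start, ft$end)
  expect_gt(max(sv$activity), 0)
})

test_that("noiseless fits recover the generating parameters", {
  p <- two_tissue_params(0.1, 0.2, 0.05)
  sim <- simulate_tumor_tac(p, shared_cp, shared_timing$start,
                            shared_timing$end)
  fit <- fit_two_tissue(sim, shared_cp)
  expect_true(fit$converged)
  cf <- coef(fit)
  expect_equal(cf[["k1"]], 0.1, tolerance = 1e-4)
  expect_equal(cf[["ki"]], 0.02, tolerance = 1e-4)
  # ki = K1 k3/(k2+k3) always recomputed and bounded by K1
  expect_equal(cf[["ki"]], flux_ki(cf[["k1"]], cf[["k2"]], cf[["k3"]]))
  expect_lte(cf[["ki"]], cf[["k1"]] + 1e-12)
})

test_that("zero and invalid TACs are flagged, not raised", {
  ft <- shared_timing
  zero <- tac((ft$start + ft$end) / 2, rep(0, length(ft$start)))
  attr(zero, "frame_start") <- ft$start; attr(zero, "frame_end") <- ft$end
  fit <- fit_two_tissue(zero, shared_cp)
  expect_true(fit$degenerate)
  expect_equal(coef(fit)[["k1"]], 0)
  short <- tac(c(1, 2, 3), c(1, 2, 3))
  expect_error(fit_two_tissue(short, shared_cp, frame_start = 0:2,
                              frame_end = 1:3), "at least 4")
  expect_error(two_tissue_params(-0.1, 0.2, 0.05), ">= 0")
})

test_that("fitted Ki is monotone in k3 on noiseless data", {
  kis <- vapply(c(0.02, 0.05, 0.12), function(k3) {
    sim <- simulate_tumor_tac(two_tissue_params(0.1, 0.3, k3), shared_cp,
                              shared_timing$start, shared_timing$end)
    coef(fit_two_tissue(sim, shared_cp))[["ki"]]
  }, numeric(1))
  expect_true(all(diff(kis) > 0))
})

test_that("kinetic fitting is deterministic", {
  p <- two_tissue_params(0.08, 0.4, 0.03)
  sim <- simulate_tumor_tac(p, shared_cp, shared_timing$start,
                            shared_timing$end)
  noisy <- noisy_tac(sim, 0.05, seed = 5)
  f1 <- fit_two_tissue(noisy, shared_cp)
  f2 <- fit_two_tissue(noisy, shared_cp)
  expect_identical(coef(f1), coef(f2))
  # different noise seeds differ, same seed identical
  expect_identical(noisy_tac(sim, 0.05, seed = 5)$activity, noisy$activity)
  expect_false(identical(noisy_tac(sim, 0.05, seed = 6)$activity,
                         noisy$activity))
})

test_that("MRFDG is Ki times plasma glucose with unit bookkeeping", {
  p <- two_tissue_params(0.1, 0.2, 0.05)   # ki = 0.02
  phys <- patient_physiology(370, 70, 5.0, "mmol/L")
  expect_equal(metabolic_rate_fdg(p, phys), 0.10)
  expect_equal(metabolic_rate_fdg(two_tissue_params(0.1, 0.2, 0), phys), 0)
  expect_error(metabolic_rate_fdg(p, phys, expected_unit = "mg/dL"),
               "unit mismatch")
  nog <- patient_physiology(370, 70)
  expect_error(metabolic_rate_fdg(p, nog), "glucose missing")
})

test_that("fit methods expose curves and summaries", {
  p <- two_tissue_params(0.1, 0.2, 0.05)
  sim <- simulate_tumor_tac(p, shared_cp, shared_timing$start,
                            shared_timing$end)
  fit <- fit_two_tissue(sim, shared_cp)
  expect_equal(fitted(fit), sim$activity, tolerance = 1e-6)
  expect_equal(residuals(fit), sim$activity - fitted(fit))
  pr <- predict(fit, times = c(10, 30, 59))
  expect_true(all(is.finite(pr)) && all(pr >= 0))
  s <- summary(fit)
  expect_lt(s$rmse_rel, 1e-5)
  expect_output(print(fit), "two_tissue_fit")
})
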