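test_that("DCE phantom inverts the PE/SER construction", {
  spec <- phantom_spec(noise_sd = 0)
  ph <- make_dce_phantom(spec)
  pe <- (ph$s1$voxels - ph$s0$voxels) / ph$s0$voxels
  ser <- (ph$s1$voxels - ph$s0$voxels) / (ph$s2$voxels - ph$s0$voxels)
  expect_equal(unique(round(pe[ph$truth_mask], 12)), 0.8)
  expect_equal(unique(round(ser[ph$truth_mask], 12)), 1.3)
  expect_equal(unique(round(pe[!ph$truth_mask], 12)), 0.1)
  expect_error(make_dce_phantom(phantom_spec(ser_tumor = 0)), "degenerate")
  expect_error(phantom_spec(radius_mm = 40), "does not fit")
})

test_that("phantom noise is seeded: same seed same data, masks invariant", {
  a <- make_dce_phantom(phantom_spec(noise_sd = 0.05, seed = 1))
  b <- make_dce_phantom(phantom_spec(noise_sd = 0.05, seed = 2))
  c2 <- make_dce_phantom(phantom_spec(noise_sd = 0.05, seed = 1))
  expect_false(identical(a$s1$voxels, b$s1$voxels))
  expect_identical(a$s1$voxels, c2$s1$voxels)
  expect_identical(a$truth_mask, b$truth_mask)
})

test_that("DWI phantom follows the monoexponential decay", {
  spec <- phantom_spec(noise_sd = 0, adc_tumor = 1.0e-3)
  ph <- make_dwi_phantom(spec, b_values = c(0, 100, 800))
  # S(800) = 1000 * exp(-0.8)
  expect_equal(ph$volumes[[3]]$voxels[ph$truth_mask][1], 1000 * exp(-0.8),
               tolerance = 1e-12)
  expect_equal(ph$volumes[[1]]$voxels, array(1000, spec$dims))
  z <- make_dwi_phantom(phantom_spec(noise_sd = 0, adc_tumor = 0,
                                     adc_background = 0))
  expect_identical(z$volumes[[1]]$voxels, z$volumes[[3]]$voxels)
  expect_error(make_dwi_phantom(phantom_spec(adc_tumor = -1)), ">= 0")
})

test_that("cohort generator matches its specification in the large", {
  spec <- cohort_effect_spec(n_responders = 5000, n_nonresponders = 5000)
  co <- make_cohort(spec, seed = 8)
  expect_equal(nrow(co), 10000)
  # empirical group means/SDs converge to the spec (LLN at n = 10^4)
  eff <- spec$effects
  row <- eff[eff$metric == "peak_pe" & eff$timepoint == "mid", ]
  r <- co$chg_mid_peak_pe[co$responder]
  nr <- co$chg_mid_peak_pe[!co$responder]
  expect_equal(mean(r), row$mean_responder,
               tolerance = 4 * row$sd_responder / sqrt(5000))
  expect_equal(sd(r), row$sd_responder, tolerance = 0.05 * row$sd_responder)
  expect_equal(mean(nr), row$mean_nonresponder,
               tolerance = 4 * row$sd_nonresponder / sqrt(5000))
  # survival columns respect their support
  expect_true(all(co$rfs_time > 0 & co$rfs_time <= 10))
  expect_true(all(co$rfs_event %in% 0:1))
})

test_that("cohort generator is deterministic and handles edge sizes", {
  s <- cohort_effect_spec()
  expect_identical(make_cohort(s, seed = 4), make_cohort(s, seed = 4))
  expect_false(identical(make_cohort(s, seed = 4)$rfs_time,
                         make_cohort(s, seed = 5)$rfs_time))
  one <- make_cohort(cohort_effect_spec(n_responders = 1,
                                        n_nonresponders = 3), seed = 1)
  expect_equal(sum(one$responder), 1)
  expect_error(cohort_effect_spec(n_responders = 0), ">= 1")
  bad <- reference_change_effects(); bad$sd_responder[1] <- -2
  expect_error(cohort_effect_spec(effects = bad), "SDs")
})

test_that("baseline values carry the specified copula correlations", {
  co <- make_cohort(cohort_effect_spec(n_responders = 3000,
                                       n_nonresponders = 3000), seed = 12)
  r1 <- cor(log(co$k1_baseline), log(co$peak_pe_baseline))
  r2 <- cor(log(co$mrfdg_baseline), log(co$adc_baseline))
  expect_equal(r1, 0.35, tolerance = 0.05)
  expect_equal(r2, 0.38, tolerance = 0.05)
  # ratio baselines are consistent with their components
  expect_equal(co$mrfdg_k1_baseline, co$mrfdg_baseline / co$k1_baseline)
})

test_that("reference effect and hazard tables carry the reported values", {
  eff <- reference_change_effects()
  row <- eff[eff$metric == "peak_pe" & eff$timepoint == "mid", ]
  expect_equal(c(row$mean_responder, row$sd_responder,
                 row$mean_nonresponder, row$sd_nonresponder),
               c(-31.1, 12.6, -15.1, 28.0))
  hz <- reference_hazard_ratios()
  expect_equal(hz$hr_per_5pct[hz$metric == "mrfdg" &
                                hz$timepoint == "mid"], 1.04)
})
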