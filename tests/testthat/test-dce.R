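test_that("PE map implements (S1 - S0)/S0 with masked degenerate voxels", {
  s0 <- vol3(100); s1 <- vol3(180)
  expect_equal(compute_pe_map(s0, s1)$voxels, array(0.8, c(4, 4, 2)))
  expect_equal(compute_pe_map(s0, s0)$voxels, array(0, c(4, 4, 2)))
  s0z <- s0; s0z$voxels[1, 1, 1] <- 0
  pe <- compute_pe_map(s0z, s1)
  expect_true(is.nan(pe$voxels[1, 1, 1]))
  expect_equal(pe$voxels[2, 1, 1], 0.8)
  expect_error(compute_pe_map(s0, vol3(1, c(3, 3, 2))), "grid mismatch")
})

test_that("SER map implements (S1 - S0)/(S2 - S0) with degeneracy guard", {
  s0 <- vol3(100); s1 <- vol3(180); s2 <- vol3(160)
  expect_equal(compute_ser_map(s0, s1, s2)$voxels,
               array(80 / 60, c(4, 4, 2)))
  expect_equal(compute_ser_map(s0, s1, s1)$voxels, array(1, c(4, 4, 2)))
  ser <- compute_ser_map(s0, s1, s0)
  expect_true(all(is.nan(ser$voxels)))
})

test_that("segmentation thresholds the analytic sphere exactly", {
  ph <- make_dce_phantom(phantom_spec(noise_sd = 0))
  pe <- compute_pe_map(ph$s0, ph$s1)
  m <- segment_tumor(pe, threshold = 0.50)
  expect_true(m$lesion_found)
  expect_equal(sum(m$mask), 515)              # voxels in a 5 mm digital sphere
  expect_identical(m$mask, ph$truth_mask)
  # noiseless phantom inversion to float precision
  expect_equal(max(abs(pe$voxels[ph$truth_mask] - 0.8)), 0, tolerance = 1e-12)
  ser <- compute_ser_map(ph$s0, ph$s1, ph$s2)
  expect_equal(max(abs(ser$voxels[ph$truth_mask] - 1.3)), 0,
               tolerance = 1e-12)
})

test_that("segmentation handles no-lesion and seed-point selection", {
  flat <- vol3(0.4, c(5, 5, 3))
  m <- segment_tumor(flat)
  expect_false(m$lesion_found)
  # two disjoint blobs: 2x2x1 and 1x1x1 separated by > 1 voxel
  arr <- array(0.1, c(9, 9, 3))
  arr[2:3, 2:3, 2] <- 0.9
  arr[8, 8, 2] <- 0.9
  pe <- image_volume(arr, c(1, 1, 1))
  big <- segment_tumor(pe)
  expect_equal(sum(big$mask), 4)              # largest component by default
  small <- segment_tumor(pe, seed_point = c(8, 8, 2))
  expect_equal(sum(small$mask), 1)            # seed keeps its own component
  expect_error(segment_tumor(pe, seed_point = c(5, 5, 1)),
               "not inside")
})

test_that("hotspot peak equals the enumerated 3x3 in-plane window maximum", {
  # constant field: peak equals the constant
  m <- array(TRUE, c(7, 7, 2))
  flat <- vol3(3.5, c(7, 7, 2))
  expect_equal(hotspot_peak(flat, m), 3.5)
  # single hot voxel in a 5x5 slice: centered window mean (10 + 8)/9 = 2
  arr <- array(1, c(5, 5, 1)); arr[3, 3, 1] <- 10
  expect_equal(hotspot_peak(image_volume(arr, c(1, 1, 1)),
                            array(TRUE, c(5, 5, 1))), 2)
  # windows straddling the mask boundary are excluded
  mask <- array(FALSE, c(7, 7, 1)); mask[2:6, 2:6, 1] <- TRUE
  arr2 <- array(0, c(7, 7, 1)); arr2[2:6, 2:6, 1] <- 1; arr2[2, 2, 1] <- 50
  # corner voxel can never be a full-window member except in the corner
  # window, whose mean the oracle computes
  expect_equal(hotspot_peak(image_volume(arr2, c(1, 1, 1)), mask),
               oracle_hotspot(arr2, mask))
  # tiny mask: declared fallback to single-voxel max with a warning
  tiny <- array(FALSE, c(5, 5, 1)); tiny[1:2, 1:2, 1] <- TRUE
  expect_warning(pk <- hotspot_peak(image_volume(arr, c(1, 1, 1)), tiny),
                 "single-voxel")
  expect_equal(pk, 1)
  expect_error(hotspot_peak(flat, array(FALSE, c(7, 7, 2))), "empty mask")
})

test_that("hotspot never exceeds the in-mask maximum", {
  set.seed(11)
  for (i in 1:10) {
    arr <- array(rnorm(7 * 7 * 3), c(7, 7, 3))
    mask <- array(runif(7 * 7 * 3) < 0.6, c(7, 7, 3))
    if (!any(mask)) next
    pk <- suppressWarnings(hotspot_peak(image_volume(arr, c(1, 1, 1)), mask))
    expect_lte(pk, max(arr[mask]) + 1e-12)
  }
})

test_that("FTV counts qualifying voxels times voxel volume", {
  arr <- array(0.2, c(10, 10, 2))
  arr[1:10, 1:10, 1] <- 0.9                 # 100 qualifying voxels
  pe <- image_volume(arr, c(1, 1, 2))       # 2 mm^3 voxels
  mask <- array(TRUE, c(10, 10, 2))
  expect_equal(functional_tumor_volume(pe, mask), 0.2)
  expect_equal(functional_tumor_volume(pe, array(FALSE, c(10, 10, 2))), 0)
  # mask built at the same threshold: FTV equals mask volume
  m2 <- segment_tumor(pe, 0.5)
  expect_equal(functional_tumor_volume(pe, m2),
               sum(m2$mask) * voxel_volume_cc(pe))
})

test_that("washout volume respects the SER threshold and the tumor mask", {
  mask <- array(c(rep(TRUE, 50), rep(FALSE, 50)), c(10, 10, 1))
  ser <- array(NA_real_, c(10, 10, 1))
  ser[1:25] <- 1.2; ser[26:50] <- 0.9        # half of mask washes out
  sv <- image_volume(ser, c(1, 1, 1), allow_na = TRUE)
  expect_equal(washout_volume(sv, mask), 25 / 1000)
  expect_equal(washout_volume(image_volume(array(1.0, c(10, 10, 1)),
                                           c(1, 1, 1)), mask), 0)
})

test_that("washout volume never exceeds FTV on noisy phantoms", {
  for (sd in c(0.02, 0.05)) {
    ph <- make_dce_phantom(phantom_spec(noise_sd = sd, seed = 3))
    pe <- compute_pe_map(ph$s0, ph$s1)
    ser <- compute_ser_map(ph$s0, ph$s1, ph$s2)
    m <- segment_tumor(pe)
    expect_lte(washout_volume(ser, m), functional_tumor_volume(pe, m))
  }
})

test_that("volumes scale with voxel volume", {
  ph1 <- make_dce_phantom(phantom_spec(noise_sd = 0))
  ph2 <- make_dce_phantom(phantom_spec(spacing = c(2, 2, 2), radius_mm = 10,
                                       noise_sd = 0))
  pe1 <- compute_pe_map(ph1$s0, ph1$s1); pe2 <- compute_pe_map(ph2$s0, ph2$s1)
  m1 <- segment_tumor(pe1); m2 <- segment_tumor(pe2)
  expect_equal(sum(m2$mask), sum(m1$mask))   # same digital sphere
  expect_equal(functional_tumor_volume(pe2, m2),
               8 * functional_tumor_volume(pe1, m1))
})

test_that("longest dimension is the max pairwise center distance", {
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  expect_equal(longest_dimension(one, spacing = c(1, 1, 1)), 0)
  two <- array(FALSE, c(12, 3, 3)); two[1, 2, 2] <- TRUE; two[11, 2, 2] <- TRUE
  expect_equal(longest_dimension(two, spacing = c(1, 1, 1)), 10)
  # digital sphere of radius 5: diameter within one voxel diagonal of 10
  ph <- make_dce_phantom(phantom_spec(noise_sd = 0))
  ld <- longest_dimension(segment_tumor(compute_pe_map(ph$s0, ph$s1)))
  expect_lt(abs(ld - 10), sqrt(3))
  # matches brute force over all voxels
  co <- which(ph$truth_mask, arr.ind = TRUE)
  expect_equal(ld, max(stats::dist(co)))
  expect_error(longest_dimension(array(FALSE, c(2, 2, 2)),
                                 spacing = c(1, 1, 1)), "empty mask")
})
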