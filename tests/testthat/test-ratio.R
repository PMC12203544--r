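test_that("bias corrector is the identity on bias-free single-class data", {
  p <- make_phantom(clean_phantom_spec())
  m <- p$ref_masks$soft_tissue
  out <- correct_bias(p$t1w, m, 2)
  expect_lt(max(abs(out[m] / p$t1w[m] - 1)), 1e-6)
})

test_that("bias corrector recovers a known degree-2 field", {
  p <- make_phantom(clean_phantom_spec(bias_amplitude = 0.3, seed = 2))
  out <- correct_bias(p$t1w, p$ref_masks$soft_tissue, 2)
  # residual coefficient of variation of output over the class mean
  for (m in list(p$ref_masks$soft_tissue, p$chp_truth_mask)) {
    v <- out[m]
    expect_lt(sd(v) / mean(v), 0.01)
  }
})

test_that("bias corrector input contracts", {
  v <- array(1, c(8, 8, 8))
  expect_error(correct_bias(v, array(FALSE, c(8, 8, 8))), "empty")
  v[1] <- -1
  m <- array(TRUE, c(8, 8, 8))
  expect_error(correct_bias(v, m), "non-positive")
})

test_that("histogram peak finds the dominant density mode", {
  x <- plexdyn:::with_seed(4, rnorm(5000, 100, 5))
  expect_lt(abs(histogram_peak(x, 1.25) - 100), 0.5)
  y <- plexdyn:::with_seed(5, c(rnorm(1000, 50, 2), rnorm(4000, 120, 2)))
  expect_lt(abs(histogram_peak(y, 1) - 120), 1)
  expect_equal(histogram_peak(rep(7, 100), 1), 7)
  expect_error(histogram_peak(rnorm(10), 1), "at least 50")
})

test_that("calibration maps peaks onto anchors and absorbs gain", {
  p <- make_phantom(clean_phantom_spec())
  cp <- calibration_params()
  cal <- calibrate_intensities(p$t2w, p$ref_masks, cp$anchor_targets_t2)
  pk <- attr(cal, "peaks")
  # detected peaks sit on the class means, and map onto the anchors
  expect_equal(unname(pk), c(20, 60, 140), tolerance = 0.5)
  expect_equal(median(cal[p$ref_masks$soft_tissue]), 0.6, tolerance = 1e-3)
  # identity when peaks already equal anchors
  v <- array(rep(c(0.2, 0.6, 1.0), each = 200), c(20, 10, 3))
  masks <- list(bone = v == 0.2, soft_tissue = v == 0.6, csf = v == 1.0)
  almost_const <- v + plexdyn:::with_seed(1, array(rnorm(600, 0, 1e-5), dim(v)))
  cal2 <- calibrate_intensities(almost_const, masks, cp$anchor_targets_t2)
  expect_lt(max(abs(cal2 - almost_const)), 1e-3)
  # pre-multiplying the input leaves the calibrated output unchanged
  cal3 <- calibrate_intensities(3 * p$t2w, p$ref_masks, cp$anchor_targets_t2)
  expect_lt(max(abs(cal3 - cal)), 1e-6)
})

test_that("non-separable calibration anchors are rejected", {
  v <- array(rep(c(10, 10, 50), each = 200), c(20, 10, 3))
  masks <- list(bone = array(rep(c(TRUE, FALSE, FALSE), each = 200), dim(v)),
                soft_tissue = array(rep(c(FALSE, TRUE, FALSE), each = 200),
                                    dim(v)),
                csf = array(rep(c(FALSE, FALSE, TRUE), each = 200), dim(v)))
  expect_error(
    calibrate_intensities(v, masks, calibration_params()$anchor_targets_t2),
    "not separable")
})

test_that("one-voxel erosion follows the 6-connectivity oracle", {
  cube <- array(FALSE, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  er <- erode_one_voxel(cube)
  expect_equal(sum(er), 1L)
  expect_true(er[3, 3, 3])
  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_equal(sum(erode_one_voxel(single)), 0L)
  plane <- array(FALSE, c(5, 5, 5)); plane[, , 3] <- TRUE
  expect_equal(sum(erode_one_voxel(plane)), 0L)
})

test_that("ratio map and mean ratio follow their closed forms", {
  t2 <- array(plexdyn:::with_seed(3, runif(1000, 0.5, 1.5)), c(10, 10, 10))
  t1 <- 2 * t2
  m <- array(FALSE, c(10, 10, 10)); m[3:8, 3:8, 3:8] <- TRUE
  rr <- compute_ratio(t1, t2, m)
  expect_equal(rr$mean_ratio, 2)
  expect_true(all(!rr$eroded_mask | m))
  expect_error(compute_ratio(t1, t2, array(FALSE, dim(t1))), "empty")
  # eroding a single-voxel mask falls back to the un-eroded mask
  single <- array(FALSE, c(10, 10, 10)); single[5, 5, 5] <- TRUE
  expect_warning(rs <- compute_ratio(t1, t2, single), "un-eroded")
  expect_equal(rs$mean_ratio, 2)
})

test_that("noise-free ratio recovers the class-mean ratio exactly", {
  p <- make_phantom(clean_phantom_spec())
  rr <- ratio_pipeline(p$t1w, p$t2w, p$chp_truth_mask, p$ref_masks,
                       correct_bias_first = FALSE)
  # oracle: push the plexus class means through the anchor maps directly
  m1 <- p$spec$tissue_means_t1; m2 <- p$spec$tissue_means_t2
  cp <- calibration_params()
  o1 <- plexdyn:::piecewise_linear(m1[["chp"]],
                                   c(m1[["csf"]], m1[["soft_tissue"]], m1[["bone"]]),
                                   unname(cp$anchor_targets_t1[c("csf", "soft_tissue", "bone")]))
  o2 <- plexdyn:::piecewise_linear(m2[["chp"]],
                                   c(m2[["bone"]], m2[["soft_tissue"]], m2[["csf"]]),
                                   unname(cp$anchor_targets_t2[c("bone", "soft_tissue", "csf")]))
  expect_equal(rr$mean_ratio, o1 / o2, tolerance = 0.02)
})

test_that("end-to-end ratio is invariant to independent input gains", {
  p <- noisy_phantom7()
  s <- segment_chp(p$t1w, p$ventricle_mask, p$voxel_dims, p$icv_ml)
  a <- ratio_pipeline(p$t1w, p$t2w, s$mask, p$ref_masks)
  b <- ratio_pipeline(4.2 * p$t1w, 0.37 * p$t2w, s$mask, p$ref_masks)
  expect_equal(a$mean_ratio, b$mean_ratio, tolerance = 1e-6)
})

test_that("erosion shields the mean ratio from boundary corruption", {
  p <- make_phantom(clean_phantom_spec())
  # corrupt the boundary layer of the plexus mask on T2w (partial-volume-like)
  boundary <- p$chp_truth_mask & !erode_one_voxel(p$chp_truth_mask)
  t2 <- p$t2w
  t2[boundary] <- t2[boundary] * 2.5
  cp <- calibration_params()
  t1c <- calibrate_intensities(p$t1w, p$ref_masks, cp$anchor_targets_t1)
  t2c <- calibrate_intensities(t2, p$ref_masks, cp$anchor_targets_t2)
  truth <- 0.45 / 0.65   # calibrated class-mean ratio of the clean phantom
  rr <- compute_ratio(t1c, t2c, p$chp_truth_mask)
  err_eroded <- abs(rr$mean_ratio - truth)
  err_full <- abs(mean(rr$ratio_map[p$chp_truth_mask], na.rm = TRUE) - truth)
  expect_lt(err_eroded, err_full)
})

test_that("bias correction commutes with calibration when bias-free", {
  p <- make_phantom(clean_phantom_spec())
  cp <- calibration_params()
  direct <- calibrate_intensities(p$t2w, p$ref_masks, cp$anchor_targets_t2)
  corrected <- correct_bias(p$t2w, p$ref_masks$soft_tissue, 2)
  via <- calibrate_intensities(corrected, p$ref_masks, cp$anchor_targets_t2)
  expect_lt(max(abs(via - direct)), 1e-6)
})
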