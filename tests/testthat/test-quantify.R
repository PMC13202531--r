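test_that("decay correction doubles per half-life and inverts physical decay", {
  expect_equal(decay_correct(50, 79.2), 100)
  expect_equal(decay_correct(25, 158.4), 100)
  expect_equal(decay_correct(7.3, 0), 7.3)
  expect_error(decay_correct(10, -1), "negative")
  # round trip: decay then correct
  a0 <- 123.4
  decayed <- a0 * 2^(-c(2, 24, 240) / 79.2)
  expect_equal(decay_correct(decayed, c(2, 24, 240)), rep(a0, 3),
               tolerance = 1e-12)
})

test_that("first-frame normalisation scales proportionally and is idempotent", {
  expect_equal(normalize_to_first_frame(c(5, 4, 2.5)), c(100, 80, 50))
  expect_equal(normalize_to_first_frame(rep(3, 5)), rep(100, 5))
  once <- normalize_to_first_frame(c(8, 2, 1))
  expect_identical(normalize_to_first_frame(once), once)
  expect_error(normalize_to_first_frame(c(0, 1)), "positive")
})

test_that("ellipsoid ROI extraction follows centre-inclusion membership", {
  vol <- activity_volume(array(2.5, dim = c(20, 20, 20)), spacing = 0.5)
  roi <- ellipsoid_roi(center = c(5, 5, 5), semi_axes = 3)
  res <- extract_ellipsoid_roi(vol, roi)
  expect_equal(res$mean_conc, 2.5)
  expect_equal(res$total_activity, 2.5 * res$n_voxels * 0.5^3)
  expect_error(
    extract_ellipsoid_roi(vol, ellipsoid_roi(center = 100, semi_axes = 0.1)),
    "empty ROI")
})

test_that("a voxelised sphere integrates close to the analytic volume", {
  ph <- generate_eye_phantom(eye_center = 12, eye_radius_mm = 3,
                             eye_activity = 1, spacing = 0.5, grid_shape = 48)
  roi <- ellipsoid_roi(center = 12, semi_axes = 6)  # 12 mm ocular ROI
  res <- extract_ellipsoid_roi(ph$volume, roi)
  analytic <- 4 / 3 * pi * 3^3
  expect_lt(abs(res$total_activity - analytic) / analytic, 0.05)
  expect_equal(res$total_activity, ph$truth$voxelized_total)
})

test_that("an oversized ROI recovers the phantom's full activity exactly", {
  ph <- generate_eye_phantom(eye_center = 12, eye_radius_mm = 3,
                             eye_activity = 2, spacing = 0.5, grid_shape = 48)
  big <- ellipsoid_roi(center = 12, semi_axes = 60)
  res <- extract_ellipsoid_roi(ph$volume, big)
  expect_equal(res$total_activity, sum(ph$volume$voxels) * 0.5^3)
})

test_that("ROI totals are additive over disjoint ROIs and translation-invariant", {
  ph <- generate_eye_phantom(eye_center = c(6, 12, 12), eye_radius_mm = 2.5,
                             eye_activity = 1, spacing = 0.5, grid_shape = 48)
  vox <- ph$volume$voxels
  two <- array(0, dim = dim(vox))
  two[] <- vox
  shift <- 24L  # 12 mm in voxels
  two[(shift + 1):48, , ] <- two[(shift + 1):48, , ] + vox[1:(48 - shift), , ]
  vol2 <- activity_volume(two, spacing = 0.5)
  roi_a <- ellipsoid_roi(center = c(6, 12, 12), semi_axes = 5)
  roi_b <- ellipsoid_roi(center = c(18, 12, 12), semi_axes = 5)
  ra <- extract_ellipsoid_roi(vol2, roi_a)
  rb <- extract_ellipsoid_roi(vol2, roi_b)
  whole <- extract_ellipsoid_roi(vol2, ellipsoid_roi(center = 12, semi_axes = 60))
  expect_equal(ra$total_activity + rb$total_activity, whole$total_activity)
  # translating grid and ROI by a whole-voxel offset leaves the result unchanged
  vol_t <- activity_volume(vox, spacing = 0.5, origin = c(1.5, -2, 0.5))
  roi_t <- ellipsoid_roi(center = c(6 + 1.5, 12 - 2, 12 + 0.5), semi_axes = 5)
  expect_equal(extract_ellipsoid_roi(vol_t, roi_t),
               extract_ellipsoid_roi(ph$volume, roi_a))
})

test_that("percent injected dose follows the normalisation identity", {
  expect_equal(percent_id_per_organ(1, 10, 10), 100)  # whole dose in organ
  expect_equal(percent_id_per_organ(0, 10, 10), 0)
  # half the dose in a double-volume organ: 50% regardless of the split
  expect_equal(percent_id_per_organ(5 / 20, 20, 10), 50)
  expect_error(percent_id_per_organ(1, 10, 0), "injected_dose")
})

test_that("%ID never exceeds 100 when the phantom holds the injected dose", {
  ph <- generate_eye_phantom(eye_center = 12, eye_radius_mm = 3,
                             eye_activity = 1, spacing = 0.5, grid_shape = 48)
  dose <- sum(ph$volume$voxels) * 0.5^3
  roi <- extract_ellipsoid_roi(ph$volume, ellipsoid_roi(12, 6))
  pid <- percent_id_per_organ(roi$mean_conc, roi$roi_volume_mm3 / 1000,
                              dose / 1000)
  expect_lte(pid, 100)
})

test_that("blood activity uses the theoretical blood volume formula", {
  expect_equal(blood_volume_mL(300), 18.77)
  expect_equal(total_blood_activity(0, 300, 1), 0)
  p1 <- total_blood_activity(2, 300, 10)
  expect_equal(total_blood_activity(4, 300, 20), p1)  # scale invariance
  expect_equal(p1, 100 * 2 * 18.77 / 10)
  expect_error(total_blood_activity(1, -5, 1), "body_weight_g")
})

test_that("anterior/posterior percentages split the total exactly", {
  uni <- matrix(1, 10, 10)
  res <- anterior_posterior_split(uni, boundary = 0.5)
  expect_equal(res$pct_anterior, 50)
  expect_equal(res$pct_posterior, 50)
  img <- matrix(runif(400), 20, 20)
  for (b in c(1, 7, 13, 19)) {
    r <- anterior_posterior_split(img, boundary = b)
    expect_identical(r$pct_anterior + r$pct_posterior, 100)
  }
  allpost <- rbind(matrix(0, 5, 8), matrix(3, 5, 8))
  r <- anterior_posterior_split(allpost, boundary = 5)
  expect_equal(unlist(r[, 1:2], use.names = FALSE), c(0, 100))
  expect_error(anterior_posterior_split(matrix(0, 4, 4), 2), "zero total")
  expect_error(anterior_posterior_split(uni, 10), "boundary")
})

test_that("activity volumes survive a NIfTI round trip", {
  ph <- generate_eye_phantom(eye_center = 8, eye_radius_mm = 2,
                             eye_activity = 3, spacing = 0.5, grid_shape = 32)
  path <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(path))
  write_activity_volume(ph$volume, path)
  back <- read_activity_volume(path)
  expect_equal(back$voxels, ph$volume$voxels, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$spacing, ph$volume$spacing)
})

test_that("autoradiographs survive a plain-text round trip", {
  img <- generate_autoradiograph(c(12, 9), anterior_fraction = 0.34)$image
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path))
  write_autoradiograph(img, path)
  expect_equal(read_autoradiograph(path), img, tolerance = 1e-12)
})
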