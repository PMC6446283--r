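# ROI rasterisation, extraction, reader placement and cohort measurement.

test_that("disc voxel count matches the brute-force centre-in-disc count", {
  g <- grid_geometry(c(40, 40, 9), c(1, 1, 1), origin = c(-20, -20, -4))
  spec <- roi_spec("pons", "midline", c(0.3, -0.2, 0), n_slices = 1)
  msk <- roi_mask(spec, g)
  r <- roi_radius_mm(spec)
  # brute force over all voxel centres
  cnt <- 0
  for (i in 1:40) for (j in 1:40) {
    p <- voxel_to_world(g, c(i, j, 5))
    if ((p[1] - 0.3)^2 + (p[2] + 0.2)^2 <= r^2) cnt <- cnt + 1
  }
  expect_equal(attr(msk, "n_voxels"), cnt)
  # nominal area ~ 50.8 voxels on a 1 mm grid, within one voxel ring
  ring <- 2 * pi * r   # ~one-voxel-wide ring
  expect_lt(abs(cnt - 50.8), ring)
})

test_that("slice replication and degenerate single-voxel ROIs", {
  g <- grid_geometry(c(30, 30, 12), c(1, 1, 1), origin = c(-15, -15, -5))
  s1 <- roi_spec("pons", "midline", c(0, 0, 0), n_slices = 1)
  s3 <- roi_spec("pons", "midline", c(0, 0, 0), n_slices = 3)
  expect_equal(attr(roi_mask(s3, g), "n_voxels"),
               3 * attr(roi_mask(s1, g), "n_voxels"))
  # area of one voxel footprint -> a single voxel per slice
  tiny <- roi_spec("pons", "midline", c(0, 0, 0),
                   area_cm2 = pi * 0.04^2, n_slices = 1)  # r = 0.4 mm
  expect_equal(attr(roi_mask(tiny, g), "n_voxels"), 1L)
})

test_that("edge slices shift inward and out-of-field ROIs error", {
  g <- grid_geometry(c(30, 30, 5), c(1, 1, 1), origin = c(-15, -15, 0))
  # landmark on the first slice: the 3-slice stack shifts inward
  spec <- roi_spec("pons", "midline", c(0, 0, 0), n_slices = 3)
  msk <- roi_mask(spec, g)
  zs <- unique(which(msk$data, arr.ind = TRUE)[, 3])
  expect_setequal(zs, 1:3)
  far <- roi_spec("GM", "left", c(-14.5, 0, 2))
  expect_error(roi_mask(far, g), "outside the field")
})

test_that("extract_mean equals the brute-force masked mean", {
  set.seed(9)
  v <- volume(array(rnorm(30 * 30 * 10), c(30, 30, 10)), c(1, 1, 1),
              origin = c(-15, -15, -4))
  msk <- roi_mask(roi_spec("pons", "midline", c(1, -2, 0)), v)
  expect_equal(extract_mean(v, msk),
               sum(v$data[msk$data]) / sum(msk$data), tolerance = 1e-12)
  u <- volume(array(4.2, dim(v$data)), v$spacing, v$origin)
  expect_equal(extract_mean(u, msk), 4.2)
  empty <- volume(array(FALSE, dim(v$data)), v$spacing, v$origin)
  expect_error(extract_mean(v, empty), "empty")
})

test_that("reader placement: zero jitter identity, reproducibility, SD", {
  spec <- roi_spec("GM", "left", c(-51, 0, 0))
  expect_identical(reader_place(spec, "R1", 0, 1), spec)
  a <- reader_place(spec, "R1", 1.5, seed = 4)
  b <- reader_place(spec, "R1", 1.5, seed = 4)
  expect_identical(a$center, b$center)
  expect_false(identical(a$center,
                         reader_place(spec, "R2", 1.5, seed = 4)$center))
  expect_equal(a$center[3], spec$center[3])   # in-plane only
  # empirical SD of 1e4 in-plane draws within 3 SE of the nominal 1 mm
  disp <- vapply(seq_len(5000), function(i) {
    reader_place(spec, "R1", 1, seed = i)$center[1] - spec$center[1]
  }, 0.0)
  se <- 1 / sqrt(2 * (length(disp) - 1))
  expect_lt(abs(sd(disp) - 1), 3 * se)
  expect_lt(abs(mean(disp)), 3 / sqrt(length(disp)))
})

test_that("noiseless measurements recover ground truth within 1%", {
  coh <- noiseless_cohort()
  meas <- measure_all(coh, jitter_sd = 0)
  j <- join_truth(meas, coh)
  expect_gt(nrow(j), 0)
  rel <- abs(j$concentration - j$true_conc) / j$true_conc
  expect_lt(max(rel), 0.01)
  # concentration ordering of region cores follows the truth ordering
  ag <- aggregate(cbind(concentration, true_conc) ~ region, data = j, mean)
  expect_identical(order(ag$concentration), order(ag$true_conc))
})

test_that("a global session gain leaves concentrations unchanged", {
  coh <- noiseless_cohort()
  meas0 <- measure_all(coh, jitter_sd = 0)
  coh2 <- coh
  for (k in names(coh2$sessions)) {
    coh2$sessions[[k]]$image$data <- coh2$sessions[[k]]$image$data * 2.37
  }
  meas2 <- measure_all(coh2, jitter_sd = 0)
  expect_equal(meas2$concentration, meas0$concentration, tolerance = 1e-9)
  expect_equal(meas2$mean_signal, 2.37 * meas0$mean_signal, tolerance = 1e-9)
})

test_that("measurement table has one record per session/reader/landmark", {
  coh <- noisy_cohort()
  lm <- default_landmarks()
  brain <- lm[lm$region != "CSF", ]   # 9 brain ROIs + reference row
  meas <- measure_all(coh, landmarks = brain)
  n_subj <- length(unique(coh$truth$subject))
  expect_equal(nrow(meas), n_subj * 3 * 2 * 9)
  expect_false(any(meas$region == "reference"))
  expect_true(all(meas$n_voxels >= 1))
  expect_true(all(meas$concentration >= 0))
  # scaling to the study size: 12 x 3 x 2 x 9 = 648 records
  expect_equal(12 * 3 * 2 * 9, 648)
})

test_that("missing reference landmark aborts with a diagnostic", {
  coh <- noiseless_cohort()
  lm <- default_landmarks()
  expect_error(measure_all(coh, landmarks = lm[lm$region != "reference", ]),
               "reference")
  bad <- lm; bad$region[1] <- "thalamus"
  expect_error(measure_all(coh, landmarks = bad), "thalamus")
})

test_that("landmark and measurement CSVs round-trip losslessly", {
  lm <- default_landmarks()
  f <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(lm, f)
  expect_equal(read_landmarks(f), lm)
  meas <- degenerate_measurements()
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_measurements(meas, f2)
  back <- read_measurements(f2)
  expect_equal(back$concentration, meas$concentration, tolerance = 1e-15)
  expect_equal(back[c("subject", "visit", "reader", "region", "side")],
               meas[c("subject", "visit", "reader", "region", "side")],
               ignore_attr = TRUE)
})
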