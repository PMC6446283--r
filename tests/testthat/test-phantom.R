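# Digital phantom, forward synthesis, Rician noise and cohort generation.

test_that("default label volume populates every region generously", {
  lab <- default_cache()$labels
  regions <- attr(lab, "regions")
  counts <- table(lab$data)
  for (l in regions$label) {
    expect_gt(counts[[as.character(l)]], 100)
  }
  # every voxel carries exactly one label, background included
  expect_setequal(as.integer(names(counts)), c(0L, regions$label))
})

test_that("a single sphere rasterises to its analytic volume within 2%", {
  prim <- list(sphere_primitive("ball", "GM", "midline", c(0, 0, 0), 20, 1L,
                                clip_to_head = FALSE))
  cfg <- phantom_config(primitives = prim)
  lab <- build_label_volume(cfg)
  analytic <- 4 / 3 * pi * 20^3 / prod(lab$spacing)
  expect_equal(sum(lab$data == 1), analytic, tolerance = 0.02)
})

test_that("degenerate phantom configs are rejected", {
  expect_error(phantom_config(primitives = list()), "empty")
  expect_error(phantom_config(anat_spacing_mm = 4, sodium_spacing_mm = 2),
               "coarser")
  # reference tube overlapping the head
  prim <- list(
    ellipsoid_primitive("GM", "GM", "midline", c(0, 0, 0), c(30, 30, 30), 1L,
                        clip_to_head = FALSE),
    cylinder_primitive("reference", "reference", "midline", c(10, 0, 0),
                       radius = 5, half_length = 10, label = 2L))
  expect_error(build_label_volume(phantom_config(primitives = prim)),
               "overlaps the head")
})

test_that("uniform phantom synthesises the analytic signal in its interior", {
  prim <- list(sphere_primitive("ball", "WM", "midline", c(0, 0, 0), 30, 1L,
                                clip_to_head = FALSE))
  cfg <- phantom_config(primitives = prim)
  lab <- build_label_volume(cfg)
  lib <- default_lib(); acq <- acquisition_spec()
  img <- synthesize_sodium_image(lab, lib, acq, session_spec("S01", "V1"), cfg)
  expected <- lib$entries$WM$concentration *
    saturation_factor(acq$tr_ms, lib$entries$WM$relax$t1_ms) *
    te_decay(acq$te_ms, lib$entries$WM$relax)
  # voxels well inside the sphere (15 mm margin > ROI + PSF support)
  ctr <- world_to_voxel(img, c(0, 0, 0))
  i <- round(ctr[1, ])
  core <- img$data[(i[1] - 2):(i[1] + 2), (i[2] - 2):(i[2] + 2),
                   (i[3] - 2):(i[3] + 2)]
  expect_equal(unname(core), array(expected, dim(core)), tolerance = 1e-6)
  # all voxels are a convex combination of background 0 and the pure signal
  expect_true(all(img$data >= -1e-9 & img$data <= expected * (1 + 1e-9)))
})

test_that("boundary voxels between two compartments are intermediate", {
  prim <- list(
    ellipsoid_primitive("GM", "GM", "midline", c(0, 0, 0), c(40, 40, 40), 1L,
                        clip_to_head = FALSE),
    sphere_primitive("HCN_right", "HCN", "right", c(0, 0, 0), 20, 2L))
  cfg <- phantom_config(primitives = prim)
  lab <- build_label_volume(cfg)
  lib <- default_lib(); acq <- acquisition_spec()
  img <- synthesize_sodium_image(lab, lib, acq, session_spec("S01", "V1"), cfg)
  sig <- function(rg) lib$entries[[rg]]$concentration *
    saturation_factor(acq$tr_ms, lib$entries[[rg]]$relax$t1_ms) *
    te_decay(acq$te_ms, lib$entries[[rg]]$relax)
  # a voxel straddling the sphere boundary lies between the pure signals
  b <- round(world_to_voxel(img, c(20, 0, 0)))[1, ]
  v <- img$data[b[1], b[2], b[3]]
  expect_gt(v, min(sig("GM"), sig("HCN")) - 1e-9)
  expect_lt(v, max(sig("GM"), sig("HCN")) + 1e-9)
})

test_that("rician noise: passthrough, Rayleigh background, Rice mean, seed", {
  v <- volume(array(5, c(10, 10, 10)), c(1, 1, 1))
  expect_identical(add_rician_noise(v, 0, 1), v)
  expect_error(add_rician_noise(v, -1, 1), "sigma")

  z <- volume(array(0, c(50, 50, 40)), c(1, 1, 1))   # 1e5 voxels
  n <- length(z$data)
  out <- add_rician_noise(z, 1, seed = 99)
  se <- sqrt(2 - pi / 2) / sqrt(n)
  expect_lt(abs(mean(out$data) - sqrt(pi / 2)), 3 * se)

  s <- volume(array(50, c(50, 50, 40)), c(1, 1, 1))
  out2 <- add_rician_noise(s, 2.5, seed = 100)
  # Rice mean at v = 50, sigma = 2.5 from numerical quadrature of the pdf
  rice_mean <- 50.062539210143
  se2 <- 2.5 / sqrt(n)
  expect_lt(abs(mean(out2$data) - rice_mean), 3 * se2)

  expect_identical(add_rician_noise(s, 2.5, seed = 100)$data, out2$data)
  expect_false(identical(add_rician_noise(s, 2.5, seed = 101)$data, out2$data))
})

test_that("cohorts are reproducible and extensible by seed", {
  a <- simulate_cohort(n_subjects = 2, seed = 31, cache = default_cache())
  b <- simulate_cohort(n_subjects = 2, seed = 31, cache = default_cache())
  expect_identical(a$truth, b$truth)
  expect_identical(a$sessions[["S01/V2"]]$image$data,
                   b$sessions[["S01/V2"]]$image$data)
  # adding a subject leaves earlier subjects untouched
  c3 <- simulate_cohort(n_subjects = 3, seed = 31, cache = default_cache(),
                        images = FALSE)
  expect_identical(c3$truth[c3$truth$subject %in% c("S01", "S02"), ], a$truth)
  # different seed reshuffles
  d <- simulate_cohort(n_subjects = 2, seed = 32, cache = default_cache(),
                       images = FALSE)
  expect_false(identical(a$truth$true_conc, d$truth$true_conc))
})

test_that("visits share the subject truth and differ only by session effects", {
  coh <- noiseless_cohort()
  tr <- coh$truth
  expect_equal(nrow(tr), 3 * 9)   # 3 subjects x 9 tissue region instances
  for (s in c("S01", "S02", "S03")) {
    v1 <- coh$sessions[[paste0(s, "/V1")]]
    v2 <- coh$sessions[[paste0(s, "/V2")]]
    expect_identical(v1$concentrations, v2$concentrations)
    # no noise / no repositioning / no drift: identical images
    expect_equal(v1$image$data, v2$image$data, tolerance = 1e-12)
  }
})

test_that("between-subject SD of simulated truths matches the configured SD", {
  coh <- simulate_cohort(n_subjects = 200, seed = 77, images = FALSE,
                         config = default_cfg())
  lib <- default_lib()
  for (rg in c("GM", "WM", "HCN")) {
    sub <- coh$truth[coh$truth$region == rg, ]
    v <- sub$true_conc[!duplicated(sub$subject)]
    sd_cfg <- lib$entries[[rg]]$sd
    n <- length(v)
    se <- sd_cfg / sqrt(2 * (n - 1))   # SE of a normal SD estimate
    expect_lt(abs(sd(v) - sd_cfg), 3 * se)
  }
})

test_that("reference tube self-calibrates to the reference concentration", {
  coh <- noiseless_cohort()
  img <- coh$sessions[["S01/V1"]]$image
  lib <- coh$lib
  ref_lm <- default_landmarks()
  ref_lm <- ref_lm[ref_lm$region == "reference", ]
  spec <- roi_spec("reference", "midline",
                   c(ref_lm$x_mm, ref_lm$y_mm, ref_lm$z_mm))
  s_ref <- extract_mean(img, roi_mask(spec, img))
  got <- quantify_tsc(s_ref, s_ref, lib$reference$concentration,
                      lib$reference$relax, lib$reference$relax, coh$acq)
  expect_equal(got, lib$reference$concentration, tolerance = 0.01)
})
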