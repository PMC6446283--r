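# TSC quantification equation: saturation, biexponential decay, correction
# factor, and the calibrated concentration. Frozen expected values were
# computed by direct high-precision evaluation of the closed-form scalars.

brain <- relaxation_spec(29, 4, 29, 0.6, 0.4)
csf <- relaxation_spec(58.1, 55, 55, 0, 1)
ref <- relaxation_spec(35, 7.15, 33.7, 0.6, 0.4)
acq <- acquisition_spec()  # TR 120 / TE 0.2

test_that("saturation factor matches closed-form values and limits", {
  # 1 - exp(-120/58.1), frozen from direct evaluation
  expect_equal(saturation_factor(120, 58.1), 0.873232993893198, tolerance = 1e-12)
  expect_equal(saturation_factor(100, 100), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(saturation_factor(1e9, 42), 1.0)       # full-recovery limit
  # monotone non-decreasing in TR on a grid
  trs <- seq(5, 500, length.out = 40)
  vals <- vapply(trs, saturation_factor, 0.0, t1_ms = 58.1)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > 0 & vals < 1))
  expect_error(saturation_factor(-1, 10), "tr_ms")
  expect_error(saturation_factor(120, 0), "t1_ms")
})

test_that("TE decay matches closed-form values and is non-increasing", {
  expect_equal(te_decay(0, brain), 1.0)
  # 0.6 e^-0.05 + 0.4 e^(-0.2/29), frozen from direct evaluation
  expect_equal(te_decay(0.2, brain), 0.967988524665779, tolerance = 1e-12)
  expect_equal(te_decay(0.2, csf), exp(-0.2 / 55), tolerance = 1e-12)
  tes <- seq(0, 50, length.out = 60)
  vals <- vapply(tes, te_decay, 0.0, relax = brain)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0 & vals <= 1))
  expect_error(te_decay(-0.1, brain), "te_ms")
})

test_that("correction factor composes the two ratios and is 1 on identity", {
  # frozen composition of independently evaluated saturation/decay scalars
  expect_equal(correction_factor(brain, ref, acq), 0.996555888138297,
               tolerance = 1e-12)
  expect_equal(correction_factor(brain, brain, acq), 1.0)
  # TE = 0 and equal T1 collapses both fractions
  ref0 <- relaxation_spec(29, 7.15, 33.7, 0.6, 0.4)
  expect_equal(correction_factor(brain, ref0, acquisition_spec(te_ms = 0)), 1.0)
  # property: identity for random specs
  set.seed(42)
  for (i in 1:25) {
    rx <- random_relax()
    a <- acquisition_spec(tr_ms = runif(1, 10, 300), te_ms = runif(1, 0, 5))
    expect_equal(correction_factor(rx, rx, a), 1.0, tolerance = 1e-12)
  }
})

test_that("shared-weight mode applies the tissue weights to the reference", {
  # identical to the default for brain (same weights), different for CSF
  expect_equal(correction_factor(brain, ref, acq, ref_weights = "tissue"),
               correction_factor(brain, ref, acq))
  cf_csf <- correction_factor(csf, ref, acq, ref_weights = "tissue")
  expect_equal(cf_csf,
               (saturation_factor(120, 35) / saturation_factor(120, 58.1)) *
                 (exp(-0.2 / 33.7) / exp(-0.2 / 55)),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cf_csf, correction_factor(csf, ref, acq))))
})

test_that("quantify_tsc: self-calibration, linearity, homogeneity, errors", {
  expect_equal(quantify_tsc(7, 7, 102.7, ref, ref, acq), 102.7)
  c1 <- quantify_tsc(10, 80, 102.67, brain, ref, acq)
  expect_equal(quantify_tsc(20, 80, 102.67, brain, ref, acq), 2 * c1)
  expect_equal(quantify_tsc(10, 160, 102.67, brain, ref, acq), c1 / 2)
  expect_equal(quantify_tsc(0, 80, 102.67, brain, ref, acq), 0)
  # composition of oracle scalars at ratio 0.5
  expect_equal(quantify_tsc(40, 80, 102.67, brain, ref, acq),
               0.5 * 102.67 * 0.996555888138297, tolerance = 1e-12)
  expect_error(quantify_tsc(10, 0, 102.67, brain, ref, acq), "s_ref")
  expect_error(quantify_tsc(-1, 80, 102.67, brain, ref, acq), "s_tiss")
})

test_that("uncorrected ratio is recovered at TE = 0 and TR >> T1", {
  a <- acquisition_spec(tr_ms = 20 * 58.1, te_ms = 0)
  got <- quantify_tsc(30, 90, 102.67, csf, ref, a)
  expect_equal(got, (30 / 90) * 102.67, tolerance = 1e-6)
})

test_that("relaxation_spec enforces its invariants", {
  expect_error(relaxation_spec(0, 4, 29, 0.6, 0.4), "t1_ms")
  expect_error(relaxation_spec(29, 29, 4, 0.6, 0.4), "t2_fast")
  expect_error(relaxation_spec(29, 4, 29, 0.7, 0.4), "weight")
  expect_error(relaxation_spec(29, 4, 29, -0.1, 1.1), "weight_fast")
})

test_that("default library carries the shipped constants and all regions", {
  lib <- default_lib()
  expect_setequal(names(lib$entries),
                  c("GM", "WM", "HCN", "pons", "cerebellum", "CSF"))
  expect_equal(lib$reference$relax$t2_fast_ms, 7.15)
  expect_equal(lib$reference$relax$t2_slow_ms, 33.7)
  expect_equal(lib$reference$concentration, 102.67)
  expect_equal(lib$entries$GM$relax$t1_ms, 29)
  expect_equal(lib$entries$CSF$relax$t1_ms, 58.1)
  expect_equal(lib$entries$CSF$relax$weight_fast, 0)
  expect_equal(lib$entries$HCN$concentration, 60.9)
  a <- attr(lib, "acquisition")
  expect_equal(a$tr_ms, 120)
  expect_equal(a$te_ms, 0.2)
  expect_equal(a$voxel_mm, 3.6)
})

test_that("config loader rejects malformed configs", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(regions = list(GM = list(t1_ms = 29))), f)
  expect_error(load_compartments(f), "reference")
  yaml::write_yaml(list(
    regions = list(GM = list(t1_ms = 29, t2_fast_ms = 4, t2_slow_ms = 29,
                             weight_fast = 0.6, weight_slow = 0.4,
                             concentration = 51.5)),
    reference = list(t1_ms = 35, t2_fast_ms = 7.15, t2_slow_ms = 33.7,
                     weight_fast = 0.6, weight_slow = 0.4,
                     concentration = 102.67)), f)
  expect_error(load_compartments(f), "WM")
})
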