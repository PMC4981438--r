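test_that("water-content calibration reproduces its anchors and is monotone", {
  cal <- fatouros_calibration()
  expect_equal(fatouros_water_content(1600, cal), 84.44, tolerance = 1e-10)
  expect_equal(fatouros_water_content(cal$t1_csf_anchor, cal), 100,
               tolerance = 1e-10)
  grid <- seq(500, 5000, by = 25)
  expect_true(all(diff(fatouros_water_content(grid, cal)) > 0))
  expect_error(fatouros_water_content(-1, cal), "positive")
  expect_error(fatouros_calibration(a = 1, b = -5), "b > 0")
})

test_that("B1 map inverts the preparation-angle cosine with clamping", {
  dims <- c(4L, 4L, 4L)
  s_ref <- array(100, dims)
  mk <- function(ratio) compute_b1_map(s_ref, array(100 * ratio, dims), 45)
  expect_equal(unique(as.vector(mk(cos(45 * pi / 180))$b1)), 1, tolerance = 1e-12)
  expect_equal(unique(as.vector(mk(cos(40.5 * pi / 180))$b1)), 0.9, tolerance = 1e-12)
  # noise can push the quotient above 1; it is clamped, giving b1 = 0,
  # which the plausibility window later rejects
  over <- mk(1.05)
  expect_equal(unique(as.vector(over$b1)), 0)
  expect_true(all(over$b1 < 0.5))
  # low reference signal marks voxels invalid
  weak <- compute_b1_map(array(c(100, 1e-6), dims),
                         array(70, dims), 45)
  expect_false(all(weak$valid))
  expect_error(compute_b1_map(s_ref, s_ref, 0), "0, 90")
})

test_that("T2* map inverts the dual-echo decay and flags unphysical voxels", {
  dims <- c(2L, 2L, 2L)
  r <- compute_t2star_map(array(100, dims), array(87.459, dims), 4.3, 11)
  expect_equal(unique(as.vector(r$t2star)), 50, tolerance = 1e-4)
  # equal echoes: infinite T2*, kept valid (unit decay correction)
  eq <- compute_t2star_map(array(100, dims), array(100, dims), 4.3, 11)
  expect_true(all(is.infinite(eq$t2star)))
  expect_true(all(eq$valid))
  # signal growing with TE is unphysical
  up <- compute_t2star_map(array(80, dims), array(100, dims), 4.3, 11)
  expect_false(any(up$valid))
  expect_true(all(is.na(up$t2star)))
})

test_that("two-point VFA fit recovers T1 exactly and guards its domain", {
  dims <- c(3L, 3L, 3L)
  mk <- function(t1, b1_true) {
    list(pdw = array(spgr_signal(90, t1, 66, 4, b1 = b1_true), dims),
         t1w = array(spgr_signal(90, t1, 66, 24, b1 = b1_true), dims))
  }
  s <- mk(1400, 1)
  fit <- fit_t1_vfa(s$pdw, s$t1w, b1 = 1)
  expect_true(all(fit$valid))
  expect_lt(max(abs(fit$t1_app - 1400)) / 1400, 1e-9)
  # m0 carries the T2* decay of the acquisition echo
  expect_equal(unique(as.vector(round(fit$m0_app, 9))),
               round(90 * exp(-6.7 / 66), 9))
  # with the true transmit field supplied, recovery is exact off-nominal too
  s8 <- mk(1400, 0.8)
  fit8 <- fit_t1_vfa(s8$pdw, s8$t1w, b1 = array(0.8, dims))
  expect_lt(max(abs(fit8$t1_app - 1400)) / 1400, 1e-9)
  # overestimating B1 (assumed 1.0, true 0.8) shortens apparent T1
  # (flip-angle scaling enters quadratically; direction fixed by
  # brute-force simulation of the forward model)
  wrong <- fit_t1_vfa(s8$pdw, s8$t1w, b1 = 1)
  expect_lt(unique(as.vector(wrong$t1_app)), 1400)
  expect_equal(unique(as.vector(wrong$t1_app)) / 1400, 0.8^2, tolerance = 0.01)
  # a slope at or above 1 (high-angle signal implausibly strong relative
  # to the low-angle one) is flagged, never a crash
  bad <- fit_t1_vfa(array(1, dims), array(10, dims), b1 = 1)
  slope_bad <- (10 / sin(24 * pi / 180) - 1 / sin(4 * pi / 180)) /
    (10 / tan(24 * pi / 180) - 1 / tan(4 * pi / 180))
  expect_gte(slope_bad, 1)
  expect_false(any(bad$valid))
  expect_true(all(is.na(bad$t1_app)))
  # degenerate voxels (equal abscissae) are flagged too
  deg <- fit_t1_vfa(array(1, dims),
                    array(tan(24 * pi / 180) / tan(4 * pi / 180), dims),
                    b1 = 1)
  expect_false(any(deg$valid))
})

test_that("spoiling correction defaults to identity and round-trips YAML", {
  t1 <- array(seq(800, 1600, length.out = 8), c(2, 2, 2))
  expect_equal(apply_spoiling_correction(t1, 1, spoiling_correction()), t1)
  scaled <- spoiling_correction(data.frame(i = 1, j = 0, c = 0.95))
  expect_equal(apply_spoiling_correction(t1, 1, scaled), 0.95 * t1)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_spoiling_correction(scaled, f)
  back <- read_spoiling_correction(f)
  expect_equal(apply_spoiling_correction(t1, 1, back), 0.95 * t1)
})

test_that("receive-bias estimation recovers smooth fields", {
  truth <- flat_truth(dims = c(24L, 24L, 24L), t1 = 900, pd = 69,
                      t2star = 53)
  dims <- dim(truth$labels)
  proto <- acquisition_protocol(noise_sd = 0)
  brain <- truth$labels > 0

  run_fit <- function(bias) {
    acq <- simulate_vfa_pair(truth, proto, bias)
    de <- simulate_dual_echo(truth, bias, noise_sd = 0)
    t2 <- compute_t2star_map(de$s_te1, de$s_te2)
    fit <- fit_t1_vfa(acq$s_pdw, acq$s_t1w, b1 = bias$b1_field)
    decay <- exp(proto$te / t2$t2star)
    decay[is.infinite(t2$t2star)] <- 1
    estimate_receive_bias(fit$m0_app * decay, fit$t1_app,
                          brain & fit$valid & t2$valid)
  }
  # flat field: estimate within 1% of 1 in-brain after normalisation
  est_flat <- run_fit(unit_bias(dims))
  expect_lt(max(abs(est_flat[brain] - 1)), 0.01)
  # second-order polynomial field: recovered up to a global scale
  bias2 <- make_bias_fields(dims, 0, 0.2, order = 2L, seed = 8)
  est2 <- run_fit(bias2)
  ratio <- est2[brain] / bias2$receive_field[brain]
  expect_lt((max(ratio) - min(ratio)) / stats::median(ratio), 0.02)
  # too few voxels is an estimation error
  tiny <- array(FALSE, dims); tiny[1:2, 1, 1] <- TRUE
  expect_error(estimate_receive_bias(array(70, dims), array(900, dims),
                                     tiny), "too few")
})

test_that("PD derivation normalises CSF to 100 and is scale invariant", {
  truth <- flat_truth(t1 = 900, pd = 69, t2star = 53)
  dims <- dim(truth$labels)
  proto <- acquisition_protocol(noise_sd = 0)
  bias <- unit_bias(dims)
  acq <- simulate_acquisitions(truth, proto, bias)
  csf <- truth$labels == TISSUE_CODES[["csf"]]
  t2 <- compute_t2star_map(acq$te1, acq$te2)
  fit <- fit_t1_vfa(acq$pdw, acq$t1w, b1 = 1)
  pd <- derive_pd_map(fit$m0_app, t2$t2star, 1, proto$te, csf)
  expect_equal(median(pd[csf]), 100, tolerance = 1e-9)
  wm_mask <- truth$labels == TISSUE_CODES[["cortex"]]
  expect_lt(abs(mean(pd[wm_mask]) - 69) / 69, 0.005)
  # halving the receive field globally leaves normalised PD unchanged
  pd_half <- derive_pd_map(fit$m0_app, t2$t2star,
                           array(0.5, dims), proto$te, csf)
  expect_equal(pd_half, pd, tolerance = 1e-12)
  expect_error(derive_pd_map(fit$m0_app, t2$t2star, 1, proto$te,
                             array(FALSE, dims)), "empty")
})

test_that("full mapping round-trips a noiseless subject", {
  subj <- sample_subject(cohort_spec(), "patient", seed = 13)
  proto <- acquisition_protocol(noise_sd = 0)
  bias <- unit_bias(dim(subj$labels))
  acq <- simulate_acquisitions(subj, proto, bias)
  brain <- brain_mask(labels = subj$labels)
  csf <- subj$labels == TISSUE_CODES[["csf"]]
  maps <- map_qmri(acq, proto, csf, brain, oracle_bias = bias)
  inb <- brain & maps$valid_mask
  expect_gt(mean(maps$valid_mask[brain]), 0.999)
  expect_lt(max(abs(maps$t1[inb] - subj$true_t1[inb]) / subj$true_t1[inb]),
            1e-6)
  expect_lt(max(abs(maps$pd[inb] - subj$true_pd[inb]) / subj$true_pd[inb]),
            1e-6)
  # B1-map invariance: the quotient cancels PD and the receive profile
  bias2 <- make_bias_fields(dim(subj$labels), 0.1, 0.2, seed = 3)
  pair <- simulate_b1_pair(subj, bias2, 45, noise_sd = 0)
  b1 <- compute_b1_map(pair$s_ref, pair$s_prep, 45)
  expect_lt(max(abs(b1$b1[inb] - bias2$b1_field[inb])), 1e-9)
})
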