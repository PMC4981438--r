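test_that("cubic erosion follows its mm-to-voxel kernel rule", {
  # 5x5x5 cube at 1 mm, 3 mm kernel: the 3x3x3 core survives
  m <- array(FALSE, c(9L, 9L, 9L))
  m[3:7, 3:7, 3:7] <- TRUE
  e <- erode_mask(m, 3, voxel_size = 1)
  expect_equal(sum(e), 27)
  expect_true(all(which(e) %in% which(m)))
  # single voxel vanishes for any kernel of 3 mm or more
  s <- array(FALSE, c(5L, 5L, 5L)); s[3, 3, 3] <- TRUE
  expect_equal(sum(erode_mask(s, 3, voxel_size = 1)), 0)
  # 1-voxel kernel is the identity
  expect_identical(erode_mask(m, 1, voxel_size = 1), m)
  # 6 mm at 2 mm voxels is a 3-voxel cube: 7^3 cube -> 5^3 survivors
  big <- array(FALSE, c(11L, 11L, 11L)); big[3:9, 3:9, 3:9] <- TRUE
  expect_equal(sum(erode_mask(big, 6, voxel_size = 2)), 125)
  # 3 mm at 2 mm voxels rounds to an even edge, forced odd -> identity
  expect_identical(erode_mask(big, 3, voxel_size = 2), big)
})

test_that("erosion is monotone over random masks and kernel sizes", {
  set.seed(99)
  for (rep in 1:5) {
    m <- array(runif(12^3) > 0.35, c(12L, 12L, 12L))
    e3 <- erode_mask(m, 3, voxel_size = 1)
    e5 <- erode_mask(m, 5, voxel_size = 1)
    expect_true(all(which(e3) %in% which(m)))
    expect_true(all(which(e5) %in% which(e3)))
  }
})

test_that("hole filling closes enclosed cavities only", {
  m <- array(FALSE, c(10L, 10L, 10L))
  m[2:9, 2:9, 2:9] <- TRUE
  m[5:6, 5:6, 5:6] <- FALSE        # internal cavity
  m[1:2, 5, 5] <- c(FALSE, FALSE)  # border notch stays open
  f <- fill_holes(m)
  expect_true(all(f[5:6, 5:6, 5:6]))
  expect_false(f[1, 5, 5])
  expect_true(all(f[m]))
})

test_that("cortex weights honour PVE, T1 window and exclusions", {
  dims <- c(4L, 4L, 4L)
  gm <- array(0.97, dims)
  t1 <- array(1400, dims)
  excl <- array(FALSE, dims)
  les <- array(FALSE, dims)
  gm[1, 1, 1] <- 0.94          # below the 0.95 threshold
  t1[2, 1, 1] <- 1700          # outside the 1200-1600 ms window
  excl[3, 1, 1] <- TRUE
  les[4, 1, 1] <- TRUE
  w <- build_cortex_pve(gm, t1, excl, les)
  expect_equal(w[1, 1, 1], 0)
  expect_equal(w[2, 1, 1], 0)
  expect_equal(w[3, 1, 1], 0)
  expect_equal(w[4, 1, 1], 0)
  expect_equal(w[2, 2, 2], 0.97)
  expect_warning(build_cortex_pve(array(0.5, dims), t1, excl, les),
                 "empty")
})

test_that("deep-gray ROIs are eroded then lesion-free", {
  labs <- build_phantom_geometry(phantom_geometry(grid_shape = c(96L, 96L, 96L),
                                                  voxel_size = 1,
                                                  n_lesions = 0L), seed = 3)
  deep <- deep_gm_labels(labs)
  les <- array(FALSE, dim(labs))
  rois <- build_deep_gm_rois(deep, les, voxel_size = 1, kernel_mm = 3)
  for (nm in names(rois)) {
    expect_true(any(rois[[nm]]))
    expect_true(all(which(rois[[nm]]) %in% which(deep[[nm]])))
    expect_lt(sum(rois[[nm]]), sum(deep[[nm]]))  # erosion removed a shell
  }
  # a structure thinner than the kernel empties out, flagged not fatal
  thin <- list(sliver = array(FALSE, dim(labs)))
  thin$sliver[40, 40:60, 40] <- TRUE
  expect_warning(r <- build_deep_gm_rois(thin, les, voxel_size = 1,
                                         kernel_mm = 3), "empty")
  expect_false(any(r$sliver))
  # with lesions disjoint from deep gray, exclusion order is immaterial
  les2 <- array(FALSE, dim(labs)); les2[1:3, 1:3, 1:3] <- TRUE
  a <- build_deep_gm_rois(deep, les2, voxel_size = 1)
  for (nm in names(a)) expect_equal(unname(a[[nm]] & TRUE),
                                    unname(rois[[nm]] & TRUE))
})

test_that("NAWM is binarised, eroded white matter minus lesions", {
  dims <- c(20L, 20L, 20L)
  wm_pve <- array(0, dims)
  wm_pve[4:17, 4:17, 4:17] <- 1
  les <- array(FALSE, dims); les[9:10, 9:10, 9:10] <- TRUE
  roi <- build_nawm_roi(wm_pve, les, voxel_size = 2, kernel_mm = 6)
  expect_false(any(roi & les))
  # without lesions the ROI is exactly the eroded mask
  roi0 <- build_nawm_roi(wm_pve, array(FALSE, dims), voxel_size = 2,
                         kernel_mm = 6)
  eroded <- erode_mask(wm_pve >= 0.95, 6, voxel_size = 2)
  expect_equal(unname(roi0 & TRUE), unname(eroded & TRUE))
  expect_equal(sum(roi0) - sum(roi), sum(les))
})

test_that("whole-brain masks are parameter-specific CSF exclusions", {
  dims <- c(3L, 3L, 3L)
  t1 <- array(1400, dims); pd <- array(80, dims)
  t1[1, 1, 1] <- 4300; pd[1, 1, 1] <- 100   # pure CSF voxel
  t1[2, 1, 1] <- 1650                       # T1 above cutoff only
  pd[3, 1, 1] <- 85                         # PD above 84.44 only
  brain <- array(TRUE, dims)
  wb <- build_whole_brain_mask(t1, pd, brain)
  expect_false(wb$t1[1, 1, 1] || wb$pd[1, 1, 1])
  expect_false(wb$t1[2, 1, 1]); expect_true(wb$pd[2, 1, 1])
  expect_true(wb$t1[3, 1, 1]); expect_false(wb$pd[3, 1, 1])
  expect_true(wb$t1[2, 2, 2] && wb$pd[2, 2, 2])
  joint <- build_whole_brain_mask(t1, pd, brain, joint = TRUE)
  expect_identical(joint$t1, joint$pd)
  expect_false(joint$t1[2, 1, 1] || joint$t1[3, 1, 1])
})

test_that("global gray matter is the maximum of cortex weights and deep masks", {
  dims <- c(4L, 4L, 4L)
  cortex <- array(0, dims); cortex[1, 1, 1] <- 0.97
  deep <- list(pallidum = array(FALSE, dims))
  deep$pallidum[2, 2, 2] <- TRUE
  g <- build_global_gm(cortex, deep)
  expect_equal(g[1, 1, 1], 0.97)
  expect_equal(g[2, 2, 2], 1)
  expect_equal(sum(g > 0), 2)
  # overlap violates the disjointness invariant
  cortex[2, 2, 2] <- 0.96
  expect_error(build_global_gm(cortex, deep), "overlap")
})

test_that("weighted ROI means follow the weight algebra", {
  dims <- c(2L, 1L, 1L)
  v <- array(c(1000, 1400), dims)
  w <- array(c(1, 0.95), dims)
  m <- weighted_roi_mean(v, w, array(TRUE, dims))
  expect_equal(m$mean, (1000 + 1400 * 0.95) / 1.95, tolerance = 1e-12)
  expect_equal(m$weight_sum, 1.95)
  # uniform map: weights are immaterial
  u <- weighted_roi_mean(array(1400, dims), w, array(TRUE, dims))
  expect_equal(u$mean, 1400)
  # all-zero weights flag the measurement
  z <- weighted_roi_mean(v, array(0, dims), array(TRUE, dims))
  expect_true(z$empty)
  expect_true(is.na(z$mean))
})

test_that("no ROI ever overlaps the lesion mask", {
  cfg <- pipeline_config(save_volumes = FALSE, seed = 6)
  subj <- sample_subject(cfg$cohort, "patient", seed = 17)
  res <- qgmri:::process_subject(subj, cfg, seed = 5)
  for (nm in names(res$extraction$rois)) {
    roi <- res$extraction$rois[[nm]]
    if (startsWith(nm, "whole_brain")) next  # whole brain retains lesions
    expect_equal(sum((roi > 0) & subj$lesion_mask), 0, label = nm)
  }
})
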