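test_that("Mann-Whitney U matches brute-force enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1, tolerance = 1e-12)  # 2/20 orderings as extreme
  # identical samples: p is 1 (ties force the corrected approximation)
  same <- mann_whitney_u(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_gt(same$p, 0.95)
  # swapping labels preserves p and reflects U
  a <- c(0.3, 1.7, 2.2, 5.1); b <- c(0.9, 3.3, 4.8)
  ab <- mann_whitney_u(a, b); ba <- mann_whitney_u(b, a)
  expect_equal(ab$p, ba$p)
  expect_equal(ba$U, length(a) * length(b) - ab$U)
  expect_error(mann_whitney_u(1, c(1, 2)), "at least 2")
})

test_that("Spearman correlation matches the rank closed form", {
  r <- spearman_rank(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$r, 0.8, tolerance = 1e-12)  # 1 - 6*2/(4*15)
  expect_equal(r$r, spearman_d2(c(1, 2, 3, 4), c(1, 3, 2, 4)))
  # strictly monotone pairing
  expect_equal(spearman_rank(1:6, c(2, 5, 9, 14, 20, 33))$r, 1)
  # antisymmetry under reversal
  expect_equal(spearman_rank(c(1, 2, 3, 4), rev(c(1, 3, 2, 4)))$r, -0.8,
               tolerance = 1e-12)
  # constant input leaves r undefined, flagged not fatal
  flat <- spearman_rank(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_false(flat$defined)
  expect_true(is.na(flat$r))
})

test_that("gating reports correlations only for significant increases", {
  set.seed(10)
  # cortex PD: huge increase; cortex T1: no effect; wm PD: huge DECREASE
  meas <- rbind(
    toy_measurements(rnorm(11, 90, 1), rnorm(11, 80, 1), "cortex", "pd"),
    toy_measurements(rnorm(11, 1400, 20), rnorm(11, 1400, 20), "cortex", "t1"),
    toy_measurements(rnorm(11, 60, 1), rnorm(11, 70, 1), "wm", "pd"))
  covs <- toy_covariates(11, 11)
  rep <- gated_analysis(meas, covs)
  gt <- rep$group_table; ct <- rep$cor_table
  expect_true(gt$significant[gt$roi == "cortex" & gt$parameter == "pd"])
  expect_true(gt$significant[gt$roi == "wm" & gt$parameter == "pd"])
  tested <- ct[ct$tested, ]
  expect_true(all(tested$roi == "cortex" & tested$parameter == "pd"))
  # the decreased cell stays in the group table but is never correlated
  expect_false(any(ct$tested[ct$roi == "wm"]))
  # untested cells carry no r or p
  expect_true(all(is.na(ct$r[!ct$tested])))
  # two-sided gating admits the decrease as well
  rep2 <- gated_analysis(meas, covs, direction = "two_sided")
  expect_true(any(rep2$cor_table$tested[rep2$cor_table$roi == "wm"]))
  # degenerate gate: alpha 1 with two-sided direction tests every cell
  rep3 <- gated_analysis(meas, covs, alpha = 1, direction = "two_sided")
  expect_true(all(rep3$cor_table$tested))
})

test_that("a subject missing from the covariates is an error naming it", {
  meas <- toy_measurements(c(80, 81, 82), c(78, 79, 80))
  covs <- toy_covariates(3, 3)
  covs <- covs[covs$subject_id != "p02", ]
  expect_error(gated_analysis(meas, covs), "p02")
})

test_that("gate soundness holds across random tables", {
  set.seed(77)
  for (rep_i in 1:10) {
    meas <- rbind(
      toy_measurements(rnorm(8, 80 + runif(1, -2, 4)), rnorm(8, 80), "a", "pd"),
      toy_measurements(rnorm(8, 1400 + runif(1, -40, 40)), rnorm(8, 1400), "b", "t1"))
    covs <- toy_covariates(8, 8, seed = rep_i)
    rep <- gated_analysis(meas, covs)
    gt <- rep$group_table
    for (i in seq_len(nrow(gt))) {
      rows <- rep$cor_table[rep$cor_table$roi == gt$roi[i] &
                              rep$cor_table$parameter == gt$parameter[i], ]
      gate <- gt$significant[i] && gt$patient_mean[i] > gt$control_mean[i]
      if (!gate) expect_false(any(rows$tested))
    }
  }
})

test_that("EDSS-linked generator yields positive cortex-T1 correlations that grow with the slope", {
  median_r <- function(slope) {
    spec <- cohort_spec(link_slope_t1 = slope, link_slope_pd = 0)
    seeds <- qgmri:::derive_seeds(314 + round(slope), 100)
    rs <- vapply(seeds, function(s) {
      tl <- truth_level_cohort(spec, seed = s)
      m <- merge(tl$measurements, tl$covariates, by = "subject_id")
      pat <- m[m$group == "patient" & m$roi == "cortex" & m$parameter == "t1", ]
      cor(pat$mean, pat$edss, method = "spearman")
    }, 0)
    median(rs)
  }
  r_small <- median_r(7)
  r_large <- median_r(28)
  expect_gt(r_small, 0)
  expect_gt(r_large, r_small)
})

test_that("power experiment is calibrated and monotone in n", {
  null_spec <- cohort_spec(n_per_group = 11L,
                           tissue_patients = tissue_defaults("control"),
                           link_slope_t1 = 0, link_slope_pd = 0)
  pw <- power_experiment(null_spec, n_replicates = 200L, seed = 2)
  cell <- pw[pw$roi == "cortex" & pw$parameter == "pd", ]
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(cell$rejection_fraction - 0.05), 3 * se)

  # doubling the group size does not reduce power (within Monte-Carlo error)
  eff <- cohort_spec(link_slope_t1 = 0, link_slope_pd = 0)
  p11 <- power_experiment(eff, n_replicates = 150L, seed = 3)
  eff22 <- cohort_spec(n_per_group = 22L, link_slope_t1 = 0,
                       link_slope_pd = 0)
  p22 <- power_experiment(eff22, n_replicates = 150L, seed = 3)
  c11 <- p11[p11$roi == "cortex" & p11$parameter == "pd", ]
  c22 <- p22[p22$roi == "cortex" & p22$parameter == "pd", ]
  expect_gte(c22$rejection_fraction,
             c11$rejection_fraction - 2 * (c11$mc_se + c22$mc_se))
})
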