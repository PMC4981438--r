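# Shared fixtures: all built in code at test time.

# A uniform single-tissue "subject": one tissue block plus a CSF block,
# embedded in background, for acquisition/mapping unit tests.
flat_truth <- function(dims = c(16L, 16L, 16L), t1 = 1400, pd = 80,
                       t2star = 66, voxel_size = 2) {
  labels <- array(0L, dims)
  labels[3:(dims[1] - 2), 3:(dims[2] - 2), 3:(dims[3] - 2)] <-
    qgmri::TISSUE_CODES[["cortex"]]
  labels[7:10, 7:10, 7:10] <- qgmri::TISSUE_CODES[["csf"]]
  vol <- function(tissue_val, csf_val) {
    v <- array(0, dims)
    v[labels == qgmri::TISSUE_CODES[["cortex"]]] <- tissue_val
    v[labels == qgmri::TISSUE_CODES[["csf"]]] <- csf_val
    with_voxel_size(v, voxel_size)
  }
  structure(list(
    labels = with_voxel_size(labels, voxel_size),
    true_t1 = vol(t1, 4300),
    true_pd = vol(pd, 100),
    true_t2star = vol(t2star, 500),
    lesion_mask = with_voxel_size(array(FALSE, dims), voxel_size),
    tissue_values = list(t1 = c(cortex = t1, csf = 4300),
                         pd = c(cortex = pd, csf = 100),
                         t2star = c(cortex = t2star, csf = 500)),
    group = "control", edss = NA_real_, age = 40, sex = 0L,
    disease_duration = NA_real_, subject_id = "flat", seed = 1L
  ), class = "subject_truth")
}

unit_bias <- function(dims) make_bias_fields(dims, 0, 0)

# Brute-force Mann-Whitney: exact two-sided p by enumeration of all
# assignments of the pooled ranks to group A (tie-free inputs only).
enumerate_mwu <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!any(duplicated(pooled)))
  n1 <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  })
  n1n2 <- n1 * length(b)
  # two-sided: double the smaller tail (U distribution is symmetric)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(U = u_obs, p = min(p, 1))
}

# Spearman closed form for tie-free data: 1 - 6 sum(d^2) / (n (n^2 - 1)).
spearman_d2 <- function(x, y) {
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (length(x) * (length(x)^2 - 1))
}

# Small measurement/covariate tables built from per-group generators, for
# statistics tests that bypass the imaging pipeline.
toy_measurements <- function(values_pat, values_ctl, roi = "cortex",
                             parameter = "pd") {
  n1 <- length(values_pat)
  n2 <- length(values_ctl)
  data.frame(
    subject_id = c(sprintf("p%02d", seq_len(n1)), sprintf("c%02d", seq_len(n2))),
    roi = roi, parameter = parameter,
    mean = c(values_pat, values_ctl), empty = FALSE)
}

toy_covariates <- function(n_pat, n_ctl, edss = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(edss)) edss <- sample(seq(3, 8.5, by = 0.5), n_pat, replace = TRUE)
  data.frame(
    subject_id = c(sprintf("p%02d", seq_len(n_pat)),
                   sprintf("c%02d", seq_len(n_ctl))),
    group = rep(c("patient", "control"), c(n_pat, n_ctl)),
    edss = c(edss, rep(NA_real_, n_ctl)),
    age = rnorm(n_pat + n_ctl, 45, 10),
    sex = rbinom(n_pat + n_ctl, 1, 0.4),
    disease_duration = c(pmax(rnorm(n_pat, 15, 6), 1), rep(NA_real_, n_ctl)))
}
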