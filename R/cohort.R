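# Two-group synthetic cohorts whose per-tissue T1/PD population values match
# published group statistics for secondary-progressive MS patients and
# healthy controls, with a configurable monotone disability link.

#' Default per-tissue population values
#'
#' T1 (ms) and PD (pu, percent of CSF water) means and between-subject SDs
#' per tissue and group; cortex and the four deep-gray structures carry the
#' group statistics of the emulated study population, white matter those of
#' normal-appearing white matter. CSF is the PD anchor (100 pu exactly,
#' SD 0). T2* (ms) is a fixed per-tissue constant at 3 T; lesions (patients
#' only) get mildly prolonged T1 and raised water content.
#'
#' @param group `"patient"` or `"control"`.
#' @return data.frame with columns name, t1_mean, t1_sd, pd_mean, pd_sd,
#'   t2star.
#' @export
tissue_defaults <- function(group = c("patient", "control")) {
  group <- match.arg(group)
  t2s <- c(csf = 500, cortex = 66, wm = 53, thalamus = 58,
           caudate = 50, putamen = 45, pallidum = 35, lesion = 70)
  if (group == "patient") {
    tab <- data.frame(
      name    = c("csf", "cortex", "wm", "thalamus", "caudate", "putamen",
                  "pallidum", "lesion"),
      t1_mean = c(4300, 1425.9, 911.0, 1252.6, 1326.7, 1264.5, 1003.4, 1500),
      t1_sd   = c(0, 27.09, 41.16, 83.98, 48.93, 54.64, 49.08, 80),
      pd_mean = c(100, 83.8, 71.7, 78.7, 81.8, 82.5, 77.1, 86),
      pd_sd   = c(0, 1.91, 2.49, 2.01, 2.51, 2.91, 2.63, 2)
    )
  } else {
    tab <- data.frame(
      name    = c("csf", "cortex", "wm", "thalamus", "caudate", "putamen",
                  "pallidum", "lesion"),
      t1_mean = c(4300, 1403.0, 865.8, 1184.4, 1343.1, 1278.6, 1016.2, 1500),
      t1_sd   = c(0, 15.93, 28.75, 54.55, 43.30, 39.96, 42.15, 80),
      pd_mean = c(100, 80.8, 67.9, 75.6, 80.2, 79.7, 74.4, 86),
      pd_sd   = c(0, 1.67, 1.68, 2.60, 2.01, 1.69, 1.76, 2)
    )
  }
  tab$t2star <- unname(t2s[tab$name])
  validate_tissue_table(tab)
  tab
}

validate_tissue_table <- function(tab) {
  need <- c("name", "t1_mean", "t1_sd", "pd_mean", "pd_sd", "t2star")
  if (!all(need %in% names(tab))) {
    stop("tissue table must have columns: ", paste(need, collapse = ", "))
  }
  stopifnot(all(tab$t1_mean > 0), all(tab$t2star > 0),
            all(tab$pd_mean > 0), all(tab$t1_sd >= 0), all(tab$pd_sd >= 0))
  non_csf <- tab$name != "csf"
  if (any(tab$pd_mean[non_csf] > 100)) {
    stop("non-CSF pd_mean must be <= 100 pu")
  }
  if ("csf" %in% tab$name && tab$pd_mean[tab$name == "csf"] != 100) {
    stop("CSF pd_mean must be exactly 100 pu (the normalisation anchor)")
  }
  invisible(tab)
}

# Tissues whose values are shifted by the disability link.
LINKED_TISSUES <- c("cortex", "thalamus", "caudate", "putamen", "pallidum")

#' Cohort specification
#'
#' @param n_per_group subjects per group (>= 2).
#' @param tissue_patients,tissue_controls per-group tissue tables, see
#'   [tissue_defaults()].
#' @param edss_mean,edss_sd,edss_min,edss_max parameters of the truncated
#'   Gaussian the patient EDSS is drawn from (rounded to 0.5 steps).
#' @param link_slope_t1,link_slope_pd linear shift of cortical and deep-gray
#'   tissue values per EDSS point (ms/point, pu/point), applied about the
#'   configured EDSS mean. Defaults give a population rank correlation of
#'   roughly 0.7 between EDSS and cortical values.
#' @param link_noise_sd_t1,link_noise_sd_pd SD of additive Gaussian noise on
#'   the link (ms, pu).
#' @param age_mean_patients,age_sd_patients,age_mean_controls,age_sd_controls
#'   age distributions (years); defaults keep the groups age-matched.
#' @param duration_mean,duration_sd disease duration (years), patients only.
#' @param male_frac_patients,male_frac_controls probability of sex code 1.
#' @param geometry a [phantom_geometry()].
#' @param seed master seed; every per-subject stream is derived from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 11L,
                        tissue_patients = tissue_defaults("patient"),
                        tissue_controls = tissue_defaults("control"),
                        edss_mean = 5.8, edss_sd = 1.88,
                        edss_min = 3, edss_max = 8.5,
                        link_slope_t1 = 14, link_slope_pd = 1.0,
                        link_noise_sd_t1 = 0, link_noise_sd_pd = 0,
                        age_mean_patients = 46.8, age_sd_patients = 11.03,
                        age_mean_controls = 43.6, age_sd_controls = 11.17,
                        duration_mean = 15.3, duration_sd = 6.75,
                        male_frac_patients = 4 / 11,
                        male_frac_controls = 5 / 11,
                        geometry = phantom_geometry(),
                        seed = 1L) {
  stopifnot(n_per_group >= 2, edss_min <= edss_max, edss_sd >= 0)
  validate_tissue_table(tissue_patients)
  validate_tissue_table(tissue_controls)
  structure(as.list(environment()), class = "cohort_spec")
}

# Truncated-Gaussian draw by rejection, with a hard cap on redraws.
rtrunc_norm <- function(n, mean, sd, lower, upper, max_redraw = 10000L) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > max_redraw) stop("rejection sampling failed to converge")
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Draw one patient EDSS score
#'
#' Truncated Gaussian (rejection sampling) rounded to the 0.5-step
#' granularity of the scale.
#' @param cohort a [cohort_spec()].
#' @param n number of draws.
#' @return numeric vector in `[edss_min, edss_max]`, multiples of 0.5.
#' @export
draw_edss <- function(cohort, n = 1L) {
  x <- rtrunc_norm(n, cohort$edss_mean, cohort$edss_sd,
                   cohort$edss_min, cohort$edss_max)
  pmin(pmax(round(x * 2) / 2, cohort$edss_min), cohort$edss_max)
}

# Per-subject tissue parameter draw: group Gaussians, then (patients) the
# EDSS link shift on cortex and deep gray. Negative draws are rejected with
# a redraw cap.
draw_tissue_values <- function(cohort, group, edss = NULL) {
  tab <- if (group == "patient") cohort$tissue_patients else cohort$tissue_controls
  draw_one <- function(mean, sd) {
    for (i in 1:100) {
      v <- rnorm(1, mean, sd)
      if (v > 0) return(v)
    }
    stop("exceeded redraw cap for a tissue parameter (mean ", mean, ")")
  }
  t1 <- mapply(draw_one, tab$t1_mean, tab$t1_sd)
  pd <- mapply(draw_one, tab$pd_mean, tab$pd_sd)
  names(t1) <- names(pd) <- tab$name
  if (group == "patient" && !is.null(edss)) {
    linked <- intersect(LINKED_TISSUES, tab$name)
    de <- edss - cohort$edss_mean
    t1[linked] <- t1[linked] + cohort$link_slope_t1 * de +
      rnorm(length(linked), 0, cohort$link_noise_sd_t1)
    pd[linked] <- pd[linked] + cohort$link_slope_pd * de +
      rnorm(length(linked), 0, cohort$link_noise_sd_pd)
  }
  if (any(t1 <= 0) || any(pd <= 0)) stop("linked tissue value became non-positive")
  t2s <- tab$t2star
  names(t2s) <- tab$name
  list(t1 = t1, pd = pd, t2star = t2s)
}

#' Sample one synthetic subject
#'
#' Draws clinical covariates and per-tissue parameter values, then paints
#' ground-truth T1/PD/T2* volumes over the phantom labels. Parameter volumes
#' are constant within each tissue label (before any acquisition bias or
#' noise). Patients get the EDSS-linked shift of cortical and deep-gray
#' values and white-matter lesions; controls are lesion-free.
#'
#' @param cohort a [cohort_spec()].
#' @param group `"patient"` or `"control"`.
#' @param seed integer stream seed for this subject.
#' @param subject_id optional identifier.
#' @return object of class `subject_truth` with elements labels, true_t1,
#'   true_pd, true_t2star, lesion_mask, group, edss, age, sex,
#'   disease_duration, subject_id, seed.
#' @export
sample_subject <- function(cohort, group = c("patient", "control"),
                           seed = 1L, subject_id = NULL) {
  group <- match.arg(group)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  edss <- if (group == "patient") draw_edss(cohort) else NA_real_
  vals <- draw_tissue_values(cohort, group, edss = edss)
  age <- if (group == "patient") {
    rnorm(1, cohort$age_mean_patients, cohort$age_sd_patients)
  } else {
    rnorm(1, cohort$age_mean_controls, cohort$age_sd_controls)
  }
  sex <- rbinom(1, 1, if (group == "patient") cohort$male_frac_patients
                      else cohort$male_frac_controls)
  duration <- if (group == "patient") {
    max(rnorm(1, cohort$duration_mean, cohort$duration_sd), 1)
  } else NA_real_

  geom <- cohort$geometry
  if (group == "control") {
    geom$n_lesions <- 0L
  }
  labels <- build_phantom_geometry(geom, seed = seed)
  vs <- voxel_size(labels)

  paint <- function(values) {
    vol <- array(0, dim(labels))
    for (nm in names(values)) {
      code <- TISSUE_CODES[[nm]]
      vol[labels == code] <- values[[nm]]
    }
    with_voxel_size(vol, vs)
  }
  structure(list(
    labels = labels,
    true_t1 = paint(vals$t1),
    true_pd = paint(vals$pd),
    true_t2star = paint(vals$t2star),
    lesion_mask = with_voxel_size(labels == TISSUE_CODES[["lesion"]], vs),
    tissue_values = vals,
    group = group, edss = edss, age = age, sex = sex,
    disease_duration = duration,
    subject_id = if (is.null(subject_id)) paste0(substr(group, 1, 1), seed)
                 else subject_id,
    seed = as.integer(seed)
  ), class = "subject_truth")
}

#' Generate a full two-group cohort
#'
#' Per-subject seeds are derived deterministically from the master seed, so
#' an identical specification reproduces an identical cohort.
#'
#' @param cohort a [cohort_spec()].
#' @return list of `subject_truth` (patients first).
#' @export
generate_cohort <- function(cohort) {
  n <- cohort$n_per_group
  seeds <- derive_seeds(cohort$seed, 2L * n)
  subjects <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    subjects[[i]] <- sample_subject(cohort, "patient", seed = seeds[i],
                                    subject_id = sprintf("pat%02d", i))
  }
  for (i in seq_len(n)) {
    subjects[[n + i]] <- sample_subject(cohort, "control", seed = seeds[n + i],
                                        subject_id = sprintf("ctl%02d", i))
  }
  subjects
}

#' Cohort covariate table
#' @param subjects list of `subject_truth`.
#' @return data.frame with subject_id, group, edss, age, sex,
#'   disease_duration, seed.
#' @export
cohort_covariates <- function(subjects) {
  data.frame(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    group = vapply(subjects, `[[`, "", "group"),
    edss = vapply(subjects, `[[`, 0, "edss"),
    age = vapply(subjects, `[[`, 0, "age"),
    sex = vapply(subjects, `[[`, 0L, "sex"),
    disease_duration = vapply(subjects, `[[`, 0, "disease_duration"),
    seed = vapply(subjects, `[[`, 0L, "seed")
  )
}

#' Write a subject's ground truth as NIfTI plus covariates
#' @param subject a `subject_truth`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_subject_truth <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- subject$subject_id
  paths <- c(
    write_volume(subject$labels, file.path(dir, paste0(id, "_labels.nii.gz")),
                 datatype = "uint8"),
    write_volume(subject$true_t1, file.path(dir, paste0(id, "_true_t1.nii.gz"))),
    write_volume(subject$true_pd, file.path(dir, paste0(id, "_true_pd.nii.gz"))),
    write_volume(subject$true_t2star,
                 file.path(dir, paste0(id, "_true_t2star.nii.gz"))),
    write_volume(subject$lesion_mask,
                 file.path(dir, paste0(id, "_lesions.nii.gz")),
                 datatype = "uint8")
  )
  invisible(paths)
}
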