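# Nonparametric group comparison and gated disability correlations.
# Group differences per ROI and parameter use the Mann-Whitney U test;
# correlations with clinical covariates are computed only for cells whose
# parameter is significantly increased in the patient group (the gate).

#' Mann-Whitney U test
#'
#' Exact two-sided p by enumeration of the U distribution for combined
#' sample sizes up to `exact_limit` without ties; normal approximation with
#' tie correction (and continuity correction) otherwise. U is counted for
#' the first sample.
#'
#' @param group_a,group_b numeric vectors (each length >= 2).
#' @param exact_limit combined-size threshold for the exact test.
#' @return list with `U` and `p`.
#' @export
mann_whitney_u <- function(group_a, group_b, exact_limit = 25L) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 observations")
  }
  ties <- any(duplicated(c(group_a, group_b)))
  use_exact <- !ties && (length(group_a) + length(group_b)) <= exact_limit
  wt <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = use_exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Spearman rank correlation
#'
#' Tie-aware Pearson correlation on average ranks, with the p-value from
#' the t approximation. A constant input vector leaves the correlation
#' undefined; the result is flagged rather than an error.
#'
#' @param x,y paired numeric vectors, length >= 3 (binary covariates coded
#'   0/1 before ranking).
#' @return list with `r`, `p` and `defined`.
#' @export
spearman_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, defined = FALSE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, defined = TRUE)
}

#' Gated group-comparison and correlation analysis
#'
#' Step 1: a Mann-Whitney U test per ROI x parameter cell (patients vs
#' controls). Step 2: for every cell with `p < alpha` whose patient mean
#' exceeds the control mean (a significant increase; set
#' `direction = "two_sided"` to gate on significance alone), patient-only
#' Spearman correlations of the measurement with EDSS, age, sex and disease
#' duration. All other cells are marked untested.
#'
#' @param measurements long-format data.frame with subject_id, roi,
#'   parameter, mean (one row per subject x ROI x parameter); flagged-empty
#'   rows (`empty == TRUE`) are dropped.
#' @param covariates data.frame with subject_id, group, edss, age, sex,
#'   disease_duration.
#' @param alpha significance level (default 0.05).
#' @param direction `"increase"` (default) or `"two_sided"` gating.
#' @param p_adjust multiple-testing correction for the group comparisons
#'   (`"none"`, default, or any [stats::p.adjust] method such as `"holm"`).
#' @return object of class `stat_report`: `group_table` (roi, parameter,
#'   patient mean/SD, control mean/SD, U, p, significant) and `cor_table`
#'   (roi, parameter, covariate, r, p, tested).
#' @export
gated_analysis <- function(measurements, covariates, alpha = 0.05,
                           direction = c("increase", "two_sided"),
                           p_adjust = "none") {
  direction <- match.arg(direction)
  if ("empty" %in% names(measurements)) {
    measurements <- measurements[!measurements$empty, ]
  }
  missing_subj <- setdiff(unique(measurements$subject_id),
                          covariates$subject_id)
  if (length(missing_subj) > 0) {
    stop("subjects absent from the covariate table: ",
         paste(missing_subj, collapse = ", "))
  }
  m <- merge(measurements, covariates, by = "subject_id")
  cells <- unique(m[, c("roi", "parameter")])
  cells <- cells[order(cells$roi, cells$parameter), ]

  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- m[m$roi == cells$roi[i] & m$parameter == cells$parameter[i], ]
    pat <- sub$mean[sub$group == "patient"]
    ctl <- sub$mean[sub$group == "control"]
    if (length(pat) < 2 || length(ctl) < 2) {
      stop("both groups must be present for ", cells$roi[i], "/",
           cells$parameter[i])
    }
    mw <- mann_whitney_u(pat, ctl)
    rows[[i]] <- data.frame(
      roi = cells$roi[i], parameter = cells$parameter[i],
      patient_mean = mean(pat), patient_sd = sd(pat),
      control_mean = mean(ctl), control_sd = sd(ctl),
      U = mw$U, p = mw$p
    )
  }
  group_table <- do.call(rbind, rows)
  group_table$p_adjusted <- stats::p.adjust(group_table$p, method = p_adjust)
  group_table$significant <- group_table$p_adjusted < alpha

  covs <- c("edss", "age", "sex", "disease_duration")
  cor_rows <- list()
  for (i in seq_len(nrow(group_table))) {
    g <- group_table[i, ]
    gate <- g$significant &&
      (direction == "two_sided" || g$patient_mean > g$control_mean)
    sub <- m[m$roi == g$roi & m$parameter == g$parameter &
               m$group == "patient", ]
    for (cv in covs) {
      if (gate) {
        sr <- spearman_rank(sub$mean, sub[[cv]])
        cor_rows[[length(cor_rows) + 1L]] <- data.frame(
          roi = g$roi, parameter = g$parameter, covariate = cv,
          r = sr$r, p = sr$p, tested = sr$defined)
      } else {
        cor_rows[[length(cor_rows) + 1L]] <- data.frame(
          roi = g$roi, parameter = g$parameter, covariate = cv,
          r = NA_real_, p = NA_real_, tested = FALSE)
      }
    }
  }
  cor_table <- do.call(rbind, cor_rows)
  structure(list(group_table = group_table, cor_table = cor_table,
                 alpha = alpha, direction = direction),
            class = "stat_report")
}

#' Truth-level measurements of a cohort
#'
#' Per-subject tissue parameter values (no imaging simulation) arranged as
#' a measurement table, for statistical validation at scale.
#'
#' @param cohort a [cohort_spec()].
#' @param seed integer.
#' @return list with `measurements` and `covariates`.
#' @export
truth_level_cohort <- function(cohort, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  n <- cohort$n_per_group
  rows <- list()
  cov_rows <- list()
  for (g in c("patient", "control")) {
    tab <- if (g == "patient") cohort$tissue_patients else cohort$tissue_controls
    for (i in seq_len(n)) {
      id <- sprintf("%s%02d", substr(g, 1, 3), i)
      edss <- if (g == "patient") draw_edss(cohort) else NA_real_
      vals <- draw_tissue_values(cohort, g, edss = edss)
      keep <- setdiff(tab$name, c("csf", "lesion"))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id,
        roi = rep(keep, 2L),
        parameter = rep(c("t1", "pd"), each = length(keep)),
        mean = c(vals$t1[keep], vals$pd[keep]),
        empty = FALSE)
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        subject_id = id, group = g, edss = edss,
        age = rnorm(1, if (g == "patient") cohort$age_mean_patients
                       else cohort$age_mean_controls,
                    if (g == "patient") cohort$age_sd_patients
                    else cohort$age_sd_controls),
        sex = rbinom(1, 1, if (g == "patient") cohort$male_frac_patients
                           else cohort$male_frac_controls),
        disease_duration = if (g == "patient") {
          max(rnorm(1, cohort$duration_mean, cohort$duration_sd), 1)
        } else NA_real_)
    }
  }
  list(measurements = do.call(rbind, rows),
       covariates = do.call(rbind, cov_rows))
}

#' Monte-Carlo rejection rates of the group comparison
#'
#' Repeatedly generates truth-level cohorts, applies the Mann-Whitney test
#' per ROI x parameter cell and reports the fraction of replicates with
#' `p < alpha`, with the binomial Monte-Carlo standard error. With
#' identical group distributions this is a type-I-error calibration; with
#' distinct means it is a power estimate.
#'
#' @param cohort a [cohort_spec()].
#' @param n_replicates number of simulated cohorts.
#' @param alpha significance level.
#' @param seed integer master seed.
#' @return data.frame with roi, parameter, rejection_fraction, mc_se,
#'   n_replicates.
#' @export
power_experiment <- function(cohort, n_replicates = 500L, alpha = 0.05,
                             seed = 1L) {
  seeds <- derive_seeds(seed, n_replicates)
  counts <- NULL
  for (r in seq_len(n_replicates)) {
    tl <- truth_level_cohort(cohort, seed = seeds[r])
    m <- merge(tl$measurements, tl$covariates[, c("subject_id", "group")],
               by = "subject_id")
    cells <- unique(m[, c("roi", "parameter")])
    cells <- cells[order(cells$roi, cells$parameter), ]
    rej <- logical(nrow(cells))
    for (i in seq_len(nrow(cells))) {
      sub <- m[m$roi == cells$roi[i] & m$parameter == cells$parameter[i], ]
      mw <- mann_whitney_u(sub$mean[sub$group == "patient"],
                           sub$mean[sub$group == "control"])
      rej[i] <- mw$p < alpha
    }
    if (is.null(counts)) {
      counts <- cbind(cells, n_reject = as.integer(rej))
    } else {
      counts$n_reject <- counts$n_reject + as.integer(rej)
    }
  }
  frac <- counts$n_reject / n_replicates
  data.frame(roi = counts$roi, parameter = counts$parameter,
             rejection_fraction = frac,
             mc_se = sqrt(pmax(frac * (1 - frac), 1e-12) / n_replicates),
             n_replicates = n_replicates)
}

#' Write the report tables
#' @param report a `stat_report`.
#' @param dir output directory.
#' @return invisibly, the two paths (`table1.tsv`, `table2.tsv`).
#' @export
write_stat_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "table1.tsv")
  p2 <- file.path(dir, "table2.tsv")
  write.table(report$group_table, p1, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report$cor_table, p2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(p1, p2))
}
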