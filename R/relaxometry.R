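# Map estimation: B1 from the prepared/reference quotient, T2* from the
# dual-echo log-ratio, T1 and equilibrium signal from the two-point
# variable-flip-angle linearisation, and PD from the corrected equilibrium
# signal with CSF normalisation.

#' Water-content calibration (Fatouros relation)
#'
#' Tissue water content as a function of T1: `W(t1) = 1/(a + b/t1)`
#' (fractional; multiplied by 100 for percentage units). The default 3 T
#' calibration is fixed by two anchors: `W = 1` at the CSF T1 anchor and
#' `W = 0.8444` at 1600 ms; `a` and `b` follow from the 2x2 linear system.
#' Literature coefficients can be substituted directly via `a` and `b`.
#'
#' @param t1_csf_anchor CSF T1, ms (default 4300).
#' @param t1_ref,w_ref second anchor: T1 (ms) and fractional water content.
#' @param a,b explicit coefficients (override the anchors when both given).
#' @return object of class `fatouros_calibration` with fields a, b (ms),
#'   t1_csf_anchor.
#' @export
fatouros_calibration <- function(t1_csf_anchor = 4300, t1_ref = 1600,
                                 w_ref = 0.8444, a = NULL, b = NULL) {
  if (is.null(a) || is.null(b)) {
    m <- rbind(c(1, 1 / t1_csf_anchor), c(1, 1 / t1_ref))
    ab <- solve(m, c(1, 1 / w_ref))
    a <- ab[1]
    b <- ab[2]
  }
  if (b <= 0) stop("calibration requires b > 0 (monotone water content)")
  structure(list(a = a, b = b, t1_csf_anchor = t1_csf_anchor),
            class = "fatouros_calibration")
}

#' Water content predicted from T1
#'
#' @param t1 T1 in ms (> 0), scalar or array.
#' @param cal a [fatouros_calibration()].
#' @return water content in percentage units (CSF anchor = 100 pu).
#' @export
fatouros_water_content <- function(t1, cal = fatouros_calibration()) {
  if (any(t1 <= 0, na.rm = TRUE)) stop("t1 must be positive")
  100 / (cal$a + cal$b / t1)
}

#' PD cutoff equivalent to a T1 cutoff
#'
#' The whole-brain CSF exclusion removes voxels above a T1 threshold from
#' the T1 maps and voxels above the water content corresponding to that
#' threshold from the PD maps.
#' @param t1_cutoff ms (default 1600).
#' @param cal a [fatouros_calibration()].
#' @return PD threshold in pu (84.44 under the defaults).
#' @export
csf_pd_threshold <- function(t1_cutoff = 1600, cal = fatouros_calibration()) {
  fatouros_water_content(t1_cutoff, cal)
}

#' Compute the B1 map from the prepared/reference quotient
#'
#' The quotient of the prepared and reference volumes is the cosine of the
#' local preparation angle; B1 is the ratio of that angle to the nominal
#' one. The quotient is clamped to `[-1, 1]` before the arccosine; voxels
#' with reference signal at or below `ref_threshold` are marked invalid.
#'
#' @param s_ref,s_prep volumes on one grid.
#' @param nominal_prep_angle degrees, in (0, 90).
#' @param ref_threshold reference-signal floor; `NULL` uses 1 percent of the
#'   99th percentile of `s_ref`.
#' @return list with `b1` (dimensionless volume) and `valid` (logical).
#' @export
compute_b1_map <- function(s_ref, s_prep, nominal_prep_angle = 45,
                           ref_threshold = NULL) {
  check_same_grid(s_ref, s_prep)
  if (nominal_prep_angle <= 0 || nominal_prep_angle >= 90) {
    stop("nominal preparation angle must lie in (0, 90) degrees")
  }
  if (is.null(ref_threshold)) {
    ref_threshold <- 0.01 * quantile(s_ref, 0.99, names = FALSE)
  }
  valid <- s_ref > ref_threshold
  ratio <- array(NA_real_, dim(s_ref))
  ratio[valid] <- pmin(pmax(s_prep[valid] / s_ref[valid], -1), 1)
  b1 <- array(NA_real_, dim(s_ref))
  b1[valid] <- acos(ratio[valid]) / (nominal_prep_angle * pi / 180)
  list(b1 = b1, valid = valid & is.finite(b1))
}

#' Compute the T2* map from a dual-echo pair
#'
#' `t2star = (te2 - te1) / log(s_te1 / s_te2)`. Non-positive and NaN results
#' are flagged invalid; an infinite T2* (equal echoes) is kept valid, its
#' decay correction factor being exactly 1.
#'
#' @param s_te1,s_te2 volumes on one grid.
#' @param te1,te2 echo times, ms (te2 > te1).
#' @return list with `t2star` (ms) and `valid`.
#' @export
compute_t2star_map <- function(s_te1, s_te2, te1 = 4.3, te2 = 11) {
  check_same_grid(s_te1, s_te2)
  stopifnot(te2 > te1)
  r <- s_te1 / s_te2
  t2s <- suppressWarnings((te2 - te1) / log(r))
  valid <- is.finite(r) & r >= 1 & s_te1 > 0 & !is.nan(t2s) & (t2s > 0 | is.infinite(t2s))
  t2s[!valid] <- NA_real_
  list(t2star = t2s, valid = valid)
}

#' Two-point variable-flip-angle T1 fit
#'
#' With `x_i = S_i/tan(a_i)` and `y_i = S_i/sin(a_i)` (effective angles
#' `a_i = b1 x nominal`), the spoiled gradient-echo equation is linear:
#' `y = E1 x + M0 (1 - E1)`. The two-point fit is solved in closed form;
#' `t1 = -tr/log(slope)` and `m0 = intercept/(1 - slope)`. Voxels whose
#' slope falls outside (0, 1), or with degenerate abscissae, are flagged
#' invalid, never a crash.
#'
#' @param s_pdw,s_t1w signal volumes at the low and high flip angle.
#' @param alpha1,alpha2 nominal angles, degrees.
#' @param b1 transmit-field volume (or scalar 1).
#' @param tr repetition time, ms.
#' @return list with `t1_app` (ms), `m0_app` (signal units; the equilibrium
#'   amplitude, still carrying T2* decay and the receive profile) and
#'   `valid`.
#' @export
fit_t1_vfa <- function(s_pdw, s_t1w, alpha1 = 4, alpha2 = 24, b1 = 1,
                       tr = 16.4) {
  check_same_grid(s_pdw, s_t1w)
  if (is.array(b1)) check_same_grid(s_pdw, b1)
  a1 <- b1 * alpha1 * pi / 180
  a2 <- b1 * alpha2 * pi / 180
  x1 <- s_pdw / tan(a1); y1 <- s_pdw / sin(a1)
  x2 <- s_t1w / tan(a2); y2 <- s_t1w / sin(a2)
  dx <- x2 - x1
  slope <- (y2 - y1) / dx
  ok <- is.finite(slope) & dx != 0 & slope > 0 & slope < 1
  t1 <- m0 <- array(NA_real_, dim(s_pdw))
  t1[ok] <- -tr / log(slope[ok])
  intercept <- y1 - slope * x1
  m0[ok] <- intercept[ok] / (1 - slope[ok])
  ok <- ok & is.finite(t1) & t1 > 0
  t1[!ok] <- NA_real_
  m0[!ok] <- NA_real_
  list(t1_app = t1, m0_app = m0, valid = ok)
}

#' Spoiling correction
#'
#' Hook for correcting apparent T1 for incomplete spoiling of transverse
#' magnetisation. The correction is a polynomial in apparent T1 and B1,
#' `t1 = sum c t1_app^i b1^j` over the given terms; the default single term
#' (i = 1, j = 0, c = 1) is the identity, appropriate for the ideally
#' spoiled simulator. Externally calibrated coefficients can be loaded from
#' YAML.
#'
#' @param terms data.frame with columns `i`, `j`, `c`.
#' @return object of class `spoiling_correction`.
#' @export
spoiling_correction <- function(terms = data.frame(i = 1, j = 0, c = 1)) {
  stopifnot(all(c("i", "j", "c") %in% names(terms)))
  structure(list(terms = terms), class = "spoiling_correction")
}

#' @rdname spoiling_correction
#' @param t1_app apparent T1 volume (ms).
#' @param b1 transmit-field volume or scalar.
#' @param corr a [spoiling_correction()].
#' @return corrected T1 volume.
#' @export
apply_spoiling_correction <- function(t1_app, b1 = 1,
                                      corr = spoiling_correction()) {
  out <- array(0, dim(t1_app))
  for (r in seq_len(nrow(corr$terms))) {
    out <- out + corr$terms$c[r] * t1_app^corr$terms$i[r] * b1^corr$terms$j[r]
  }
  attributes(out) <- attributes(t1_app)
  out
}

#' Write / read spoiling-correction coefficients
#' @param corr a [spoiling_correction()].
#' @param path YAML file.
#' @return the path / the correction object.
#' @export
write_spoiling_correction <- function(corr, path) {
  yaml::write_yaml(list(terms = as.list(corr$terms)), path)
  invisible(path)
}

#' @rdname write_spoiling_correction
#' @export
read_spoiling_correction <- function(path) {
  x <- yaml::read_yaml(path)
  spoiling_correction(as.data.frame(x$terms))
}

#' Estimate the receive-sensitivity field
#'
#' The T1-, T2*- and B1-corrected equilibrium amplitude divided by the
#' water content predicted from T1 is, up to tissue-level deviations from
#' the calibration, the receive profile times a constant. The ratio is
#' fitted with a low-order 3D polynomial. By default the fit is restricted
#' to a T1-homogeneous white-matter compartment (T1 inside `t1_window`),
#' which makes it robust to tissue-wise departures of true water content
#' from the calibration curve; the fitted polynomial is evaluated over the
#' whole grid and normalised to median 1 inside the brain mask (the global
#' scale is immaterial, since PD is later normalised in CSF).
#'
#' @param s_pdw_corrected equilibrium amplitude corrected for T1, T2* and
#'   B1 (i.e. `m0_app x exp(te/t2star)`).
#' @param t1 T1 volume, ms.
#' @param brain_mask logical volume.
#' @param cal a [fatouros_calibration()].
#' @param order polynomial order (default 3).
#' @param t1_window T1 range (ms) of voxels entering the fit; `NULL` fits
#'   over the whole brain mask.
#' @param min_voxels minimum number of fit voxels.
#' @return receive-field estimate over the whole grid (median 1 in-brain).
#' @export
estimate_receive_bias <- function(s_pdw_corrected, t1, brain_mask,
                                  cal = fatouros_calibration(), order = 3L,
                                  t1_window = c(600, 1100),
                                  min_voxels = 200L) {
  check_same_grid(s_pdw_corrected, t1, brain_mask)
  sel <- brain_mask & is.finite(t1) & t1 > 0 & is.finite(s_pdw_corrected) &
    s_pdw_corrected > 0
  if (!is.null(t1_window)) {
    sel_w <- sel & t1 >= t1_window[1] & t1 <= t1_window[2]
    if (sum(sel_w) >= min_voxels) sel <- sel_w
  }
  if (sum(sel) < min_voxels) {
    stop("too few valid voxels (", sum(sel), ") for the receive-bias fit")
  }
  dims <- dim(t1)
  ratio <- s_pdw_corrected[sel] / fatouros_water_content(t1[sel], cal)
  co <- grid_coords(dims)
  X <- poly3d_design(co[which(sel), , drop = FALSE], dims, order)
  beta <- lm.fit(X, ratio)$coefficients
  beta[is.na(beta)] <- 0
  field <- array(as.vector(poly3d_design(co, dims, order) %*% beta), dims)
  field <- field / median(field[brain_mask])
  field[field <= 0] <- min(field[field > 0])
  field
}

#' Derive the PD map
#'
#' The equilibrium amplitude is corrected for T2* decay at the effective
#' echo time and for the receive profile, then normalised so the median
#' value inside the CSF reference mask is 100 pu. An infinite T2* yields a
#' unit decay correction.
#'
#' @param m0_app equilibrium amplitude from [fit_t1_vfa()].
#' @param t2star T2* volume, ms.
#' @param receive_field receive-sensitivity volume (or scalar 1).
#' @param te echo time of the VFA acquisition, ms.
#' @param csf_mask logical volume, nonempty.
#' @return PD volume in pu.
#' @export
derive_pd_map <- function(m0_app, t2star, receive_field = 1, te = 6.7,
                          csf_mask) {
  check_same_grid(m0_app, t2star, csf_mask)
  if (!any(csf_mask)) stop("CSF reference mask is empty; cannot normalise")
  decay <- exp(te / t2star)
  decay[is.infinite(t2star)] <- 1
  pd_raw <- m0_app * decay / receive_field
  ref <- median(pd_raw[csf_mask], na.rm = TRUE)
  if (!is.finite(ref) || ref <= 0) stop("non-positive CSF reference signal")
  out <- 100 * pd_raw / ref
  attributes(out) <- attributes(m0_app)
  out
}

#' Full map estimation for one simulated (or externally loaded) subject
#'
#' Runs B1 mapping, T2* mapping, the VFA T1 fit with voxelwise B1
#' correction, the spoiling-correction hook, receive-bias estimation (or an
#' oracle field) and PD derivation with CSF normalisation.
#'
#' @param acq list of the six contrast volumes (pdw, t1w, b1ref, b1prep,
#'   te1, te2).
#' @param protocol an [acquisition_protocol()].
#' @param csf_mask CSF reference mask (e.g. ventricle truth labels).
#' @param brain_mask brain mask.
#' @param cal a [fatouros_calibration()].
#' @param spoiling a [spoiling_correction()].
#' @param oracle_bias optional list with known `b1_field` and/or
#'   `receive_field`; a supplied field bypasses its estimation.
#' @param b1_window plausibility window outside which B1 voxels are invalid.
#' @return object of class `qmap_set`: t1, pd, b1, t2star, m0_app volumes,
#'   `valid_mask`, `receive_field`, voxel size.
#' @export
map_qmri <- function(acq, protocol = acquisition_protocol(), csf_mask,
                     brain_mask, cal = fatouros_calibration(),
                     spoiling = spoiling_correction(), oracle_bias = NULL,
                     b1_window = c(0.5, 1.5)) {
  vs <- voxel_size(acq$pdw)
  if (!is.null(oracle_bias) && !is.null(oracle_bias$b1_field)) {
    b1 <- oracle_bias$b1_field
    b1_valid <- array(TRUE, dim(b1))
  } else {
    bm <- compute_b1_map(acq$b1ref, acq$b1prep, protocol$prep_angle)
    b1 <- bm$b1
    b1_valid <- bm$valid
  }
  b1_valid <- b1_valid & !is.na(b1) & b1 >= b1_window[1] & b1 <= b1_window[2]
  b1_use <- b1
  b1_use[!b1_valid] <- 1  # placeholder; flagged invalid downstream

  t2m <- compute_t2star_map(acq$te1, acq$te2, protocol$te1, protocol$te2)
  fit <- fit_t1_vfa(acq$pdw, acq$t1w, protocol$alpha1, protocol$alpha2,
                    b1 = b1_use, tr = protocol$tr)
  t1 <- apply_spoiling_correction(fit$t1_app, b1_use, spoiling)

  valid <- b1_valid & t2m$valid & fit$valid & brain_mask
  decay <- exp(protocol$te / t2m$t2star)
  decay[is.infinite(t2m$t2star)] <- 1
  s_corr <- fit$m0_app * decay

  if (!is.null(oracle_bias) && !is.null(oracle_bias$receive_field)) {
    receive <- oracle_bias$receive_field
  } else {
    receive <- estimate_receive_bias(s_corr, t1, brain_mask & valid, cal)
  }
  pd <- derive_pd_map(fit$m0_app, t2m$t2star, receive, protocol$te,
                      csf_mask & valid)
  valid <- valid & is.finite(pd) & pd > 0 & is.finite(t1) & t1 > 0
  structure(list(t1 = with_voxel_size(t1, vs),
                 pd = with_voxel_size(pd, vs),
                 b1 = b1, t2star = t2m$t2star,
                 m0_app = fit$m0_app,
                 receive_field = receive,
                 valid_mask = valid,
                 voxel_size = vs),
            class = "qmap_set")
}

#' Write the estimated maps of one subject
#' @param maps a `qmap_set`.
#' @param dir output directory.
#' @param subject_id file-name prefix.
#' @return invisibly, the paths.
#' @export
write_qmaps <- function(maps, dir, subject_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vols <- list(t1 = maps$t1, pd = maps$pd, b1 = maps$b1,
               t2star = maps$t2star)
  paths <- character()
  for (nm in names(vols)) {
    v <- vols[[nm]]
    v[!is.finite(v)] <- 0
    paths <- c(paths, write_volume(with_voxel_size(v, maps$voxel_size),
      file.path(dir, sprintf("%s_%s.nii.gz", subject_id, nm))))
  }
  paths <- c(paths, write_volume(
    with_voxel_size(maps$valid_mask, maps$voxel_size),
    file.path(dir, sprintf("%s_valid.nii.gz", subject_id)),
    datatype = "uint8"))
  invisible(paths)
}
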