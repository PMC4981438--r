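# Forward simulation of the three acquisitions: a variable-flip-angle
# spoiled gradient-echo pair (PD- and T1-weighted), a B1-mapping pair
# (reference plus magnetisation-prepared), and a dual-echo gradient-echo
# pair for T2*. All volumes are generated on the common truth grid;
# multiplicative transmit (B1) and receive-sensitivity fields and additive
# Gaussian noise model the main instrumental confounds.

#' Acquisition protocol
#'
#' Defaults are the emulated 3 T protocol: VFA TR/TE 16.4/6.7 ms at flip
#' angles 4 and 24 degrees; B1-mapping preparation angle 45 degrees;
#' dual-echo TE 4.3/11 ms. `noise_sd` is the SD of additive Gaussian noise
#' in the arbitrary signal units of the simulator (proton density scaled
#' 0-100); 0 gives a noiseless simulation.
#'
#' @param tr,te VFA repetition and echo time, ms.
#' @param alpha1,alpha2 VFA excitation angles, degrees (0 < a1 < a2 < 90).
#' @param prep_angle nominal B1 preparation angle, degrees.
#' @param te1,te2 dual-echo times, ms (te1 < te2).
#' @param noise_sd additive noise SD, signal units.
#' @return object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(tr = 16.4, te = 6.7, alpha1 = 4, alpha2 = 24,
                                 prep_angle = 45, te1 = 4.3, te2 = 11,
                                 noise_sd = 0.05) {
  stopifnot(tr > 0, te > 0, 0 < alpha1, alpha1 < alpha2, alpha2 < 90,
            0 < te1, te1 < te2, prep_angle > 0, prep_angle < 90,
            noise_sd >= 0)
  structure(list(tr = tr, te = te, alpha1 = alpha1, alpha2 = alpha2,
                 prep_angle = prep_angle, te1 = te1, te2 = te2,
                 noise_sd = noise_sd),
            class = "acquisition_protocol")
}

#' Smooth multiplicative bias fields
#'
#' Transmit (B1) and receive-sensitivity fields as low-order polynomials in
#' space, strictly positive by construction: 1 plus an `amplitude`-scaled
#' polynomial whose coefficients are drawn once from the seed. Amplitude 0
#' gives unit fields.
#'
#' @param dims grid shape.
#' @param b1_amplitude,receive_amplitude peak deviation from 1.
#' @param order polynomial order (default 2).
#' @param seed integer.
#' @return list with `b1_field` and `receive_field` (3D arrays).
#' @export
make_bias_fields <- function(dims, b1_amplitude = 0.1,
                             receive_amplitude = 0.2, order = 2L,
                             seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  co <- grid_coords(dims)
  X <- poly3d_design(co, dims, order)[, -1, drop = FALSE]  # drop intercept
  one_field <- function(amplitude) {
    if (amplitude == 0) return(array(1, dims))
    w <- rnorm(ncol(X))
    f <- as.vector(X %*% w)
    f <- f / max(abs(f)) * amplitude
    array(1 + f, dims)
  }
  list(b1_field = one_field(b1_amplitude),
       receive_field = one_field(receive_amplitude))
}

#' Ideally spoiled gradient-echo steady-state signal
#'
#' `S = pd sin(b1 a) (1 - E1) / (1 - cos(b1 a) E1) exp(-te/t2star)` with
#' `E1 = exp(-tr/t1)`; the effective excitation angle is the transmit field
#' times the nominal angle. Vectorised over voxels.
#'
#' @param pd proton density, pu.
#' @param t1 longitudinal relaxation time, ms (> 0).
#' @param t2star effective transverse relaxation time, ms (> 0).
#' @param alpha nominal excitation angle, degrees.
#' @param b1 transmit field (actual/nominal flip angle), dimensionless.
#' @param tr,te repetition and echo time, ms.
#' @return signal in arbitrary units.
#' @export
spgr_signal <- function(pd, t1, t2star, alpha, b1 = 1, tr = 16.4, te = 6.7) {
  if (any(t1 <= 0) || any(t2star <= 0)) {
    stop("t1 and t2star must be positive")
  }
  stopifnot(all(b1 > 0), tr > 0, te >= 0, alpha > 0)
  a <- b1 * alpha * pi / 180
  e1 <- exp(-tr / t1)
  pd * sin(a) * (1 - e1) / (1 - cos(a) * e1) * exp(-te / t2star)
}

# Signal over a truth volume: background (pd == 0) contributes no signal.
signal_volume <- function(truth, fun) {
  d <- dim(truth$labels)
  out <- array(0, d)
  inb <- truth$labels > 0
  out[inb] <- fun(truth$true_pd[inb], truth$true_t1[inb],
                  truth$true_t2star[inb])
  out
}

add_noise <- function(vol, noise_sd) {
  if (noise_sd > 0) vol + array(rnorm(length(vol), 0, noise_sd), dim(vol))
  else vol
}

#' Simulate the variable-flip-angle pair
#'
#' @param truth a `subject_truth`.
#' @param protocol an [acquisition_protocol()].
#' @param bias list with `b1_field` and `receive_field` on the truth grid.
#' @param seed integer, fixes the noise realisation.
#' @return list with `s_pdw` (low-angle) and `s_t1w` (high-angle) volumes.
#' @export
simulate_vfa_pair <- function(truth, protocol = acquisition_protocol(),
                              bias = NULL, seed = 1L) {
  if (is.null(bias)) bias <- make_bias_fields(dim(truth$labels), 0, 0)
  check_same_grid(truth$labels, bias$b1_field, bias$receive_field)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  vs <- voxel_size(truth$labels)
  inb <- truth$labels > 0
  one <- function(alpha) {
    s <- array(0, dim(truth$labels))
    s[inb] <- spgr_signal(truth$true_pd[inb], truth$true_t1[inb],
                          truth$true_t2star[inb], alpha,
                          b1 = bias$b1_field[inb],
                          tr = protocol$tr, te = protocol$te)
    s <- s * bias$receive_field
    with_voxel_size(add_noise(s, protocol$noise_sd), vs)
  }
  list(s_pdw = one(protocol$alpha1), s_t1w = one(protocol$alpha2))
}

#' Simulate the B1-mapping pair
#'
#' The reference volume is acquired after full relaxation and is
#' proportional to PD times the receive field; the prepared volume carries
#' an extra factor `cos(b1_field x nominal angle)`. Relaxation during the
#' sequence is not modelled, so no relaxation correction is needed on the
#' mapping side.
#'
#' @inheritParams simulate_vfa_pair
#' @param prep_angle nominal preparation angle, degrees.
#' @param noise_sd additive noise SD.
#' @return list with `s_ref` and `s_prep`.
#' @export
simulate_b1_pair <- function(truth, bias = NULL, prep_angle = 45,
                             noise_sd = 0.05, seed = 1L) {
  if (is.null(bias)) bias <- make_bias_fields(dim(truth$labels), 0, 0)
  check_same_grid(truth$labels, bias$b1_field, bias$receive_field)
  stopifnot(prep_angle >= 0, prep_angle < 90)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  vs <- voxel_size(truth$labels)
  s_ref <- truth$true_pd * bias$receive_field
  s_prep <- s_ref * cos(bias$b1_field * prep_angle * pi / 180)
  list(s_ref = with_voxel_size(add_noise(s_ref, noise_sd), vs),
       s_prep = with_voxel_size(add_noise(s_prep, noise_sd), vs))
}

#' Simulate the dual-echo gradient-echo pair
#'
#' Before noise, `s_te2 = s_te1 exp(-(te2 - te1)/t2star)` voxelwise.
#'
#' @inheritParams simulate_vfa_pair
#' @param te1,te2 echo times, ms.
#' @param noise_sd additive noise SD.
#' @return list with `s_te1` and `s_te2`.
#' @export
simulate_dual_echo <- function(truth, bias = NULL, te1 = 4.3, te2 = 11,
                               noise_sd = 0.05, seed = 1L) {
  if (is.null(bias)) bias <- make_bias_fields(dim(truth$labels), 0, 0)
  check_same_grid(truth$labels, bias$b1_field, bias$receive_field)
  stopifnot(te1 > 0, te2 >= te1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  vs <- voxel_size(truth$labels)
  inb <- truth$labels > 0
  base <- truth$true_pd * bias$receive_field
  s1 <- s2 <- array(0, dim(truth$labels))
  s1[inb] <- base[inb] * exp(-te1 / truth$true_t2star[inb])
  s2[inb] <- base[inb] * exp(-te2 / truth$true_t2star[inb])
  list(s_te1 = with_voxel_size(add_noise(s1, noise_sd), vs),
       s_te2 = with_voxel_size(add_noise(s2, noise_sd), vs))
}

#' Simulate all six contrasts for one subject
#'
#' @inheritParams simulate_vfa_pair
#' @return list with pdw, t1w, b1ref, b1prep, te1, te2 volumes.
#' @export
simulate_acquisitions <- function(truth, protocol = acquisition_protocol(),
                                  bias = NULL, seed = 1L) {
  if (is.null(bias)) bias <- make_bias_fields(dim(truth$labels), 0, 0)
  seeds <- derive_seeds(seed, 3L)
  vfa <- simulate_vfa_pair(truth, protocol, bias, seed = seeds[1])
  b1p <- simulate_b1_pair(truth, bias, protocol$prep_angle,
                          protocol$noise_sd, seed = seeds[2])
  de <- simulate_dual_echo(truth, bias, protocol$te1, protocol$te2,
                           protocol$noise_sd, seed = seeds[3])
  list(pdw = vfa$s_pdw, t1w = vfa$s_t1w,
       b1ref = b1p$s_ref, b1prep = b1p$s_prep,
       te1 = de$s_te1, te2 = de$s_te2)
}

#' Write simulated contrasts as NIfTI files
#' @param acq list from [simulate_acquisitions()].
#' @param dir output directory.
#' @param subject_id file-name prefix.
#' @return invisibly, the paths.
#' @export
write_acquisitions <- function(acq, dir, subject_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(acq), function(nm) {
    write_volume(acq[[nm]],
                 file.path(dir, sprintf("%s_%s.nii.gz", subject_id, nm)))
  }, "")
  invisible(paths)
}
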