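# Synthetic T1-weighted anatomy from the quantitative maps, and tissue
# segmentation on it. Because the anatomy is computed voxelwise from the
# maps, it shares their coordinate space exactly and no registration exists
# anywhere in the pipeline.

#' Synthetic MP-RAGE parameters
#'
#' Defaults: TR 1900 ms, TI 900 ms, excitation angle 9 degrees. The input
#' maps are already corrected for T2* decay, so the nominal TE of the
#' synthetic anatomy is zero. The excitation angle is protocol metadata;
#' the single-exponential inversion-recovery closed form used for synthesis
#' does not depend on it.
#'
#' @param tr,ti repetition and inversion time, ms (0 < ti < tr).
#' @param alpha excitation angle, degrees.
#' @return object of class `mprage_params`.
#' @export
mprage_params <- function(tr = 1900, ti = 900, alpha = 9) {
  stopifnot(ti > 0, ti < tr)
  structure(list(tr = tr, ti = ti, alpha = alpha, te = 0),
            class = "mprage_params")
}

#' Synthesize a T1-weighted MP-RAGE anatomy from T1 and PD maps
#'
#' Voxelwise inversion-recovery closed form
#' `S = pd (1 - 2 exp(-ti/t1) + exp(-tr/t1))`. The default output is the
#' magnitude `|S|`; `signed = TRUE` gives the phase-sensitive signal.
#' Voxels with non-positive or missing T1 are set to 0.
#'
#' @param t1,pd volumes on one grid.
#' @param params an [mprage_params()].
#' @param signed logical; keep the sign of the inversion-recovery signal.
#' @return anatomy volume (arbitrary units).
#' @export
synthesize_mprage <- function(t1, pd, params = mprage_params(),
                              signed = FALSE) {
  check_same_grid(t1, pd)
  s <- array(0, dim(t1))
  ok <- is.finite(t1) & t1 > 0 & is.finite(pd)
  s[ok] <- pd[ok] * (1 - 2 * exp(-params$ti / t1[ok]) +
                       exp(-params$tr / t1[ok]))
  if (!signed) s <- abs(s)
  attributes(s) <- attributes(t1)
  s
}

#' Brain mask from phantom truth or an external mask
#'
#' Internal mode: the union of all non-background truth labels. External
#' mode: a user-supplied mask volume, validated against the grid and passed
#' through unchanged.
#'
#' @param labels truth label volume (internal mode).
#' @param external external mask volume (external mode).
#' @param reference volume whose grid the external mask must match.
#' @return logical volume.
#' @export
brain_mask <- function(labels = NULL, external = NULL, reference = NULL) {
  if (!is.null(external)) {
    if (!is.null(reference)) check_same_grid(external, reference)
    m <- external > 0
    if (!any(m)) stop("external brain mask is empty")
    attr(m, "voxel_size") <- attr(external, "voxel_size")
    return(m)
  }
  if (is.null(labels)) stop("supply truth labels or an external mask")
  m <- labels > 0
  if (!any(m)) stop("brain mask is empty")
  attr(m, "voxel_size") <- attr(labels, "voxel_size")
  m
}

# 1D Gaussian-mixture EM with k-means initialisation and a variance floor
# (keeps the fit well-posed on piecewise-constant synthetic intensities).
gmm_em_1d <- function(x, k = 3L, seed = 1L, max_iter = 300L, tol = 1e-8,
                      var_floor_frac = 1e-3) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  # k-means started from intensity quantiles, with the first and last start
  # in the distribution tails so that rare extreme classes (CSF is < 1% of
  # a brain volume) seed their own component.
  probs <- (seq_len(k) - 0.5) / k
  probs[1] <- 0.005
  probs[k] <- 0.995
  ctr <- quantile(x, probs, names = FALSE)
  if (any(duplicated(ctr))) {
    ctr <- ctr + rnorm(k, 0, 1e-6 * (diff(range(x)) + 1))
  }
  km <- kmeans(x, centers = matrix(ctr, ncol = 1), iter.max = 50)
  mu <- as.vector(km$centers)
  floor_sd <- var_floor_frac * diff(range(x))
  if (floor_sd == 0) floor_sd <- 1e-8
  sdv <- pmax(sqrt(km$withinss / pmax(km$size, 1)), floor_sd)
  w <- km$size / length(x)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * dnorm(x, mu[j], sdv[j]),
                   numeric(length(x)))
    tot <- rowSums(dens) + .Machine$double.xmin
    z <- dens / tot
    ll <- sum(log(tot))
    nk <- colSums(z)
    w <- nk / length(x)
    mu <- colSums(z * x) / nk
    sdv <- pmax(sqrt(colSums(z * (x - rep(mu, each = length(x)))^2) / nk),
                floor_sd)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged) {
    stop("EM did not converge within ", max_iter, " iterations ",
         "(final means ", paste(signif(mu, 4), collapse = ", "), ")")
  }
  list(mu = mu, sd = sdv, w = w, z = z, loglik = ll, iterations = it)
}

#' Segment an anatomy into CSF/GM/WM partial volume estimates
#'
#' Three-component Gaussian-mixture fit on the in-mask intensities (EM with
#' k-means initialisation, fixed seed); partial volume estimates are the
#' posterior responsibilities. On a magnitude MP-RAGE the components map to
#' tissues by ascending mean intensity: CSF darkest, WM brightest.
#' Externally produced PVE maps may be supplied instead; they are validated
#' (range, grid, voxelwise sum) and passed through.
#'
#' @param anatomy volume from [synthesize_mprage()] (or a real scan).
#' @param mask logical brain mask.
#' @param k number of classes (3).
#' @param seed integer.
#' @param external optional list with `gm`, `wm`, `csf` volumes.
#' @return object of class `pve_maps`: gm, wm, csf volumes in `[0, 1]`,
#'   `source` (`"internal"` or `"external"`).
#' @export
segment_pve <- function(anatomy, mask, k = 3L, seed = 1L, external = NULL) {
  if (!is.null(external)) {
    for (nm in c("gm", "wm", "csf")) {
      check_same_grid(anatomy, external[[nm]])
      rng <- range(external[[nm]], na.rm = TRUE)
      if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6) {
        stop("external PVE map out of [0, 1]: ", nm)
      }
    }
    s <- external$gm + external$wm + external$csf
    if (any(s[mask] > 1 + 1e-3)) {
      stop("external PVE maps sum to more than 1 inside the brain mask")
    }
    return(structure(list(gm = external$gm, wm = external$wm,
                          csf = external$csf, source = "external"),
                     class = "pve_maps"))
  }
  check_same_grid(anatomy, mask)
  x <- anatomy[mask]
  fit <- gmm_em_1d(x, k = k, seed = seed)
  ord <- order(fit$mu)  # ascending: CSF, GM, WM
  zero <- array(0, dim(anatomy))
  out <- list(csf = zero, gm = zero, wm = zero)
  cls <- c("csf", "gm", "wm")
  for (i in 1:3) {
    v <- array(0, dim(anatomy))
    v[mask] <- fit$z[, ord[i]]
    attr(v, "voxel_size") <- attr(anatomy, "voxel_size")
    out[[cls[i]]] <- v
  }
  structure(c(out, list(source = "internal", fit = fit[c("mu", "sd", "w",
                                                         "iterations")])),
            class = "pve_maps")
}

# Default mapping from a common subcortical labelling convention
# (FIRST-style codes, left/right) to the four deep-gray structures.
DEFAULT_SUBCORTICAL_CODES <- list(
  thalamus = c(10L, 49L),
  caudate = c(11L, 50L),
  putamen = c(12L, 51L),
  pallidum = c(13L, 52L)
)

#' Deep gray-matter structure masks
#'
#' Internal mode reads the phantom truth labels (both hemispheres of a
#' structure already share one code, so they are combined into one ROI per
#' structure). External mode maps a supplied label volume through a
#' code-mapping table (default: a common subcortical labelling convention
#' with left/right codes per structure).
#'
#' @param labels truth label volume, or an external label volume when
#'   `codes` is given.
#' @param codes named list mapping structure name to the integer codes of
#'   an external labelling; `NULL` uses the phantom's own codes.
#' @return named list of four logical volumes (thalamus, caudate, putamen,
#'   pallidum).
#' @export
deep_gm_labels <- function(labels, codes = NULL) {
  structures <- c("thalamus", "caudate", "putamen", "pallidum")
  if (is.null(codes)) {
    codes <- as.list(TISSUE_CODES[structures])
  }
  out <- list()
  for (nm in structures) {
    m <- array(labels, dim(labels)) %in% codes[[nm]]
    m <- array(m, dim(labels))
    if (!any(m)) stop("missing deep gray-matter structure: ", nm)
    attr(m, "voxel_size") <- attr(labels, "voxel_size")
    out[[nm]] <- m
  }
  out
}
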