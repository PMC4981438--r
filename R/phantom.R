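# Digital brain phantom: concentric analytic shapes on a regular grid.
# The anatomy is deliberately schematic (ellipsoids and shells); the claims
# exercised downstream are parameter-level, not shape-level.

#' Tissue label codes used by the phantom
#'
#' Background is 0. Both hemispheres of a deep-gray structure carry the same
#' code, so they are combined into one ROI per structure downstream.
#' @export
TISSUE_CODES <- c(csf = 1L, cortex = 2L, wm = 3L, thalamus = 4L,
                  caudate = 5L, putamen = 6L, pallidum = 7L, lesion = 8L)

#' Phantom geometry specification
#'
#' All placement parameters are in voxel units on the simulation grid;
#' `voxel_size` (mm) scales the grid physically. The default is a desk-scale
#' 64^3 grid at 2 mm isotropic; `protocol_geometry()` gives the acquisition
#' grid of the emulated protocol (1 mm, 256 x 224 x 160).
#'
#' @param grid_shape integer length 3.
#' @param voxel_size mm, isotropic scalar or length 3.
#' @param brain,cortex_inner semi-axes (voxels) of the brain envelope and of
#'   the inner surface of the cortical ribbon.
#' @param ventricle,thalamus,caudate,putamen,pallidum lists with `offset`
#'   (voxel offset of the right-hemisphere centre from the grid centre; the
#'   left one is mirrored in x) and `semi` (semi-axes, voxels).
#' @param n_lesions number of spherical white-matter lesions.
#' @param lesion_radius range (voxels) lesion radii are drawn from.
#' @return object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(grid_shape = c(64L, 64L, 64L),
                             voxel_size = 2,
                             brain = c(26, 24, 22),
                             cortex_inner = c(21, 19, 17),
                             ventricle = list(offset = c(5, 1.5, 0.5), semi = c(2.5, 5.5, 3)),
                             thalamus = list(offset = c(9, -7.5, -2), semi = c(3.5, 4.5, 4)),
                             caudate = list(offset = c(5.5, 10, 4.5), semi = c(2.5, 4, 2.5)),
                             putamen = list(offset = c(16, 3.5, -1), semi = c(3, 5.5, 4)),
                             pallidum = list(offset = c(10.5, 4, -2.5), semi = c(2.5, 3.5, 3)),
                             n_lesions = 3L,
                             lesion_radius = c(1.2, 2.2)) {
  stopifnot(all(grid_shape > 0), all(voxel_size > 0),
            all(brain > 0), all(cortex_inner > 0),
            all(cortex_inner < brain), n_lesions >= 0)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = rep(as.numeric(voxel_size), length.out = 3),
                 brain = brain, cortex_inner = cortex_inner,
                 ventricle = ventricle, thalamus = thalamus,
                 caudate = caudate, putamen = putamen, pallidum = pallidum,
                 n_lesions = as.integer(n_lesions),
                 lesion_radius = lesion_radius),
            class = "phantom_geometry")
}

#' Geometry matching the emulated acquisition grid (1 mm, 256 x 224 x 160)
#'
#' Structure placements are scaled from the desk-scale default.
#' @export
protocol_geometry <- function() {
  g <- phantom_geometry()
  s <- 2  # 2 mm voxels -> 1 mm voxels: double all voxel extents
  scale_part <- function(p) list(offset = p$offset * s, semi = p$semi * s)
  phantom_geometry(grid_shape = c(256L, 224L, 160L), voxel_size = 1,
                   brain = g$brain * s, cortex_inner = g$cortex_inner * s,
                   ventricle = scale_part(g$ventricle),
                   thalamus = scale_part(g$thalamus),
                   caudate = scale_part(g$caudate),
                   putamen = scale_part(g$putamen),
                   pallidum = scale_part(g$pallidum),
                   n_lesions = g$n_lesions,
                   lesion_radius = g$lesion_radius * s)
}

# Logical volume of an ellipsoid given centre and semi-axes (voxel units).
ellipsoid_mask <- function(dims, centre, semi) {
  x <- (seq_len(dims[1]) - centre[1]) / semi[1]
  y <- (seq_len(dims[2]) - centre[2]) / semi[2]
  z <- (seq_len(dims[3]) - centre[3]) / semi[3]
  r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  r2 <= 1
}

# Mirrored pair of ellipsoids for a bilateral structure.
paired_mask <- function(dims, centre0, part) {
  m <- ellipsoid_mask(dims, centre0 + part$offset, part$semi) |
    ellipsoid_mask(dims, centre0 + part$offset * c(-1, 1, 1), part$semi)
  m
}

#' Build the phantom label volume
#'
#' Produces an integer volume with the codes of [TISSUE_CODES]: a cortical
#' ribbon between the brain envelope and an inner surface, a white-matter
#' core, bilateral ventricles (CSF) and four bilateral deep-gray structures,
#' plus optional spherical white-matter lesions placed at random strictly
#' inside white matter. Deep-gray structures must be disjoint from each
#' other, from the ventricles and from the cortical ribbon; violations are
#' configuration errors naming the offending structure.
#'
#' @param geometry a [phantom_geometry()].
#' @param seed integer; fixes lesion placement.
#' @return integer label volume with `voxel_size` attribute.
#' @export
build_phantom_geometry <- function(geometry = phantom_geometry(), seed = 1L) {
  d <- geometry$grid_shape
  c0 <- (d + 1) / 2
  brain <- ellipsoid_mask(d, c0, geometry$brain)
  inner <- ellipsoid_mask(d, c0, geometry$cortex_inner)
  structs <- list(
    csf = paired_mask(d, c0, geometry$ventricle),
    thalamus = paired_mask(d, c0, geometry$thalamus),
    caudate = paired_mask(d, c0, geometry$caudate),
    putamen = paired_mask(d, c0, geometry$putamen),
    pallidum = paired_mask(d, c0, geometry$pallidum)
  )
  for (nm in names(structs)) {
    if (!any(structs[[nm]])) {
      stop("structure does not fit in the grid: ", nm)
    }
    if (any(structs[[nm]] & !inner)) {
      stop("structure extends outside the white-matter core: ", nm)
    }
  }
  nms <- names(structs)
  for (i in seq_along(structs)) for (j in seq_along(structs)) {
    if (i < j && any(structs[[i]] & structs[[j]])) {
      stop("structures overlap: ", nms[i], " and ", nms[j])
    }
  }
  labels <- array(0L, d)
  labels[inner] <- TISSUE_CODES[["wm"]]
  labels[brain & !inner] <- TISSUE_CODES[["cortex"]]
  for (nm in nms) {
    labels[structs[[nm]]] <- TISSUE_CODES[[nm]]
  }

  if (geometry$n_lesions > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    wm <- labels == TISSUE_CODES[["wm"]]
    placed <- 0L
    attempts <- 0L
    lesion <- array(FALSE, d)
    while (placed < geometry$n_lesions && attempts < 2000L) {
      attempts <- attempts + 1L
      r <- runif(1, geometry$lesion_radius[1], geometry$lesion_radius[2])
      idx <- which(wm)
      ctr <- arrayInd(idx[sample.int(length(idx), 1L)], d)
      cand <- ellipsoid_mask(d, as.numeric(ctr), rep(r, 3))
      if (all(wm[cand]) && !any(lesion & cand)) {
        lesion <- lesion | cand
        placed <- placed + 1L
      }
    }
    if (placed < geometry$n_lesions) {
      stop("could not place all lesions inside white matter")
    }
    labels[lesion] <- TISSUE_CODES[["lesion"]]
  }
  with_voxel_size(labels, geometry$voxel_size)
}
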