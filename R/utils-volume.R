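#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rbinom runif kmeans dnorm median quantile
#'   wilcox.test cor.test lm.fit sd
#' @importFrom utils write.table read.delim
NULL

# Voxel volumes are plain 3D arrays; voxel size (mm, per axis) travels
# alongside them as an attribute so that mm-specified kernels can be
# converted to voxel units.

#' Attach a voxel size to a volume
#'
#' @param x 3D array.
#' @param voxel_size numeric length 1 or 3, voxel edge length in mm.
#' @return `x` with a `voxel_size` attribute (always length 3).
#' @export
with_voxel_size <- function(x, voxel_size) {
  stopifnot(length(dim(x)) == 3L, all(voxel_size > 0))
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  attr(x, "voxel_size") <- as.numeric(voxel_size)
  x
}

#' Voxel size of a volume
#' @param x 3D array carrying a `voxel_size` attribute.
#' @param default value returned when the attribute is absent.
#' @return numeric length 3 (mm).
#' @export
voxel_size <- function(x, default = NULL) {
  vs <- attr(x, "voxel_size")
  if (is.null(vs)) {
    if (is.null(default)) stop("volume carries no voxel_size attribute")
    vs <- default
  }
  if (length(vs) == 1L) vs <- rep(vs, 3L)
  as.numeric(vs)
}

check_same_grid <- function(...) {
  vols <- list(...)
  dims <- lapply(vols, dim)
  ref <- dims[[1L]]
  ok <- vapply(dims, function(d) identical(as.integer(d), as.integer(ref)),
               logical(1))
  if (!all(ok)) stop("volumes do not share one grid: ",
                     paste(vapply(dims, paste, "", collapse = "x"),
                           collapse = " vs "))
  invisible(ref)
}

# Integer shift of a 3D array; voxels shifted in from outside take `fill`.
shift_volume <- function(a, s, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  if (any(abs(s) >= d)) return(out)
  idx_dst <- idx_src <- vector("list", 3L)
  for (i in 1:3) {
    if (s[i] >= 0) {
      idx_dst[[i]] <- (1L + s[i]):d[i]
      idx_src[[i]] <- 1L:(d[i] - s[i])
    } else {
      idx_dst[[i]] <- 1L:(d[i] + s[i])
      idx_src[[i]] <- (1L - s[i]):d[i]
    }
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Kernel edge in voxels from a mm edge: nearest integer, forced odd
# (decremented when even), never below 1. Computed per axis.
kernel_voxels <- function(kernel_mm, voxel_size) {
  k <- round(kernel_mm / voxel_size)
  k <- ifelse(k %% 2 == 0, pmax(k - 1, 1), pmax(k, 1))
  as.integer(k)
}

#' Binary erosion with a cubic structuring element specified in mm
#'
#' The kernel edge is converted to voxels per axis (nearest integer, forced
#' odd, minimum 1), so a 6 mm kernel on a 2 mm grid is a 3x3x3-voxel cube
#' and a 3 mm kernel on a 1 mm grid is a 3x3x3 mm cube. Anisotropic voxels
#' get per-axis kernel extents.
#'
#' @param mask logical 3D array.
#' @param kernel_mm cube edge length in mm.
#' @param voxel_size voxel edge length in mm (length 1 or 3); defaults to
#'   the mask's `voxel_size` attribute.
#' @return eroded logical array (voxel size preserved).
#' @export
erode_mask <- function(mask, kernel_mm, voxel_size = NULL) {
  if (is.null(voxel_size)) voxel_size <- voxel_size(mask)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(kernel_mm > 0, all(voxel_size > 0))
  k <- kernel_voxels(kernel_mm, voxel_size)
  h <- (k - 1L) %/% 2L
  m <- mask & TRUE  # coerce to logical
  out <- m
  for (dx in -h[1]:h[1]) for (dy in -h[2]:h[2]) for (dz in -h[3]:h[3]) {
    if (dx == 0L && dy == 0L && dz == 0L) next
    out <- out & shift_volume(m, c(-dx, -dy, -dz), fill = FALSE)
  }
  if (!is.null(attr(mask, "voxel_size"))) {
    attr(out, "voxel_size") <- attr(mask, "voxel_size")
  }
  out
}

#' Fill internal cavities of a binary mask
#'
#' A hole is any background component not connected (6-connectivity) to the
#' volume border. Used to build the "filled" white-matter exclusion mask,
#' which swallows enclosed lesions, ventricles and deep-gray structures.
#'
#' @param mask logical 3D array.
#' @return logical array with holes filled.
#' @export
fill_holes <- function(mask) {
  m <- mask & TRUE
  comp <- !m
  d <- dim(m)
  outside <- array(FALSE, d)
  outside[c(1L, d[1]), , ] <- TRUE
  outside[, c(1L, d[2]), ] <- TRUE
  outside[, , c(1L, d[3])] <- TRUE
  outside <- outside & comp
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  repeat {
    grown <- outside
    for (i in seq_len(nrow(offs))) {
      grown <- grown | shift_volume(outside, offs[i, ], fill = FALSE)
    }
    grown <- grown & comp
    if (identical(grown, outside)) break
    outside <- grown
  }
  out <- m | (comp & !outside)
  if (!is.null(attr(mask, "voxel_size"))) {
    attr(out, "voxel_size") <- attr(mask, "voxel_size")
  }
  out
}

# Design matrix of 3D polynomial terms up to total degree `order`,
# on coordinates normalised to [-1, 1] per axis.
poly3d_design <- function(coords, dims, order) {
  stopifnot(order >= 0)
  u <- sweep(coords, 2L, (dims + 1) / 2, "-")
  u <- sweep(u, 2L, pmax((dims - 1) / 2, 1), "/")
  cols <- list()
  nm <- character()
  for (i in 0:order) for (j in 0:(order - i)) for (k in 0:(order - i - j)) {
    cols[[length(cols) + 1L]] <- u[, 1]^i * u[, 2]^j * u[, 3]^k
    nm <- c(nm, sprintf("x%dy%dz%d", i, j, k))
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nm
  m
}

# All voxel coordinates of a grid as an n x 3 matrix (column-major order).
grid_coords <- function(dims) {
  cbind(
    rep.int(seq_len(dims[1]), times = dims[2] * dims[3]),
    rep.int(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]),
    rep(seq_len(dims[3]), each = dims[1] * dims[2])
  )
}

# Deterministic per-item seed streams derived from one master seed,
# kept below 2^31 so they stay valid R integers.
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master_seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Read a NIfTI volume as a plain array with voxel size attached
#' @param path file path (.nii or .nii.gz).
#' @return 3D array with a `voxel_size` attribute.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  with_voxel_size(array(as.numeric(img), dim(img)[1:3]), vs)
}

#' Write a volume to NIfTI-1
#' @param x 3D array (logical, integer or numeric) with a `voxel_size`
#'   attribute (or supply `voxel_size`).
#' @param path output path; `.nii.gz` gives a compressed file.
#' @param voxel_size optional override, mm.
#' @param datatype NIfTI datatype; labels/masks are written as unsigned
#'   integers, parameter maps as 32-bit float.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, voxel_size = NULL,
                         datatype = c("float", "uint8", "int16")) {
  datatype <- match.arg(datatype)
  vs <- if (is.null(voxel_size)) voxel_size(x) else rep(voxel_size, length.out = 3)
  a <- array(if (datatype == "float") as.numeric(x) else as.integer(x),
             dim(x))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- vs
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
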