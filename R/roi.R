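# ROI construction: a partial-volume-weighted cortex map, eroded deep-gray
# and white-matter masks, parameter-specific whole-brain masks and a global
# gray-matter map, with lesion exclusion everywhere.

#' Build the cortex partial-volume weight map
#'
#' Weights are the gray-matter PVE values where the PVE is at least
#' `pve_threshold` (default 0.95), zeroed wherever an exclusion mask, the
#' lesion mask, or a T1 value outside `t1_window` (default 1200-1600 ms)
#' applies. The exclusion mask is the union of deep gray matter, the
#' hole-filled white-matter mask, the ventricles and (optionally) a
#' cerebellum mask.
#'
#' @param gm_pve gray-matter PVE volume.
#' @param t1 T1 volume, ms.
#' @param exclusion_mask logical volume (union of non-cortical structures).
#' @param lesion_mask logical volume.
#' @param pve_threshold minimum PVE retained.
#' @param t1_window permitted absolute T1 range, ms.
#' @return weight volume in `[0, 1]`; attribute `empty` flags an all-zero
#'   result (a warning, not an error).
#' @export
build_cortex_pve <- function(gm_pve, t1, exclusion_mask, lesion_mask,
                             pve_threshold = 0.95,
                             t1_window = c(1200, 1600)) {
  check_same_grid(gm_pve, t1, exclusion_mask, lesion_mask)
  keep <- gm_pve >= pve_threshold & !exclusion_mask & !lesion_mask &
    is.finite(t1) & t1 >= t1_window[1] & t1 <= t1_window[2]
  w <- array(0, dim(gm_pve))
  w[keep] <- gm_pve[keep]
  attributes(w) <- attributes(gm_pve)
  if (!any(w > 0)) {
    warning("cortex PVE map is empty after exclusions")
    attr(w, "empty") <- TRUE
  }
  w
}

#' Build the four deep gray-matter ROIs
#'
#' Each structure mask (hemispheres already combined) is eroded with a
#' cubic kernel (default 3 mm edge) to avoid partial voluming with CSF,
#' then lesion voxels are removed.
#'
#' @param structure_masks named list from [deep_gm_labels()].
#' @param lesion_mask logical volume.
#' @param voxel_size mm; defaults to the masks' attribute.
#' @param kernel_mm erosion kernel edge, mm.
#' @return named list of logical ROI masks; empty ROIs carry an `empty`
#'   attribute.
#' @export
build_deep_gm_rois <- function(structure_masks, lesion_mask,
                               voxel_size = NULL, kernel_mm = 3) {
  out <- list()
  for (nm in names(structure_masks)) {
    m <- erode_mask(structure_masks[[nm]], kernel_mm, voxel_size)
    m <- m & !lesion_mask
    if (!any(m)) {
      warning("deep gray-matter ROI is empty after erosion: ", nm)
      attr(m, "empty") <- TRUE
    }
    out[[nm]] <- m
  }
  out
}

#' Build the normal-appearing white-matter ROI
#'
#' The white-matter mask is the PVE binarised at `pve_threshold`, eroded
#' with a cubic kernel (default 6 mm edge) to reduce partial volume
#' effects; lesion voxels (and any additional exclusion, e.g. deep gray
#' matter misassigned to the white-matter intensity class) are then
#' removed.
#'
#' @param wm_pve white-matter PVE volume.
#' @param lesion_mask logical volume.
#' @param voxel_size mm.
#' @param kernel_mm erosion kernel edge, mm.
#' @param pve_threshold binarisation threshold.
#' @param exclude_mask optional extra exclusion.
#' @return logical ROI mask.
#' @export
build_nawm_roi <- function(wm_pve, lesion_mask, voxel_size = NULL,
                           kernel_mm = 6, pve_threshold = 0.95,
                           exclude_mask = NULL) {
  check_same_grid(wm_pve, lesion_mask)
  if (is.null(voxel_size)) voxel_size <- voxel_size(wm_pve)
  m <- wm_pve >= pve_threshold
  m <- with_voxel_size(m, voxel_size)
  m <- erode_mask(m, kernel_mm, voxel_size)
  m <- m & !lesion_mask
  if (!is.null(exclude_mask)) m <- m & !exclude_mask
  with_voxel_size(m, voxel_size)
}

#' Parameter-specific whole-brain masks
#'
#' CSF is excluded by thresholds: voxels with T1 above `t1_cutoff` are
#' removed for the T1 analysis, and voxels with PD above the water content
#' corresponding to that cutoff (84.44 pu under the default calibration)
#' for the PD analysis. A conjunctive mode applies both thresholds to one
#' shared mask.
#'
#' @param t1,pd parameter volumes.
#' @param brain_mask logical volume.
#' @param cal a [fatouros_calibration()].
#' @param t1_cutoff ms.
#' @param joint logical; `TRUE` returns the conjunction for both analyses.
#' @return list with logical masks `t1` and `pd`.
#' @export
build_whole_brain_mask <- function(t1, pd, brain_mask,
                                   cal = fatouros_calibration(),
                                   t1_cutoff = 1600, joint = FALSE) {
  check_same_grid(t1, pd, brain_mask)
  pd_cutoff <- csf_pd_threshold(t1_cutoff, cal)
  m_t1 <- brain_mask & is.finite(t1) & t1 <= t1_cutoff
  m_pd <- brain_mask & is.finite(pd) & pd <= pd_cutoff
  if (joint) {
    m <- m_t1 & m_pd
    return(list(t1 = m, pd = m))
  }
  list(t1 = m_t1, pd = m_pd)
}

#' Global gray-matter weight map
#'
#' Voxelwise maximum of the cortex weights and binary deep-gray membership.
#' Cortex and deep-gray ROIs are disjoint by construction; this is
#' asserted.
#'
#' @param cortex_weights volume in `[0, 1]`.
#' @param deep_gm_rois named list of logical masks.
#' @return weight volume.
#' @export
build_global_gm <- function(cortex_weights, deep_gm_rois) {
  deep <- Reduce(`|`, deep_gm_rois)
  check_same_grid(cortex_weights, deep)
  if (any(cortex_weights > 0 & deep)) {
    stop("cortex weights overlap deep gray-matter ROIs")
  }
  w <- pmax(cortex_weights, deep * 1)
  attributes(w) <- attributes(cortex_weights)
  w
}

#' Weighted ROI mean of a parameter map
#'
#' `sum(w v) / sum(w)` over voxels that are inside the validity mask.
#'
#' @param param_map parameter volume.
#' @param weight_map weight volume (binary masks allowed).
#' @param valid_mask logical volume of usable voxels.
#' @param roi,parameter,subject_id labels carried into the result.
#' @return one-row data.frame: subject_id, roi, parameter, mean,
#'   weight_sum, n_voxels, empty.
#' @export
weighted_roi_mean <- function(param_map, weight_map, valid_mask = NULL,
                              roi = NA_character_,
                              parameter = NA_character_,
                              subject_id = NA_character_) {
  check_same_grid(param_map, weight_map)
  w <- as.numeric(weight_map)
  if (!is.null(valid_mask)) w <- w * as.numeric(valid_mask)
  w[!is.finite(param_map)] <- 0
  ws <- sum(w)
  empty <- ws <= 0
  m <- if (empty) NA_real_ else sum(w * as.numeric(param_map), na.rm = TRUE) / ws
  data.frame(subject_id = subject_id, roi = roi, parameter = parameter,
             mean = m, weight_sum = ws, n_voxels = sum(w > 0),
             empty = empty)
}

#' Build all ROIs and extract weighted means for one subject
#'
#' Constructs the cortex weight map, the four eroded deep-gray ROIs, the
#' eroded normal-appearing white-matter ROI, the parameter-specific
#' whole-brain masks and the global gray-matter map, then measures weighted
#' mean T1 and PD for each. The global gray-matter ROI is reported as
#' `nagm`.
#'
#' @param maps a `qmap_set` from [map_qmri()].
#' @param pve a `pve_maps` from [segment_pve()].
#' @param deep_masks named list from [deep_gm_labels()].
#' @param lesion_mask logical volume.
#' @param brain logical brain mask.
#' @param subject_id identifier.
#' @param cal a [fatouros_calibration()].
#' @param cerebellum_mask optional extra cortical exclusion.
#' @param pve_threshold cortex/WM PVE threshold.
#' @param t1_window cortical T1 window, ms.
#' @param t1_cutoff whole-brain T1 cutoff, ms.
#' @param deep_kernel_mm,wm_kernel_mm erosion kernel edges, mm.
#' @param joint_whole_brain see [build_whole_brain_mask()].
#' @return list with `rois` (the weight/mask volumes) and `measurements`
#'   (long-format data.frame).
#' @export
extract_rois <- function(maps, pve, deep_masks, lesion_mask, brain,
                         subject_id, cal = fatouros_calibration(),
                         cerebellum_mask = NULL, pve_threshold = 0.95,
                         t1_window = c(1200, 1600), t1_cutoff = 1600,
                         deep_kernel_mm = 3, wm_kernel_mm = 6,
                         joint_whole_brain = FALSE) {
  vs <- maps$voxel_size
  deep_union <- Reduce(`|`, deep_masks)
  ventricles <- pve$csf >= pve_threshold & brain
  wm_bin <- with_voxel_size(pve$wm >= pve_threshold, vs)
  wm_filled <- fill_holes(wm_bin)
  exclusion <- deep_union | wm_filled | ventricles
  if (!is.null(cerebellum_mask)) exclusion <- exclusion | cerebellum_mask

  cortex <- build_cortex_pve(pve$gm, maps$t1, exclusion, lesion_mask,
                             pve_threshold, t1_window)
  deep_rois <- build_deep_gm_rois(deep_masks, lesion_mask, vs,
                                  deep_kernel_mm)
  nawm <- build_nawm_roi(with_voxel_size(pve$wm, vs), lesion_mask, vs,
                         wm_kernel_mm, pve_threshold,
                         exclude_mask = deep_union)
  wb <- build_whole_brain_mask(maps$t1, maps$pd, brain, cal, t1_cutoff,
                               joint_whole_brain)
  global_gm <- build_global_gm(cortex, deep_rois)

  weight_sets <- c(list(nagm = global_gm, cortex = cortex),
                   deep_rois, list(nawm = nawm))
  rows <- list()
  for (nm in names(weight_sets)) {
    rows[[length(rows) + 1L]] <-
      weighted_roi_mean(maps$t1, weight_sets[[nm]], maps$valid_mask,
                        roi = nm, parameter = "t1",
                        subject_id = subject_id)
    rows[[length(rows) + 1L]] <-
      weighted_roi_mean(maps$pd, weight_sets[[nm]], maps$valid_mask,
                        roi = nm, parameter = "pd",
                        subject_id = subject_id)
  }
  rows[[length(rows) + 1L]] <-
    weighted_roi_mean(maps$t1, wb$t1, maps$valid_mask,
                      roi = "whole_brain", parameter = "t1",
                      subject_id = subject_id)
  rows[[length(rows) + 1L]] <-
    weighted_roi_mean(maps$pd, wb$pd, maps$valid_mask,
                      roi = "whole_brain", parameter = "pd",
                      subject_id = subject_id)
  measurements <- do.call(rbind, rows)

  rois <- c(list(cortex = cortex, nawm = nawm, nagm = global_gm,
                 whole_brain_t1 = wb$t1, whole_brain_pd = wb$pd),
            deep_rois)
  list(rois = rois, measurements = measurements)
}

#' Write per-subject ROI volumes and measurements
#' @param extraction result of [extract_rois()].
#' @param dir output directory.
#' @param subject_id file-name prefix.
#' @param voxel_size mm.
#' @return invisibly, the paths.
#' @export
write_rois <- function(extraction, dir, subject_id, voxel_size) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(extraction$rois)) {
    v <- extraction$rois[[nm]]
    paths <- c(paths, write_volume(
      with_voxel_size(v * 1, voxel_size),
      file.path(dir, sprintf("%s_roi_%s.nii.gz", subject_id, nm))))
  }
  tsv <- file.path(dir, sprintf("%s_measurements.tsv", subject_id))
  write.table(extraction$measurements, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paths, tsv))
}
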