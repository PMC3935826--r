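#' Configuration for relative T1-hypointensity thresholding
#'
#' @param fraction threshold as a fraction of the surrounding
#'   normal-appearing white matter (NAWM) mean T1 intensity; the calibrated
#'   defaults are 0.85 for the pediatric protocol and 0.83 for the adult
#'   protocol.
#' @param nawm_ring_mm width of the WM ring around each lesion used as the
#'   NAWM reference (default 5 mm).
#' @param require_t2_bright restrict T1 lesions to voxels inside the final T2
#'   lesion mask (the "confirmed bright on T2" rule; default TRUE).
#' @export
t1_threshold_config <- function(fraction = 0.85, nawm_ring_mm = 5,
                                require_t2_bright = TRUE) {
  if (!(fraction > 0 && fraction < 1))
    stop("configuration error: fraction must lie strictly in (0, 1)")
  stopifnot(nawm_ring_mm > 0)
  structure(list(fraction = fraction, nawm_ring_mm = nawm_ring_mm,
                 require_t2_bright = require_t2_bright),
            class = "t1_threshold_config")
}

#' Mean T1 intensity of normal-appearing white matter surrounding lesions
#'
#' Averages the T1 intensity over WM voxels within `ring_mm` of the lesion
#' surface, excluding all lesion voxels. When the ring contains no usable
#' voxels the global NAWM mean (WM minus lesions) is used instead, with a
#' warning.
#'
#' @param t1_volume a `vol3d`.
#' @param wm_mask WM mask.
#' @param t2_lesion_mask final T2 lesion mask (defines "surrounding").
#' @param ring_mm ring width in mm.
#' @export
nawm_reference_intensity <- function(t1_volume, wm_mask, t2_lesion_mask,
                                     ring_mm = 5) {
  stop_if_grid_mismatch(t1_volume, wm_mask)
  stop_if_grid_mismatch(t1_volume, t2_lesion_mask)
  les <- unclass(t2_lesion_mask) > 0
  wm <- unclass(wm_mask) > 0
  nawm <- wm & !les
  if (!any(nawm)) stop("reference error: no NAWM voxels at all")
  if (any(les)) {
    ring <- unclass(dilate_mask_mm(t2_lesion_mask, ring_mm)) > 0
    sel <- nawm & ring
  } else {
    sel <- nawm
  }
  if (!any(sel)) {
    warning("empty NAWM ring; falling back to the global NAWM mean")
    sel <- nawm
  }
  mean(t1_volume[sel])
}

#' Segment T1-hypointense lesions ("black holes")
#'
#' A voxel is included when (a) it lies inside the final T2 lesion mask
#' (hypointensities must be confirmed bright on T2; disable via
#' `require_t2_bright`) and (b) its T1 intensity falls strictly below
#' `fraction` times the surrounding-NAWM reference intensity. The output is
#' a subset of the T2 lesion mask whenever the confirmation rule is on.
#'
#' @param t1_volume a `vol3d`.
#' @param t2_lesion_mask final (post-edit) T2 lesion mask.
#' @param wm_mask WM mask for the NAWM reference.
#' @param config a [t1_threshold_config()].
#' @return binary mask as a `vol3d`.
#' @export
segment_t1_hypointense <- function(t1_volume, t2_lesion_mask, wm_mask,
                                   config = t1_threshold_config()) {
  if (!inherits(config, "t1_threshold_config"))
    stop("configuration error: config must be a t1_threshold_config")
  stop_if_grid_mismatch(t1_volume, t2_lesion_mask)
  ref <- nawm_reference_intensity(t1_volume, wm_mask, t2_lesion_mask,
                                  config$nawm_ring_mm)
  hypo <- unclass(t1_volume) < config$fraction * ref
  if (config$require_t2_bright) hypo <- hypo & unclass(t2_lesion_mask) > 0
  with_geom(t1_volume, hypo * 1)
}

t1_lesion_volume_cm3 <- function(t1_volume, t2_lesion_mask, wm_mask, fraction,
                                 nawm_ring_mm = 5) {
  cfg <- t1_threshold_config(fraction, nawm_ring_mm)
  m <- segment_t1_hypointense(t1_volume, t2_lesion_mask, wm_mask, cfg)
  sum(m) * voxel_volume_mm3(m) / 1000
}

#' Calibrate the T1 threshold across acquisition protocols
#'
#' Given the same subjects scanned under two protocols, finds the threshold
#' fraction for protocol B that makes the T1 lesion volumes match those
#' obtained under protocol A at `reference_fraction`: the objective is the
#' absolute median, over subjects, of the per-subject volume difference
#' `T1LV_B(f) - T1LV_A(reference)`. A grid search (default step 0.005) is
#' refined by bisection on the signed median difference, which is monotone
#' in f.
#'
#' @param paired_subjects list of >= 2 pairs; each element is a list with
#'   components `A` and `B`, each carrying `t1`, `t2_lesion_mask`, `wm_mask`
#'   for that subject under the respective protocol.
#' @param reference_fraction protocol-A threshold fraction (e.g. 0.85).
#' @param grid candidate fractions for protocol B (default
#'   `seq(0.60, 0.95, by = 0.005)`).
#' @param nawm_ring_mm NAWM ring width passed through to the thresholding.
#' @param refine_tol bisection tolerance on the fraction (default 1e-4).
#' @return list with `fraction`, `discrepancy_cm3` (achieved absolute median
#'   volume difference), and `curve` (data frame of fraction vs median
#'   difference over the search grid).
#' @export
calibrate_t1_threshold <- function(paired_subjects, reference_fraction,
                                   grid = seq(0.60, 0.95, by = 0.005),
                                   nawm_ring_mm = 5, refine_tol = 1e-4) {
  if (length(paired_subjects) < 2)
    stop("calibration requires at least 2 paired subjects")
  if (!(reference_fraction > 0 && reference_fraction < 1))
    stop("configuration error: invalid reference fraction")
  ref_vol <- vapply(paired_subjects, function(s)
    t1_lesion_volume_cm3(s$A$t1, s$A$t2_lesion_mask, s$A$wm_mask,
                         reference_fraction, nawm_ring_mm), numeric(1))
  # precompute each protocol-B subject's lesion intensities relative to its
  # NAWM reference; T1LV(f) is then a cheap counting query at any fraction
  rel_b <- lapply(paired_subjects, function(s) {
    ref <- nawm_reference_intensity(s$B$t1, s$B$wm_mask, s$B$t2_lesion_mask,
                                    nawm_ring_mm)
    list(rel = s$B$t1[unclass(s$B$t2_lesion_mask) > 0] / ref,
         vvol = voxel_volume_mm3(s$B$t1) / 1000)
  })
  md_at <- function(f) {
    v <- vapply(rel_b, function(r) sum(r$rel < f) * r$vvol, numeric(1))
    stats::median(v - ref_vol)
  }
  med_diff <- vapply(grid, md_at, numeric(1))
  curve <- data.frame(fraction = grid, median_diff_cm3 = med_diff)
  if (all(med_diff > 0) || all(med_diff < 0)) {
    cond <- structure(class = c("calibration_error", "error", "condition"),
                      list(message = "calibration error: volume curves do not cross (no fraction equates volumes)",
                           call = sys.call(), curve = curve))
    stop(cond)
  }
  best <- which.min(abs(med_diff))
  # bisection between the bracketing grid points on the signed median
  # difference (non-decreasing in f)
  lo_i <- max(which(med_diff <= 0)); hi_i <- min(which(med_diff >= 0))
  lo <- grid[min(lo_i, hi_i)]; hi <- grid[max(lo_i, hi_i)]
  if (hi - lo > refine_tol) {
    while (hi - lo > refine_tol) {
      mid <- (lo + hi) / 2
      if (md_at(mid) <= 0) lo <- mid else hi <- mid
    }
  }
  f_star <- (lo + hi) / 2
  d_star <- abs(md_at(f_star))
  d_grid <- abs(med_diff[best])
  if (d_grid < d_star) { f_star <- grid[best]; d_star <- d_grid }
  list(fraction = f_star, discrepancy_cm3 = d_star, curve = curve)
}
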