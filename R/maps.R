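#' Transform a volume into template (stereotaxic) space
#'
#' Applies a supplied affine (4 x 4, mapping native world mm to template
#' world mm) and resamples onto the template grid: trilinear interpolation
#' for intensities, nearest-neighbour for masks and labels. The identity
#' transform on the native grid is a no-op. The transform itself comes from
#' outside (the phantom generator supplies identity; real use would supply a
#' fitted spatial normalization).
#'
#' @param volume a `vol3d`.
#' @param transform 4 x 4 affine matrix (native -> template).
#' @param template_geom target geometry list; defaults to the source grid.
#' @param method "trilinear" or "nearest".
#' @export
to_template <- function(volume, transform, template_geom = vol_geometry(volume),
                        method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (is.null(transform)) stop("configuration error: missing template transform")
  stopifnot(is.matrix(transform), all(dim(transform) == c(4, 4)))
  if (max(abs(transform - diag(4))) < 1e-12 &&
      identical(template_geom, vol_geometry(volume))) return(volume)
  inv <- solve(transform)
  w <- cbind(voxel_world_coords(template_geom), 1)
  src <- w %*% t(inv)
  pv <- world_to_voxel(src[, 1:3, drop = FALSE], vol_geometry(volume))
  vals <- if (method == "trilinear") trilinear_sample(volume, pv)
          else nearest_sample(volume, pv)
  vol3d(array(vals, template_geom$dim), template_geom$voxdim, template_geom$origin)
}

#' Group lesion frequency map over a compartment
#'
#' Voxelwise fraction of subjects having a lesion at each template location,
#' restricted to the given compartment (supratentorial or infratentorial).
#'
#' @param template_masks list of binary lesion masks on a common template
#'   grid (one per subject).
#' @param compartment_mask mask on the same grid.
#' @return a `vol3d` of frequencies in [0, 1], with attribute `n_subjects`.
#' @export
lesion_frequency_map <- function(template_masks, compartment_mask) {
  if (!length(template_masks)) stop("domain error: no subject masks supplied")
  for (m in template_masks) stop_if_grid_mismatch(m, compartment_mask,
                                                  "subject mask and compartment")
  acc <- Reduce(`+`, lapply(template_masks, function(m) (unclass(m) > 0) * 1))
  freq <- acc / length(template_masks) * (unclass(compartment_mask) > 0)
  out <- with_geom(compartment_mask, freq)
  attr(out, "n_subjects") <- length(template_masks)
  out
}

#' Voxelwise average anatomical image for a group
#' @param template_volumes list of `vol3d` volumes on a common grid.
#' @export
average_anatomy <- function(template_volumes) {
  if (!length(template_volumes)) stop("domain error: no volumes supplied")
  ref <- template_volumes[[1]]
  for (v in template_volumes) stop_if_grid_mismatch(v, ref)
  with_geom(ref, Reduce(`+`, lapply(template_volumes, unclass)) /
                   length(template_volumes))
}

#' Dice overlap between two binary masks
#' @param a,b binary masks on the same grid.
#' @export
dice_coefficient <- function(a, b) {
  aa <- unclass(a) > 0; bb <- unclass(b) > 0
  denom <- sum(aa) + sum(bb)
  if (denom == 0) return(1)
  2 * sum(aa & bb) / denom
}
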