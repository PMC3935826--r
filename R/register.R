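#' Rigid (6-parameter) spatial transform
#'
#' Rotation angles (radians, applied as Rz Ry Rx about the world origin, i.e.
#' the field-of-view centre) followed by a translation in mm. The transform
#' maps a world point p to `R p + t`.
#'
#' @param angles length-3 rotation angles in radians.
#' @param translation length-3 translation in mm.
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0)) {
  stopifnot(length(angles) == 3L, length(translation) == 3L)
  structure(list(angles = as.numeric(angles),
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

rotation_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  rz %*% ry %*% rx
}

# extract Rz Ry Rx angles from a rotation matrix (no gimbal handling;
# registration angles are small)
angles_from_rotation <- function(R) {
  ry <- asin(-R[3, 1])
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  c(rx, ry, rz)
}

#' Apply one rigid transform after another
#' @param a,b `rigid_transform`s; the result acts as `b(a(p))`.
#' @export
compose_rigid <- function(a, b) {
  Ra <- rotation_matrix(a$angles); Rb <- rotation_matrix(b$angles)
  R <- Rb %*% Ra
  t <- as.vector(Rb %*% a$translation) + b$translation
  rigid_transform(angles_from_rotation(R), t)
}

#' Inverse of a rigid transform
#' @param tf a `rigid_transform`.
#' @export
invert_rigid <- function(tf) {
  R <- rotation_matrix(tf$angles)
  rigid_transform(angles_from_rotation(t(R)), as.vector(-t(R) %*% tf$translation))
}

#' Move a volume's content by a rigid transform
#'
#' Pushes the image content forward: the output at world point w equals the
#' input at `T^{-1}(w)`, so a positive translation moves structures in the
#' positive world direction.
#'
#' @param vol a `vol3d`.
#' @param tf a `rigid_transform`.
#' @param method interpolation, "trilinear" or "nearest".
#' @export
apply_rigid <- function(vol, tf, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  geom <- vol_geometry(vol)
  w <- voxel_world_coords(geom)
  R <- rotation_matrix(tf$angles)
  src <- sweep(w, 2, tf$translation, "-") %*% R   # = t(R^T (w - t)) rowwise
  pv <- world_to_voxel(src, geom)
  vals <- if (method == "trilinear") trilinear_sample(vol, pv) else nearest_sample(vol, pv)
  with_geom(vol, vals)
}

msd_objective <- function(par, moving, fixed_vals, w_sel, geom_mov) {
  R <- rotation_matrix(par[1:3])
  src <- sweep(w_sel, 2, par[4:6], "-") %*% R
  pv <- world_to_voxel(src, geom_mov)
  mv <- trilinear_sample(moving, pv, fill = NA)
  ok <- !is.na(mv)
  if (sum(ok) < 0.25 * length(mv)) return(1e12)
  mean((mv[ok] - fixed_vals[ok])^2)
}

#' Rigid intensity-based registration
#'
#' Estimates the 6-parameter rigid transform aligning `moving` to `fixed` by
#' minimising the masked mean-squared intensity difference, with a
#' multi-resolution Nelder-Mead search (coarse subsampling first, then fine).
#' The returned transform, applied to `moving` with [apply_rigid()], realigns
#' it with `fixed`; registering an image against a rigidly perturbed copy of
#' itself therefore recovers the inverse of the perturbation.
#'
#' @param moving,fixed `vol3d` volumes on known geometries.
#' @param mask optional mask on the fixed grid restricting the metric
#'   (default: voxels above the 25th intensity percentile of `fixed`).
#' @param max_iter Nelder-Mead iteration cap per resolution level.
#' @param tol relative convergence tolerance on the metric.
#' @return list with `transform` (a `rigid_transform`), `resampled` (moving
#'   aligned onto the fixed grid), and `metric` (final masked MSD).
#' @export
rigid_register <- function(moving, fixed, mask = NULL, max_iter = 400, tol = 1e-9) {
  geom_f <- vol_geometry(fixed)
  geom_m <- vol_geometry(moving)
  if (is.null(mask)) {
    thr <- stats::quantile(fixed, 0.25)
    mask <- with_geom(fixed, as.numeric(fixed > thr))
  }
  stop_if_grid_mismatch(fixed, mask, "fixed volume and mask")
  w_all <- voxel_world_coords(geom_f)
  msel <- which(mask > 0)
  par <- c(0, 0, 0, 0, 0, 0)
  # multi-resolution: heavy smoothing at the coarse level removes the
  # noise-induced false minimum near identity (interpolation acts as a
  # low-pass filter, so resampling a noisy image slightly off-lattice
  # spuriously lowers the MSD); the metric is evaluated on a capped
  # subsample of mask voxels per level. Rotations in radians and
  # translations in mm are scaled comparably via parscale.
  levels <- list(list(sigma = 3, n_pts = 4000L),
                 list(sigma = 0, n_pts = 16000L))
  seeded <- FALSE
  for (lv in levels) {
    if (lv$sigma > 0) {
      fx <- gaussian_smooth(fixed, lv$sigma)
      mv <- gaussian_smooth(moving, lv$sigma)
    } else {
      fx <- fixed; mv <- moving
    }
    stride <- max(1L, length(msel) %/% lv$n_pts)
    sel <- msel[seq(1, length(msel), by = stride)]
    w_sel <- w_all[sel, , drop = FALSE]
    f_vals <- fx[sel]
    if (!seeded) {
      # coarse seeding: small grids over rotations and translations guard
      # against shallow basins (e.g. near-symmetric axial rotations)
      ang <- pi / 180 * c(-4, -2, 0, 2, 4)
      rot_grid <- as.matrix(expand.grid(ang, ang, ang))
      rot_vals <- apply(rot_grid, 1, function(a)
        msd_objective(c(a, par[4:6]), mv, f_vals, w_sel, geom_m))
      par[1:3] <- rot_grid[which.min(rot_vals), ]
      tr <- c(-3, 0, 3)
      tr_grid <- as.matrix(expand.grid(tr, tr, tr))
      tr_vals <- apply(tr_grid, 1, function(t)
        msd_objective(c(par[1:3], t), mv, f_vals, w_sel, geom_m))
      par[4:6] <- tr_grid[which.min(tr_vals), ]
      seeded <- TRUE
    }
    fit <- stats::optim(par, msd_objective, moving = mv,
                        fixed_vals = f_vals, w_sel = w_sel, geom_mov = geom_m,
                        method = "Nelder-Mead",
                        control = list(maxit = max_iter, reltol = tol,
                                       parscale = c(rep(0.02, 3), rep(1, 3))))
    par <- fit$par
  }
  if (!is.finite(fit$value) || fit$value >= 1e12)
    stop("convergence error: rigid registration failed (metric ",
         format(fit$value), ", par ", paste(signif(par, 3), collapse = ", "), ")")
  tf <- rigid_transform(par[1:3], par[4:6])
  aligned <- apply_rigid_onto(moving, tf, geom_f)
  list(transform = tf, resampled = aligned, metric = fit$value)
}

# apply a rigid transform and resample onto an arbitrary target geometry
apply_rigid_onto <- function(vol, tf, target_geom, method = "trilinear") {
  w <- voxel_world_coords(target_geom)
  R <- rotation_matrix(tf$angles)
  src <- sweep(w, 2, tf$translation, "-") %*% R
  pv <- world_to_voxel(src, vol_geometry(vol))
  vals <- if (method == "trilinear") trilinear_sample(vol, pv) else nearest_sample(vol, pv)
  vol3d(array(vals, target_geom$dim), target_geom$voxdim, target_geom$origin)
}
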