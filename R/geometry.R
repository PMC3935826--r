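#' 3-D intensity volume with voxel geometry
#'
#' A `vol3d` is a numeric 3-D array carrying its voxel dimensions (mm) and the
#' world coordinate (mm) of the centre of voxel (1,1,1). By default the field
#' of view is centred on the world origin, so volumes with the same physical
#' extent share a coordinate frame regardless of sampling.
#'
#' @param data numeric 3-D array.
#' @param voxdim numeric length-3, voxel size in mm along each axis.
#' @param origin numeric length-3, world mm of the first voxel centre;
#'   default centres the field of view at 0.
#' @return a `vol3d` array.
#' @export
vol3d <- function(data, voxdim, origin = NULL) {
  stopifnot(length(dim(data)) == 3L, length(voxdim) == 3L, all(voxdim > 0))
  if (is.null(origin)) origin <- -(dim(data) - 1) * voxdim / 2
  structure(data, voxdim = as.numeric(voxdim), origin = as.numeric(origin),
            class = c("vol3d", "array"))
}

#' @export
voxdim <- function(x) attr(x, "voxdim")

#' @export
vox_origin <- function(x) attr(x, "origin")

#' Voxel volume in mm^3
#' @param x a `vol3d` or a geometry list.
#' @export
voxel_volume_mm3 <- function(x) prod(voxdim(x))

#' Voxel geometry of a volume
#' @param x a `vol3d`.
#' @return list with `dim`, `voxdim`, `origin`.
#' @export
vol_geometry <- function(x) list(dim = dim(x), voxdim = voxdim(x), origin = vox_origin(x))

# tolerance 1e-6 mm: NIfTI headers store voxel sizes in single precision
same_grid <- function(a, b) {
  identical(dim(a), dim(b)) &&
    isTRUE(all.equal(voxdim(a), voxdim(b), tolerance = 1e-6)) &&
    isTRUE(all.equal(vox_origin(a), vox_origin(b), tolerance = 1e-6))
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) stop("geometry error: ", what, " are not on the same grid")
  invisible(TRUE)
}

# keep geometry attributes when deriving a new array on the same grid
with_geom <- function(template, data) {
  vol3d(array(data, dim = dim(template)), voxdim(template), vox_origin(template))
}

#' World coordinates of every voxel centre
#'
#' @param geom geometry list as returned by [vol_geometry()].
#' @return n x 3 matrix of world mm, voxels in array (column-major) order.
#' @export
voxel_world_coords <- function(geom) {
  d <- geom$dim; vd <- geom$voxdim; or <- geom$origin
  xs <- or[1] + (seq_len(d[1]) - 1) * vd[1]
  ys <- or[2] + (seq_len(d[2]) - 1) * vd[2]
  zs <- or[3] + (seq_len(d[3]) - 1) * vd[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

world_to_voxel <- function(pts, geom) {
  sweep(sweep(pts, 2, geom$origin, "-"), 2, geom$voxdim, "/") + 1
}

#' Trilinear sampling of a volume at fractional voxel coordinates
#'
#' @param vol 3-D array.
#' @param pts n x 3 matrix of 1-based fractional voxel coordinates.
#' @param fill value for points outside the array (default 0).
#' @return numeric vector of sampled intensities.
#' @export
trilinear_sample <- function(vol, pts, fill = 0) {
  d <- dim(vol)
  n <- nrow(pts)
  out <- rep(as.numeric(fill), n)
  inside <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
            pts[, 2] >= 1 & pts[, 2] <= d[2] &
            pts[, 3] >= 1 & pts[, 3] <= d[3]
  if (!any(inside)) return(out)
  x <- pts[inside, 1]; y <- pts[inside, 2]; z <- pts[inside, 3]
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1); z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  s1 <- d[1]; s2 <- d[1] * d[2]
  base <- x0 + (y0 - 1) * s1 + (z0 - 1) * s2
  v000 <- vol[base];            v100 <- vol[base + 1]
  v010 <- vol[base + s1];       v110 <- vol[base + 1 + s1]
  v001 <- vol[base + s2];       v101 <- vol[base + 1 + s2]
  v011 <- vol[base + s1 + s2];  v111 <- vol[base + 1 + s1 + s2]
  out[inside] <-
    v000 * (1 - fx) * (1 - fy) * (1 - fz) + v100 * fx * (1 - fy) * (1 - fz) +
    v010 * (1 - fx) * fy * (1 - fz)       + v110 * fx * fy * (1 - fz) +
    v001 * (1 - fx) * (1 - fy) * fz       + v101 * fx * (1 - fy) * fz +
    v011 * (1 - fx) * fy * fz             + v111 * fx * fy * fz
  out
}

nearest_sample <- function(vol, pts, fill = 0) {
  d <- dim(vol)
  n <- nrow(pts)
  i <- round(pts[, 1]); j <- round(pts[, 2]); k <- round(pts[, 3])
  inside <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out <- rep(as.numeric(fill), n)
  idx <- i[inside] + (j[inside] - 1) * d[1] + (k[inside] - 1) * d[1] * d[2]
  out[inside] <- vol[idx]
  out
}

#' Resample a volume onto a target voxel grid
#'
#' Maps every target voxel centre into the source frame through world
#' coordinates and interpolates. Used to bring thin-slice acquisitions onto
#' the common 3 mm analysis grid. Intensities are interpolated trilinearly;
#' label/mask volumes should use `method = "nearest"` or be re-thresholded at
#' 0.5 after trilinear resampling.
#'
#' @param volume a `vol3d`.
#' @param target geometry list (`dim`, `voxdim`, optional `origin`).
#' @param method "trilinear" (default) or "nearest".
#' @param fill intensity for target voxels outside the source field of view.
#' @return a `vol3d` on the target grid.
#' @export
resample_to_grid <- function(volume, target, method = c("trilinear", "nearest"),
                             fill = 0) {
  method <- match.arg(method)
  stopifnot(all(target$voxdim > 0))
  if (is.null(target$origin)) target$origin <- -(target$dim - 1) * target$voxdim / 2
  src <- vol_geometry(volume)
  # degenerate fast path: identical geometry is a no-op
  if (identical(as.integer(target$dim), as.integer(src$dim)) &&
      isTRUE(all.equal(target$voxdim, src$voxdim, tolerance = 1e-12)) &&
      isTRUE(all.equal(target$origin, src$origin, tolerance = 1e-12))) {
    return(volume)
  }
  lo_s <- src$origin - src$voxdim / 2
  hi_s <- src$origin + (src$dim - 0.5) * src$voxdim
  lo_t <- target$origin - target$voxdim / 2
  hi_t <- target$origin + (target$dim - 0.5) * target$voxdim
  if (any(hi_t < lo_s) || any(lo_t > hi_s))
    stop("geometry error: source and target fields of view do not overlap")
  w <- voxel_world_coords(target)
  pv <- world_to_voxel(w, src)
  vals <- if (method == "trilinear") trilinear_sample(volume, pv, fill = fill)
          else nearest_sample(volume, pv, fill = fill)
  vol3d(array(vals, dim = target$dim), target$voxdim, target$origin)
}

# --- smoothing and morphology helpers ----------------------------------------

# dense 1-D Gaussian operator along one axis (exact, zero boundary);
# rows are normalised so smoothing a constant stays constant away from any
# masked normalisation the caller applies
axis_gaussian_matrix <- function(n, step_mm, sigma_mm, normalize = TRUE) {
  pos <- (seq_len(n) - 1) * step_mm
  K <- exp(-outer(pos, pos, "-")^2 / (2 * sigma_mm^2))
  if (normalize) K <- K / rowSums(K)
  K
}

apply_along_axis1 <- function(vol, K) {
  d <- dim(vol)
  array(K %*% matrix(vol, d[1]), d)
}

#' Gaussian smoothing of a 3-D volume (separable, mm-scaled kernel)
#'
#' Exact separable convolution with zero-value boundary handling; callers
#' doing masked smoothing should smooth `vol * mask` and `mask` with
#' `normalize = FALSE` and divide, which cancels the boundary truncation.
#'
#' @param vol a `vol3d` or array with matching `voxdim`.
#' @param sigma_mm isotropic kernel standard deviation in mm.
#' @param voxdim voxel size; taken from `vol` when absent.
#' @param normalize normalise kernel rows to sum 1 (default TRUE).
#' @export
gaussian_smooth <- function(vol, sigma_mm, voxdim = attr(vol, "voxdim"),
                            normalize = TRUE) {
  stopifnot(!is.null(voxdim), sigma_mm > 0)
  d <- dim(vol)
  out <- unclass(vol)
  for (ax in 1:3) {
    K <- axis_gaussian_matrix(d[ax], voxdim[ax], sigma_mm, normalize)
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
    out <- aperm(apply_along_axis1(aperm(out, perm), K), order(perm))
  }
  if (inherits(vol, "vol3d")) with_geom(vol, out) else out
}

# binary dilation by a physical radius (mm) via explicit index shifts
# (no wrap-around); radius 0 returns the mask itself
dilate_mask_mm <- function(mask, radius_mm, voxdim = attr(mask, "voxdim")) {
  stopifnot(!is.null(voxdim), radius_mm >= 0)
  m <- unclass(mask) > 0
  d <- dim(m)
  if (radius_mm > 0) {
    half <- as.integer(floor(radius_mm / voxdim))
    off <- as.matrix(expand.grid(x = -half[1]:half[1], y = -half[2]:half[2],
                                 z = -half[3]:half[3]))
    r <- sqrt((off[, 1] * voxdim[1])^2 + (off[, 2] * voxdim[2])^2 +
              (off[, 3] * voxdim[3])^2)
    off <- off[r <= radius_mm + 1e-9 & r > 0, , drop = FALSE]
    out <- m
    for (i in seq_len(nrow(off))) {
      sx <- off[i, 1]; sy <- off[i, 2]; sz <- off[i, 3]
      xs <- max(1, 1 + sx):min(d[1], d[1] + sx)
      ys <- max(1, 1 + sy):min(d[2], d[2] + sy)
      zs <- max(1, 1 + sz):min(d[3], d[3] + sz)
      out[xs, ys, zs] <- out[xs, ys, zs] | m[xs - sx, ys - sy, zs - sz]
    }
    m <- out
  }
  out <- m * 1
  if (inherits(mask, "vol3d")) with_geom(mask, out) else out
}
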