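#' Acquisition protocol specification
#'
#' Defines the phantom's emulation of one acquisition protocol: grid sampling
#' (in-plane resolution and slice thickness), per-tissue mean intensities for
#' the PD/T2/T1 contrasts, the noise level, and the T1 lesion-intensity model.
#'
#' The pediatric protocol uses 2 mm contiguous axial slices and the adult
#' protocol 3 mm slices, both at 0.98 mm in-plane. The T2 tissue means are set
#' so that the WM:GM contrast ratio is 1.36 (pediatric) and 1.38 (adult). The
#' two protocols also differ slightly in T1 lesion contrast: lesion T1
#' intensities, expressed as a fraction of the WM mean, are scaled by
#' `t1_profile_scale`, constructed so that a relative threshold of 0.85 under
#' the pediatric protocol selects the same tissue as 0.83 under the adult
#' protocol (`0.83/0.85` scaling). `t1_threshold_fraction` records the
#' protocol's nominal segmentation threshold.
#'
#' Within-tissue intensity texture (`texture_sigma`, one SD per contrast,
#' spatial scale `texture_scale_mm`) emulates the smooth biological
#' variability of real tissue, which broadens the intensity histogram around
#' each class mean the way real scans do; without it percentile-based
#' intensity standardization would be ill-posed. The milder T1 texture
#' reflects the flatter appearance of the spoiled-gradient T1 acquisition.
#'
#' @param name "pediatric" or "adult".
#' @param ... overrides for any protocol field.
#' @return list of class `protocol_spec`.
#' @export
protocol_spec <- function(name = c("pediatric", "adult"), ...) {
  name <- match.arg(name)
  tm <- rbind(WM     = c(PD = 110, T2 = 136, T1 = 100),
              GM     = c(PD = 118, T2 = 100, T1 = 85),
              CSF    = c(PD = 155, T2 = 250, T1 = 40),
              lesion = c(PD = 145, T2 = 190, T1 = 100))
  p <- list(name = name,
            slice_thickness_mm = if (name == "pediatric") 2.0 else 3.0,
            inplane_mm = 0.98,
            tissue_means = tm,
            noise_sigma = 1.5,
            t1_lesion_core_multiplier = 0.7,
            t1_threshold_fraction = if (name == "pediatric") 0.85 else 0.83,
            t1_profile_scale = if (name == "pediatric") 1.0 else 0.83 / 0.85,
            t1_profile_knot = 0.85,
            texture_sigma = c(PD = 3, T2 = 3, T1 = 1),
            texture_scale_mm = 8)
  if (name == "adult") p$tissue_means["WM", "T2"] <- 138
  ov <- list(...)
  p[names(ov)] <- ov
  stopifnot(p$slice_thickness_mm > 0, p$inplane_mm > 0,
            p$noise_sigma >= 0,
            p$t1_lesion_core_multiplier > 0, p$t1_lesion_core_multiplier < 1,
            p$t1_threshold_fraction > 0, p$t1_threshold_fraction < 1)
  class(p) <- "protocol_spec"
  p
}

#' @export
protocol_voxdim <- function(protocol) {
  c(protocol$inplane_mm, protocol$inplane_mm, protocol$slice_thickness_mm)
}

default_grid_for <- function(protocol) {
  # 94 x 94 x 120 mm field of view under either slice thickness
  c(96L, 96L, as.integer(round(120 / protocol$slice_thickness_mm)))
}

#' Phantom specification for one subject
#'
#' @param protocol a [protocol_spec()].
#' @param grid_shape array dimensions; default gives a 94 x 94 x 120 mm field
#'   of view at the protocol's sampling.
#' @param n_lesions_by_region named nonnegative integer vector over lesion
#'   placement regions (`supratentorial`, `cerebellum`, `midbrain`, `pons`,
#'   `medulla`).
#' @param lesion_radius_range_mm sampling interval for lesion radii.
#' @param t1_core_fraction fraction of each lesion's voxels made
#'   T1-hypointense (the chronic "black hole" core).
#' @param bias_field_amplitude peak magnitude of the log bias field over the
#'   brain (0 disables it).
#' @param seed integer RNG seed; same spec + seed reproduces the subject
#'   bit for bit.
#' @param lesion_radii_by_region optional named list of explicit radii (mm)
#'   per region, overriding random draws (used by the cohort sampler to hit
#'   volume targets).
#' @param inter_contrast_shift_mm optional length-3 translation applied to the
#'   PD and T1 volumes to emulate inter-contrast misalignment (default 0).
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(protocol = protocol_spec("pediatric"),
                         grid_shape = default_grid_for(protocol),
                         n_lesions_by_region = c(supratentorial = 8L, pons = 1L),
                         lesion_radius_range_mm = c(2.5, 6),
                         t1_core_fraction = 0.4,
                         bias_field_amplitude = 0,
                         seed = 1L,
                         lesion_radii_by_region = NULL,
                         inter_contrast_shift_mm = c(0, 0, 0)) {
  stopifnot(inherits(protocol, "protocol_spec"),
            length(lesion_radius_range_mm) == 2L,
            all(lesion_radius_range_mm > 0),
            diff(lesion_radius_range_mm) >= 0,
            t1_core_fraction >= 0, t1_core_fraction <= 1,
            bias_field_amplitude >= 0)
  if (length(n_lesions_by_region) && is.null(names(n_lesions_by_region)))
    stop("n_lesions_by_region must be named by region")
  ok <- c("supratentorial", "cerebellum", "midbrain", "pons", "medulla",
          "brainstem", "infratentorial")
  bad <- setdiff(names(n_lesions_by_region), ok)
  if (length(bad)) stop("unknown lesion placement region(s): ", paste(bad, collapse = ", "))
  structure(list(protocol = protocol, grid_shape = as.integer(grid_shape),
                 n_lesions_by_region = n_lesions_by_region,
                 lesion_radius_range_mm = lesion_radius_range_mm,
                 t1_core_fraction = t1_core_fraction,
                 bias_field_amplitude = bias_field_amplitude,
                 seed = as.integer(seed),
                 lesion_radii_by_region = lesion_radii_by_region,
                 inter_contrast_shift_mm = inter_contrast_shift_mm),
            class = "phantom_spec")
}

# relative T1 intensity profile inside a lesion: ramps from the core
# multiplier at the centre to the profile knot (0.85) at the edge of the
# hypointense core, then on up to 1 at the lesion boundary; the protocol's
# t1_profile_scale is applied afterwards. r and r_core/r_lesion in mm.
t1_relative_profile <- function(r, r_core, r_lesion, core_mult, knot = 0.85) {
  u <- numeric(length(r))
  if (r_core > 0) {
    inside <- r < r_core
    u[inside] <- core_mult + (knot - core_mult) * (r[inside] / r_core)
    u[!inside] <- knot + (1 - knot) * pmin(1, (r[!inside] - r_core) /
                                              max(r_lesion - r_core, 1e-9))
  } else {
    u <- knot + (1 - knot) * pmin(1, r / r_lesion)
  }
  u
}

# smooth multiplicative bias field: 2-3 broad gaussian bumps in the log
# domain, zero-centred over the brain and scaled to the requested peak
# magnitude, then exponentiated (strictly positive by construction)
make_bias_field <- function(geom, brain, amplitude) {
  ones <- array(1, geom$dim)
  if (amplitude <= 0) return(ones)
  w <- voxel_world_coords(geom)
  nb <- sample(2:3, 1)
  g <- numeric(nrow(w))
  half_fov <- geom$dim * geom$voxdim / 2
  for (i in seq_len(nb)) {
    ctr <- stats::runif(3, -0.5, 0.5) * half_fov
    sg <- stats::runif(1, 25, 45)
    amp <- sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1)
    d2 <- (w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2 + (w[, 3] - ctr[3])^2
    g <- g + amp * exp(-d2 / (2 * sg^2))
  }
  g <- g - mean(g[brain])
  peak <- max(abs(g[brain]))
  if (peak > 0) g <- g * amplitude / peak
  array(exp(g), geom$dim)
}

#' Generate one synthetic multi-contrast subject with ground truth
#'
#' Builds the region atlas on the protocol grid, implants PD/T2-hyperintense
#' spherical lesions (jittered radii) into the WM of the requested regions —
#' enforcing a separation of at least one voxel between distinct lesions —
#' gives each lesion a graded T1-hypointense core covering `t1_core_fraction`
#' of its voxels, then applies a smooth multiplicative bias field and additive
#' Gaussian noise.
#'
#' @param spec a [phantom_spec()].
#' @param atlas optional pre-built [build_region_atlas()] on the spec grid
#'   (rebuilt when absent).
#' @param id subject identifier stored in the scan.
#' @return list with `scan` (class `subject_scan`: `pd`, `t2`, `t1`,
#'   `brain_mask`, `protocol`, `id`) and `truth` (class `ground_truth`:
#'   `t2_lesion_mask`, `t1_lesion_mask`, `lesions` data frame,
#'   `true_bias_field`, `template_transform`).
#' @export
generate_subject <- function(spec, atlas = NULL, id = "subject") {
  stopifnot(inherits(spec, "phantom_spec"))
  p <- spec$protocol
  vd <- protocol_voxdim(p)
  if (is.null(atlas)) atlas <- build_region_atlas(spec$grid_shape, vd)
  if (!identical(as.integer(dim(atlas$labels)), spec$grid_shape))
    stop("atlas grid does not match phantom spec grid")
  set.seed(spec$seed)
  geom <- atlas$geometry
  d <- geom$dim
  nvox <- prod(d)
  tissue <- as.integer(atlas$tissue)
  brain <- tissue > 0L

  # noiseless tissue intensities (air at a small positive mean)
  base <- matrix(5, nvox, 3, dimnames = list(NULL, c("PD", "T2", "T1")))
  for (cls in rownames(p$tissue_means)[1:3]) {
    ix <- tissue == TISSUE_LABELS[[cls]]
    base[ix, ] <- rep(p$tissue_means[cls, ], each = sum(ix))
  }

  # --- lesion placement ------------------------------------------------------
  t2les <- logical(nvox)
  blocked <- logical(nvox)   # lesions dilated by one voxel (26-sense)
  s1 <- d[1]; s2 <- d[1] * d[2]
  box_off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  lesion_rows <- list()
  rel_t1 <- numeric(nvox)    # relative T1 profile on lesion voxels
  lid <- 0L
  regs <- names(spec$n_lesions_by_region)
  for (reg in regs) {
    n_req <- spec$n_lesions_by_region[[reg]]
    if (n_req < 1) next
    wm <- region_wm_mask(atlas, reg)
    cand <- which(wm > 0)
    if (!length(cand)) stop("placement error: region ", reg, " has no WM voxels")
    wm_l <- as.logical(wm > 0)
    radii <- spec$lesion_radii_by_region[[reg]]
    for (i in seq_len(n_req)) {
      r_mm <- if (!is.null(radii)) radii[i] else
        stats::runif(1, spec$lesion_radius_range_mm[1], spec$lesion_radius_range_mm[2])
      placed <- FALSE
      for (try in seq_len(300L)) {
        ctr <- cand[sample.int(length(cand), 1L)]
        ci <- ((ctr - 1) %% s1) + 1
        cj <- (((ctr - 1) %/% s1) %% d[2]) + 1
        ck <- ((ctr - 1) %/% s2) + 1
        # continuous sub-voxel centre: real lesions are not grid-aligned,
        # and grid-centred spheres would bias slice-direction volumes
        oc <- stats::runif(3, -0.5, 0.5)
        half <- ceiling(r_mm / vd + 0.5)
        ii <- max(1, ci - half[1]):min(d[1], ci + half[1])
        jj <- max(1, cj - half[2]):min(d[2], cj + half[2])
        kk <- max(1, ck - half[3]):min(d[3], ck + half[3])
        g <- expand.grid(i = ii, j = jj, k = kk)
        dist <- sqrt(((g$i - ci - oc[1]) * vd[1])^2 +
                     ((g$j - cj - oc[2]) * vd[2])^2 +
                     ((g$k - ck - oc[3]) * vd[3])^2)
        keep <- dist <= r_mm
        if (!any(keep)) next
        vox <- g[keep, ]
        dist <- dist[keep]
        lin <- vox$i + (vox$j - 1) * s1 + (vox$k - 1) * s2
        # whole sphere must sit in this region's WM (no clipping at the
        # array edge either), clear of previously placed lesions
        if ((ci - half[1] < 1) || (ci + half[1] > d[1]) ||
            (cj - half[2] < 1) || (cj + half[2] > d[2]) ||
            (ck - half[3] < 1) || (ck + half[3] > d[3])) next
        if (!all(wm_l[lin]) || any(blocked[lin])) next
        lid <- lid + 1L
        t2les[lin] <- TRUE
        r_core <- r_mm * spec$t1_core_fraction^(1 / 3)
        rel_t1[lin] <- t1_relative_profile(dist, r_core, r_mm,
                                           p$t1_lesion_core_multiplier,
                                           p$t1_profile_knot)
        # block the one-voxel neighbourhood for later lesions
        nb <- unique(as.vector(outer(lin, box_off[, 1] + box_off[, 2] * s1 +
                                       box_off[, 3] * s2, "+")))
        nb <- nb[nb >= 1 & nb <= nvox]
        blocked[nb] <- TRUE
        lesion_rows[[lid]] <- data.frame(
          id = lid, region = reg, cx = ci, cy = cj, cz = ck,
          radius_mm = r_mm, n_voxels = length(lin),
          volume_mm3 = length(lin) * prod(vd))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("placement error: could not place a ", round(r_mm, 2),
             " mm lesion in region ", reg, " after 300 attempts")
    }
  }

  les_ix <- which(t2les)
  if (length(les_ix)) {
    base[les_ix, "PD"] <- p$tissue_means["lesion", "PD"]
    base[les_ix, "T2"] <- p$tissue_means["lesion", "T2"]
    base[les_ix, "T1"] <- p$t1_profile_scale * rel_t1[les_ix] *
      p$tissue_means["WM", "T1"]
  }
  # smooth within-tissue texture (biological variability; part of the
  # noiseless anatomy, so it precedes the ground-truth T1 thresholding)
  for (ctr in colnames(base)) {
    ts <- p$texture_sigma[[ctr]]
    if (is.null(ts) || ts <= 0) next
    tex <- gaussian_smooth(array(stats::rnorm(nvox), d), p$texture_scale_mm, vd)
    tex <- tex / stats::sd(tex[brain])
    base[brain, ctr] <- base[brain, ctr] + ts * tex[brain]
  }

  # ground-truth T1 core: voxels strictly below the protocol threshold,
  # evaluated on the noiseless volume relative to the WM mean
  t1les <- logical(nvox)
  t1les[les_ix] <- base[les_ix, "T1"] <
    p$t1_threshold_fraction * p$tissue_means["WM", "T1"]

  bias <- make_bias_field(geom, brain, spec$bias_field_amplitude)
  mkvol <- function(v) vol3d(array(v, d), geom$voxdim, geom$origin)
  noise <- function() if (p$noise_sigma > 0)
    stats::rnorm(nvox, 0, p$noise_sigma) else 0
  vols <- list()
  for (ctr in c("PD", "T2", "T1"))
    vols[[ctr]] <- mkvol(base[, ctr] * as.vector(bias) + noise())
  shift <- spec$inter_contrast_shift_mm
  if (any(shift != 0)) {
    tf <- rigid_transform(c(0, 0, 0), shift)
    vols$PD <- apply_rigid(vols$PD, tf)
    vols$T1 <- apply_rigid(vols$T1, tf)
  }

  scan <- structure(list(id = id, protocol = p,
                         pd = vols$PD, t2 = vols$T2, t1 = vols$T1,
                         brain_mask = atlas$brain_mask,
                         normalized = FALSE),
                    class = "subject_scan")
  lesions <- if (length(lesion_rows)) do.call(rbind, lesion_rows) else
    data.frame(id = integer(), region = character(), cx = integer(),
               cy = integer(), cz = integer(), radius_mm = numeric(),
               n_voxels = integer(), volume_mm3 = numeric())
  truth <- structure(list(
    t2_lesion_mask = mkvol(as.numeric(t2les)),
    t1_lesion_mask = mkvol(as.numeric(t1les)),
    lesions = lesions,
    true_bias_field = mkvol(as.vector(bias)),
    template_transform = diag(4)), class = "ground_truth")
  list(scan = scan, truth = truth, atlas = atlas)
}
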