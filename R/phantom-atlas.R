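#' Region labels used by the atlas
#' @export
REGION_LABELS <- c(supratentorial = 1L, cerebellum = 2L, midbrain = 3L,
                   pons = 4L, medulla = 5L, ventricles = 6L)

#' Tissue labels used by the phantom
#' @export
TISSUE_LABELS <- c(WM = 1L, GM = 2L, CSF = 3L)

#' Build the synthetic region atlas
#'
#' Constructs a brain made of nested ellipsoids on the requested grid: a brain
#' ellipsoid split by an axial tentorium plane into a supratentorial
#' compartment and an infratentorial compartment; the infratentorial part is
#' divided into a brainstem column (stacked midbrain / pons / medulla, taken
#' to include the cerebellar peduncles) and the surrounding cerebellum; a pair
#' of elongated ventricles sits in the supratentorial centre. Every brain
#' voxel carries exactly one base label. Tissue classes are WM (interior), GM
#' (cortical shell plus a thin cerebellar shell; the brainstem is all WM) and
#' CSF (ventricles).
#'
#' Derived masks: brainstem = midbrain + pons + medulla; infratentorial =
#' brainstem + cerebellum; periventricular = brain voxels within
#' `periventricular_mm` of a ventricle voxel.
#'
#' @param grid_shape integer length-3 array dimensions.
#' @param voxel_size numeric length-3 voxel size in mm.
#' @param periventricular_mm dilation distance defining the periventricular
#'   region (mm); 0 reduces the mask to the ventricles themselves.
#' @return object of class `region_atlas`: `labels`, `tissue`, `brain_mask`,
#'   a named list `masks`, and the grid geometry.
#' @export
build_region_atlas <- function(grid_shape = c(96L, 96L, 60L),
                               voxel_size = c(0.98, 0.98, 2.0),
                               periventricular_mm = 3) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, length(voxel_size) == 3L, all(voxel_size > 0))
  fov <- grid_shape * voxel_size
  # compartment geometry in world mm (frame centred on 0)
  brain_c <- c(0, 0, 4)
  brain_a <- c(43, 43, 52)
  tent_z <- -18            # tentorium plane
  bs_centre_y <- -12       # brainstem column axis (anterior)
  bs_radius <- 11
  vent_c1 <- c(-9, 6, 16); vent_c2 <- c(9, 6, 16)
  vent_a <- c(5, 16, 7)
  gm_shell <- 0.84         # normalised ellipsoid radius where cortex begins
  cereb_shell <- 0.945     # thin cerebellar GM shell
  csf_shell <- 0.97        # peripheral (subarachnoid) CSF inside the mask
  if (any(fov / 2 < abs(brain_c) + brain_a + voxel_size))
    stop("sizing error: grid too small to hold the brain compartments (need FOV > ",
         paste(round(2 * (abs(brain_c) + brain_a)), collapse = "x"), " mm)")

  geom <- list(dim = grid_shape, voxdim = voxel_size,
               origin = -(grid_shape - 1) * voxel_size / 2)
  w <- voxel_world_coords(geom)
  rho2 <- ((w[, 1] - brain_c[1]) / brain_a[1])^2 +
          ((w[, 2] - brain_c[2]) / brain_a[2])^2 +
          ((w[, 3] - brain_c[3]) / brain_a[3])^2
  brain <- rho2 <= 1
  rho <- sqrt(rho2)
  vent <- (((w[, 1] - vent_c1[1]) / vent_a[1])^2 +
           ((w[, 2] - vent_c1[2]) / vent_a[2])^2 +
           ((w[, 3] - vent_c1[3]) / vent_a[3])^2 <= 1) |
          (((w[, 1] - vent_c2[1]) / vent_a[1])^2 +
           ((w[, 2] - vent_c2[2]) / vent_a[2])^2 +
           ((w[, 3] - vent_c2[3]) / vent_a[3])^2 <= 1)
  vent <- vent & brain
  infra <- brain & (w[, 3] < tent_z) & !vent
  stem <- infra & ((w[, 1]^2 + (w[, 2] - bs_centre_y)^2) <= bs_radius^2)
  zr <- range(w[infra, 3])
  cuts <- zr[1] + diff(zr) * c(1, 2) / 3        # medulla | pons | midbrain
  labels <- integer(nrow(w))
  labels[brain & !vent & !infra] <- REGION_LABELS[["supratentorial"]]
  labels[infra & !stem] <- REGION_LABELS[["cerebellum"]]
  labels[stem & w[, 3] >= cuts[2]] <- REGION_LABELS[["midbrain"]]
  labels[stem & w[, 3] < cuts[2] & w[, 3] >= cuts[1]] <- REGION_LABELS[["pons"]]
  labels[stem & w[, 3] < cuts[1]] <- REGION_LABELS[["medulla"]]
  labels[vent] <- REGION_LABELS[["ventricles"]]

  tissue <- integer(nrow(w))
  tissue[brain] <- TISSUE_LABELS[["WM"]]
  supra_ix <- labels == REGION_LABELS[["supratentorial"]]
  tissue[supra_ix & rho > gm_shell] <- TISSUE_LABELS[["GM"]]
  cereb_ix <- labels == REGION_LABELS[["cerebellum"]]
  tissue[cereb_ix & rho > cereb_shell] <- TISSUE_LABELS[["GM"]]
  # peripheral subarachnoid CSF: keeps the CSF fraction of the mask
  # realistic (~9%), which anchors the extreme intensity percentiles used
  # by the two-piece normalization
  tissue[brain & rho > csf_shell] <- TISSUE_LABELS[["CSF"]]
  tissue[vent] <- TISSUE_LABELS[["CSF"]]

  as_vol <- function(v) vol3d(array(v, grid_shape), voxel_size, geom$origin)
  lab_vol <- as_vol(labels)
  brain_vol <- as_vol(as.numeric(brain))
  m <- function(labs) as_vol(as.numeric(labels %in% REGION_LABELS[labs]))
  masks <- list(
    supratentorial = m("supratentorial"),
    cerebellum = m("cerebellum"),
    midbrain = m("midbrain"),
    pons = m("pons"),
    medulla = m("medulla"),
    ventricles = m("ventricles"),
    brainstem = m(c("midbrain", "pons", "medulla")),
    infratentorial = m(c("cerebellum", "midbrain", "pons", "medulla"))
  )
  pv <- dilate_mask_mm(masks$ventricles, periventricular_mm)
  pv <- with_geom(pv, as.numeric(pv > 0 & brain_vol > 0))
  masks$periventricular <- pv
  masks$non_periventricular <- with_geom(pv, as.numeric(brain_vol > 0 & pv == 0))
  if (sum(masks$pons) < 50 || sum(masks$medulla) < 50 || sum(masks$cerebellum) < 200)
    stop("sizing error: grid too small for minimal compartment geometry")

  structure(list(labels = lab_vol, tissue = as_vol(tissue),
                 brain_mask = brain_vol, masks = masks,
                 periventricular_mm = periventricular_mm,
                 geometry = geom),
            class = "region_atlas")
}

#' WM mask of a region (where lesions can be implanted)
#' @param atlas a `region_atlas`.
#' @param region region name: one of `names(REGION_LABELS)` except
#'   "ventricles", or "brainstem"/"infratentorial".
#' @export
region_wm_mask <- function(atlas, region) {
  if (!region %in% names(atlas$masks) || region == "ventricles")
    stop("unknown lesion placement region: ", region)
  with_geom(atlas$brain_mask,
            as.numeric(atlas$masks[[region]] > 0 &
                       atlas$tissue == TISSUE_LABELS[["WM"]]))
}
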