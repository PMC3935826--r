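connectivity_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  # half-space of neighbour offsets (each undirected adjacency visited once)
  half <- off[, 3] > 0 | (off[, 3] == 0 & off[, 2] > 0) |
          (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0)
  off <- off[half, , drop = FALSE]
  deg <- rowSums(abs(off))
  switch(as.character(connectivity),
         "6" = off[deg == 1, , drop = FALSE],
         "18" = off[deg <= 2, , drop = FALSE],
         "26" = off,
         stop("connectivity must be 6, 18 or 26"))
}

#' Label connected lesion components
#'
#' Two lesion voxels belong to the same lesion iff they are connected under
#' the chosen neighbourhood; with the default 26-connectivity (faces, edges
#' and corners), clusters count as distinct lesions only when separated by at
#' least one background voxel in every direction.
#'
#' @param mask binary volume (values 0/1).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return list with `labels` (integer component volume, labels contiguous
#'   from 1) and `sizes` (voxel count per component).
#' @export
label_lesions <- function(mask, connectivity = 26) {
  v <- unclass(mask)
  if (!all(v %in% c(0, 1))) stop("domain error: mask must be binary")
  d <- dim(v)
  fg <- which(v > 0)
  labels <- array(0L, d)
  if (!length(fg)) {
    out <- if (inherits(mask, "vol3d")) with_geom(mask, labels) else labels
    return(list(labels = out, sizes = integer(0)))
  }
  rank <- integer(prod(d))
  rank[fg] <- seq_along(fg)
  ci <- ((fg - 1L) %% d[1]) + 1L
  cj <- (((fg - 1L) %/% d[1]) %% d[2]) + 1L
  ck <- ((fg - 1L) %/% (d[1] * d[2])) + 1L
  off <- connectivity_offsets(connectivity)
  edges <- vector("list", nrow(off))
  for (r in seq_len(nrow(off))) {
    ni <- ci + off[r, 1]; nj <- cj + off[r, 2]; nk <- ck + off[r, 3]
    ok <- ni >= 1L & ni <= d[1] & nj >= 1L & nj <= d[2] & nk >= 1L & nk <= d[3]
    lin <- ni[ok] + (nj[ok] - 1L) * d[1] + (nk[ok] - 1L) * d[1] * d[2]
    hit <- rank[lin] > 0L
    edges[[r]] <- cbind(rank[fg[ok]][hit], rank[lin][hit])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  memb <- igraph::components(g)$membership
  labels[fg] <- as.integer(memb)
  out <- if (inherits(mask, "vol3d")) with_geom(mask, labels) else labels
  list(labels = out, sizes = as.integer(tabulate(memb)))
}

#' Drop components below a minimum voxel count
#'
#' Applies the minimum size criterion for counting a lesion (3 voxels for
#' T2-weighted lesions); removed components disappear from both the count and
#' the volume. Remaining labels are renumbered contiguously from 1.
#'
#' @param components result of [label_lesions()].
#' @param min_voxels minimum component size in voxels (>= 1).
#' @export
filter_min_size <- function(components, min_voxels) {
  if (min_voxels < 1) stop("configuration error: min_voxels must be >= 1")
  sizes <- components$sizes
  keep <- which(sizes >= min_voxels)
  lab <- components$labels
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  newlab <- array(0L, dim(lab))
  nz <- which(unclass(lab) > 0L)
  newlab[nz] <- remap[unclass(lab)[nz]]
  out <- if (inherits(lab, "vol3d")) with_geom(lab, newlab) else newlab
  list(labels = out, sizes = sizes[keep])
}

INVENTORY_REGIONS <- c("whole_brain", "supratentorial", "infratentorial",
                       "brainstem", "midbrain", "pons", "medulla",
                       "cerebellum", "periventricular", "non_periventricular")

region_base_sets <- list(
  whole_brain = c("supratentorial", "cerebellum", "midbrain", "pons", "medulla"),
  supratentorial = "supratentorial",
  infratentorial = c("cerebellum", "midbrain", "pons", "medulla"),
  brainstem = c("midbrain", "pons", "medulla"),
  midbrain = "midbrain", pons = "pons", medulla = "medulla",
  cerebellum = "cerebellum")

inventory_one_modality <- function(mask, atlas, modality, connectivity,
                                   min_voxels, subject_id) {
  vvol <- voxel_volume_mm3(mask)
  comp <- filter_min_size(label_lesions(mask, connectivity), min_voxels)
  lab <- unclass(comp$labels)
  filt_mask <- lab > 0L
  base_names <- c("supratentorial", "cerebellum", "midbrain", "pons", "medulla")
  # per-component majority base label; ties resolved towards supratentorial
  # (first position in base_names)
  n_comp <- length(comp$sizes)
  assigned <- character(0)
  pv_flag <- logical(0)
  if (n_comp > 0) {
    ix <- which(filt_mask)
    cl <- lab[ix]
    reg <- as.integer(atlas$labels)[ix]
    reg_name <- names(REGION_LABELS)[match(reg, REGION_LABELS)]
    tab <- table(factor(cl, levels = seq_len(n_comp)),
                 factor(reg_name, levels = base_names))
    assigned <- base_names[apply(tab, 1, which.max)]
    pv <- unclass(atlas$masks$periventricular)[ix] > 0
    pv_count <- tapply(pv, factor(cl, levels = seq_len(n_comp)), sum)
    pv_flag <- as.vector(pv_count) > comp$sizes / 2
  }
  rows <- lapply(INVENTORY_REGIONS, function(rg) {
    if (rg %in% c("periventricular", "non_periventricular")) {
      rmask <- unclass(atlas$masks[[rg]]) > 0
      cnt <- if (rg == "periventricular") sum(pv_flag) else n_comp - sum(pv_flag)
    } else {
      rmask <- as.integer(atlas$labels) %in% REGION_LABELS[region_base_sets[[rg]]]
      cnt <- sum(assigned %in% region_base_sets[[rg]])
    }
    data.frame(subject_id = subject_id, modality = modality, region = rg,
               count = as.integer(cnt),
               volume_cm3 = sum(filt_mask & rmask) * vvol / 1000)
  })
  do.call(rbind, rows)
}

#' Per-region lesion counts and volumes for one subject
#'
#' Volumes are voxel-membership sums (voxels in the lesion mask intersected
#' with the region, times the voxel volume, in cm^3). Counts assign each
#' connected component once, to the region holding the majority of its
#' voxels (a lesion straddling the tentorium is counted in the compartment
#' with more of its voxels, ties going supratentorial), so compartment counts
#' add up: whole brain = supratentorial + infratentorial, brainstem =
#' midbrain + pons + medulla. The T2 mask is filtered by the 3-voxel minimum
#' size rule before counting; T1 components have no minimum by default.
#'
#' @param t2_mask,t1_mask binary lesion masks on the atlas grid.
#' @param atlas a `region_atlas`.
#' @param connectivity component connectivity (default 26).
#' @param min_voxels_t2,min_voxels_t1 minimum component sizes (defaults 3, 1).
#' @param subject_id identifier written into the table.
#' @return `lesion_inventory`: long data frame subject x modality x region
#'   with `count` and `volume_cm3`; voxel volume in attribute
#'   `voxel_volume_mm3`.
#' @export
regional_inventory <- function(t2_mask, t1_mask, atlas, connectivity = 26,
                               min_voxels_t2 = 3, min_voxels_t1 = 1,
                               subject_id = "subject") {
  stop_if_grid_mismatch(t2_mask, atlas$labels, "mask and atlas")
  stop_if_grid_mismatch(t1_mask, atlas$labels, "mask and atlas")
  inv <- rbind(
    inventory_one_modality(t2_mask, atlas, "T2w", connectivity, min_voxels_t2,
                           subject_id),
    inventory_one_modality(t1_mask, atlas, "T1w", connectivity, min_voxels_t1,
                           subject_id))
  attr(inv, "voxel_volume_mm3") <- voxel_volume_mm3(t2_mask)
  class(inv) <- c("lesion_inventory", "data.frame")
  inv
}
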