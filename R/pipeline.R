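#' Default pipeline configuration
#'
#' Single configuration object for the end-to-end run. Every default that
#' mirrors a published constant is kept here: 3 mm / 0.98 mm analysis grid,
#' T1 threshold fractions 0.85 (pediatric) / 0.83 (adult), 3-voxel minimum
#' T2 lesion size, alpha = 0.05.
#'
#' @param n_per_group subjects per cohort.
#' @param seed master seed (fans out deterministically to subjects).
#' @param out_dir artifact directory (NULL disables writing).
#' @param ... overrides for any field.
#' @export
pipeline_config <- function(n_per_group = 10, seed = 1, out_dir = NULL, ...) {
  cfg <- list(
    n_per_group = n_per_group,
    seed = seed,
    out_dir = out_dir,
    protocols = list(pediatric = protocol_spec("pediatric"),
                     adult = protocol_spec("adult")),
    preprocess = list(normalize_percentiles = c(0.02, 0.5, 0.98),
                      normalize_targets = c(0, 100, 200),
                      bias_smoothness_mm = 20,
                      register = TRUE,
                      register_max_iter = 150),
    segment = list(posterior_threshold = 0.5,
                   nawm_ring_mm = 5,
                   t1_fraction = c(pediatric = 0.85, adult = 0.83),
                   infra_multiple = 1.3,
                   min_lesion_train = 200),
    quantify = list(connectivity = 26, min_voxels_t2 = 3, min_voxels_t1 = 1,
                    periventricular_mm = 3),
    stats = list(alpha = 0.05, log_constant = 1),
    phantom = list(bias_field_amplitude = 0.2, t1_core_fraction = 0.4))
  ov <- list(...)
  cfg[names(ov)] <- ov
  stopifnot(cfg$stats$alpha > 0, cfg$stats$alpha < 1)
  cfg
}

adult_analysis_geometry <- function(cfg) {
  p <- cfg$protocols$adult
  shape <- default_grid_for(p)
  list(dim = shape, voxdim = protocol_voxdim(p),
       origin = -(shape - 1) * protocol_voxdim(p) / 2)
}

log_stage <- function(stage, subject, ...) {
  msg <- paste0("[", stage, "] ", subject,
                if (...length()) paste0(" ", paste(..., sep = " ")) else "")
  message(msg)
}

# silhouette used for inter-contrast rigid registration: MSD across
# different contrasts is meaningless, so align on the head outline
silhouette <- function(vol) with_geom(vol, as.numeric(unclass(vol) > 30))

#' Preprocess one subject onto the common analysis grid
#'
#' Resample to the adult-protocol grid (3 mm slices, 0.98 mm in-plane),
#' correct each contrast for intensity non-uniformity, rigidly register the
#' PD and T1 volumes to the T2 volume, and normalize intensities with the
#' two-piece linear map. Returns both the normalized scan (used by the
#' multispectral classifier) and the bias-corrected unnormalized T1 (used by
#' the relative-threshold T1 segmentation, which is invariant to a global
#' scale but not to the piecewise normalization).
#'
#' @param subject element of a [generate_cohort()] result.
#' @param cfg pipeline configuration.
#' @param target target geometry (default: adult analysis grid).
#' @param atlas_target atlas built on the target grid.
#' @export
preprocess_subject <- function(subject, cfg = pipeline_config(),
                               target = adult_analysis_geometry(cfg),
                               atlas_target = NULL) {
  scan <- subject$scan
  if (is.null(atlas_target))
    atlas_target <- build_region_atlas(target$dim, target$voxdim,
                                       cfg$quantify$periventricular_mm)
  log_stage("resample", scan$id, "->", paste(target$dim, collapse = "x"),
            "@", paste(target$voxdim, collapse = "x"), "mm")
  vols <- list(pd = resample_to_grid(scan$pd, target),
               t2 = resample_to_grid(scan$t2, target),
               t1 = resample_to_grid(scan$t1, target))
  bmask <- atlas_target$brain_mask
  log_stage("bias", scan$id, "sigma", cfg$preprocess$bias_smoothness_mm, "mm")
  for (ctr in names(vols)) {
    fld <- estimate_bias_field(vols[[ctr]], bmask,
                               cfg$preprocess$bias_smoothness_mm)
    vols[[ctr]] <- correct_bias(vols[[ctr]], fld, bmask)
  }
  if (isTRUE(cfg$preprocess$register)) {
    log_stage("register", scan$id, "PD,T1 -> T2")
    fix_sil <- silhouette(vols$t2)
    for (ctr in c("pd", "t1")) {
      reg <- rigid_register(silhouette(vols[[ctr]]), fix_sil,
                            mask = with_geom(fix_sil, rep(1, length(fix_sil))),
                            max_iter = cfg$preprocess$register_max_iter)
      vols[[ctr]] <- apply_rigid(vols[[ctr]], reg$transform)
    }
  }
  t1_corrected <- vols$t1
  log_stage("normalize", scan$id)
  maps <- list()
  ncfg <- list(percentiles = cfg$preprocess$normalize_percentiles,
               targets = cfg$preprocess$normalize_targets)
  for (ctr in names(vols)) {
    nm <- normalize_intensity(vols[[ctr]], bmask, ncfg)
    vols[[ctr]] <- nm$volume
    maps[[ctr]] <- nm$map
  }
  out <- structure(list(id = scan$id, protocol = scan$protocol,
                        pd = vols$pd, t2 = vols$t2, t1 = vols$t1,
                        brain_mask = bmask, normalized = TRUE),
                   class = "subject_scan")
  attr(out, "norm_mid") <- cfg$preprocess$normalize_targets[2]
  list(scan = out, t1_corrected = t1_corrected,
       truth = subject$truth, atlas = atlas_target,
       normalization_maps = maps)
}

# 1-voxel 6-connected erosion (drops boundary voxels of a mask)
erode1 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] & m[-d[1], , ]; out[-d[1], , ] <- out[-d[1], , ] & m[-1, , ]
  out[, -1, ] <- out[, -1, ] & m[, -d[2], ]; out[, -d[2], ] <- out[, -d[2], ] & m[, -1, ]
  out[, , -1] <- out[, , -1] & m[, , -d[3]]; out[, , -d[3]] <- out[, , -d[3]] & m[, , -1]
  out
}

# training voxels for the tissue model from a preprocessed training subject
# whose ground-truth lesion mask is known. Only interior voxels of each
# class are used: after resampling onto the analysis grid, boundary voxels
# are partial-volume mixtures that would smear the class Gaussians.
training_voxels <- function(pp) {
  les <- resample_to_grid(pp$truth$t2_lesion_mask, vol_geometry(pp$scan$t2))
  tis <- array(as.integer(pp$atlas$tissue), dim(pp$atlas$tissue))
  lab <- rep(NA_character_, length(tis))
  for (cls in names(TISSUE_LABELS)) {
    interior <- erode1(tis == TISSUE_LABELS[[cls]])
    lab[interior] <- cls
  }
  lab[unclass(les) > 0.9] <- "lesion"   # mostly-lesion voxels only
  lab[unclass(les) > 0.1 & unclass(les) <= 0.9] <- NA  # mixed edges: neither
  keep <- !is.na(lab)
  list(features = cbind(pp$scan$pd[keep], pp$scan$t2[keep], pp$scan$t1[keep]),
       labels = lab[keep])
}

#' Segment one preprocessed subject
#'
#' Bayesian multispectral segmentation in the supratentorial compartment,
#' relative-threshold segmentation infratentorially, union as the final T2
#' mask (a reviewer-edit volume may be merged in), then relative-threshold
#' T1-hypointensity segmentation inside the T2 mask using the protocol's
#' calibrated fraction.
#'
#' @param pp output of [preprocess_subject()].
#' @param model fitted [fit_tissue_model()] for the subject's protocol group.
#' @param cfg pipeline configuration.
#' @param edits optional reviewer edit volume (codes 0/1/2).
#' @return list with `t2_mask`, `t1_mask`.
#' @export
segment_subject <- function(pp, model, cfg = pipeline_config(), edits = NULL) {
  atlas <- pp$atlas
  log_stage("segment-t2", pp$scan$id)
  wm <- with_geom(atlas$tissue, as.numeric(atlas$tissue == TISSUE_LABELS[["WM"]]))
  # candidate voxels: interior white matter only — the one-voxel layer at
  # WM/CSF and WM/GM interfaces is partial-volume after resampling and
  # mimics lesion intensities in all three contrasts
  wm_int <- with_geom(wm, erode1(unclass(wm) > 0) * 1)
  sup_wm <- with_geom(wm, as.numeric(atlas$masks$supratentorial > 0 & wm_int > 0))
  sup <- segment_t2_lesions(pp$scan, model, sup_wm,
                            cfg$segment$posterior_threshold)
  inf <- segment_infratentorial_t2(pp$scan, atlas$masks$infratentorial, wm_int,
                                   list(multiple = cfg$segment$infra_multiple))
  t2_mask <- with_geom(sup, pmin(unclass(sup) + unclass(inf), 1))
  if (!is.null(edits)) t2_mask <- apply_manual_edits(t2_mask, edits)
  frac <- cfg$segment$t1_fraction[[pp$scan$protocol$name]]
  log_stage("segment-t1", pp$scan$id, "fraction", frac)
  t1_mask <- segment_t1_hypointense(pp$t1_corrected, t2_mask, wm,
                                    t1_threshold_config(frac,
                                                        cfg$segment$nawm_ring_mm))
  list(t2_mask = t2_mask, t1_mask = t1_mask)
}

process_group <- function(group_name, cfg, target, atlas_target) {
  protocol <- cfg$protocols[[group_name]]
  sampler <- cohort_sampler(protocol,
                            t1_core_fraction = cfg$phantom$t1_core_fraction,
                            bias_field_amplitude = cfg$phantom$bias_field_amplitude)
  group_seed <- cfg$seed + ifelse(group_name == "pediatric", 0L, 104729L)
  cohort <- generate_cohort(cfg$n_per_group, sampler, seed = group_seed,
                            id_prefix = substr(group_name, 1, 3))
  # one extra phantom trains the tissue model for this protocol group
  train_spec <- phantom_spec(protocol,
                             n_lesions_by_region = c(supratentorial = 10L,
                                                     cerebellum = 2L, pons = 1L),
                             t1_core_fraction = cfg$phantom$t1_core_fraction,
                             bias_field_amplitude = cfg$phantom$bias_field_amplitude,
                             seed = group_seed + 1L)
  train_pp <- preprocess_subject(generate_subject(train_spec,
                                                  id = paste0(group_name, "-train")),
                                 cfg, target, atlas_target)
  tv <- training_voxels(train_pp)
  model <- fit_tissue_model(tv$features, tv$labels,
                            min_per_class = cfg$segment$min_lesion_train)
  inv <- list(); t2_masks <- list(); t2_vols <- list()
  for (i in seq_along(cohort)) {
    pp <- preprocess_subject(cohort[[i]], cfg, target, atlas_target)
    seg <- segment_subject(pp, model, cfg)
    inv[[i]] <- regional_inventory(seg$t2_mask, seg$t1_mask, atlas_target,
                                   cfg$quantify$connectivity,
                                   cfg$quantify$min_voxels_t2,
                                   cfg$quantify$min_voxels_t1,
                                   subject_id = pp$scan$id)
    tf <- cohort[[i]]$truth$template_transform
    t2_masks[[i]] <- to_template(seg$t2_mask, tf, target, method = "nearest")
    t2_vols[[i]] <- to_template(pp$scan$t2, tf, target)
  }
  list(inventories = do.call(rbind, inv),
       freq_supra = lesion_frequency_map(t2_masks, atlas_target$masks$supratentorial),
       freq_infra = lesion_frequency_map(t2_masks, atlas_target$masks$infratentorial),
       avg_t2 = average_anatomy(t2_vols),
       model = model)
}

#' Run the full phantom-cohort analysis pipeline
#'
#' Generates a pediatric and an adult phantom cohort, preprocesses every
#' subject onto the common adult-protocol grid, fits one tissue model per
#' protocol group, segments T2 and T1 lesions, builds regional inventories,
#' lesion frequency maps and average anatomies, and produces the group
#' comparison report. Deterministic given the configured seed.
#'
#' @param cfg a [pipeline_config()].
#' @return list with `report`, per-group `inventories`, frequency maps and
#'   average anatomies; artifacts written under `cfg$out_dir` when set.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  target <- adult_analysis_geometry(cfg)
  atlas_target <- build_region_atlas(target$dim, target$voxdim,
                                     cfg$quantify$periventricular_mm)
  ped <- process_group("pediatric", cfg, target, atlas_target)
  adu <- process_group("adult", cfg, target, atlas_target)
  report <- group_report(ped$inventories, adu$inventories,
                         alpha = cfg$stats$alpha,
                         log_constant = cfg$stats$log_constant)
  res <- list(report = report,
              pediatric = ped, adult = adu, config = cfg)
  if (!is.null(cfg$out_dir)) write_pipeline_artifacts(res, cfg$out_dir)
  res
}
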