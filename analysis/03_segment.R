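#!/usr/bin/env Rscript
# Stage 3 — lesion segmentation.
#
# Fits one multispectral tissue model per protocol group (on a dedicated
# training phantom), segments every subject's T2 lesions (Bayesian
# supratentorially, relative-threshold infratentorially) and T1
# hypointensities (85% / 83% of surrounding NAWM), and scores the masks
# against the phantom ground truth. Also reproduces the cross-protocol T1
# threshold calibration on ten dual-scanned synthetic subjects. Masks and
# normalized T2 volumes go to scratch/ for stage 4.

source("analysis/00_config.R")

target <- lesionquant:::adult_analysis_geometry(CFG)
atlas <- build_region_atlas(target$dim, target$voxdim,
                            CFG$quantify$periventricular_mm)
index <- list()
quality <- list()
for (group in c("pediatric", "adult")) {
  cohort <- make_cohort(group)
  train_spec <- phantom_spec(CFG$protocols[[group]],
                             n_lesions_by_region = c(supratentorial = 10L,
                                                     cerebellum = 2L, pons = 1L),
                             t1_core_fraction = CFG$phantom$t1_core_fraction,
                             bias_field_amplitude = CFG$phantom$bias_field_amplitude,
                             seed = group_seed(group) + 1L)
  train_pp <- preprocess_subject(
    generate_subject(train_spec, id = paste0(group, "-train")),
    CFG, target, atlas)
  tv <- lesionquant:::training_voxels(train_pp)
  model <- fit_tissue_model(tv$features, tv$labels,
                            min_per_class = CFG$segment$min_lesion_train)
  for (s in cohort) {
    pp <- preprocess_subject(s, CFG, target, atlas)
    seg <- segment_subject(pp, model, CFG)
    truth2 <- resample_to_grid(s$truth$t2_lesion_mask, target, method = "nearest")
    quality[[length(quality) + 1]] <- data.frame(
      group = group, subject = pp$scan$id,
      dice_t2 = dice_coefficient(seg$t2_mask, truth2),
      t2lv_cm3 = sum(seg$t2_mask) * voxel_volume_mm3(seg$t2_mask) / 1000,
      t1lv_cm3 = sum(seg$t1_mask) * voxel_volume_mm3(seg$t1_mask) / 1000)
    base <- file.path(SCRATCH_DIR, "masks", pp$scan$id)
    write_volume_nifti(seg$t2_mask, paste0(base, "_t2mask.nii.gz"))
    write_volume_nifti(seg$t1_mask, paste0(base, "_t1mask.nii.gz"))
    write_volume_nifti(pp$scan$t2, paste0(base, "_t2norm.nii.gz"))
    index[[length(index) + 1]] <- data.frame(group = group,
                                             subject = pp$scan$id)
  }
}
q <- do.call(rbind, quality)
write.csv(q, file.path(RESULTS_DIR, "segmentation_quality.csv"), row.names = FALSE)
write.csv(do.call(rbind, index), file.path(SCRATCH_DIR, "masks", "index.csv"),
          row.names = FALSE)
cat(sprintf("median T2 Dice: pediatric %.3f, adult %.3f\n",
            median(q$dice_t2[q$group == "pediatric"]),
            median(q$dice_t2[q$group == "adult"])))

# threshold calibration across the two protocols
pairs <- generate_calibration_pairs(10, seed = MASTER_SEED + 7)
cal <- calibrate_t1_threshold(pairs, reference_fraction = 0.85)
cat(sprintf("calibrated adult T1 fraction: %.4f (|median volume diff| %.4f cm^3)\n",
            cal$fraction, cal$discrepancy_cm3))
write.csv(cal$curve, file.path(RESULTS_DIR, "t1_calibration_curve.csv"),
          row.names = FALSE)
cat("wrote", file.path(RESULTS_DIR, "segmentation_quality.csv"), "and",
    file.path(RESULTS_DIR, "t1_calibration_curve.csv"), "\n")
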