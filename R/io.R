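#' Write a `vol3d` as NIfTI
#' @param vol a `vol3d`.
#' @param path output path (.nii or .nii.gz).
#' @export
write_volume_nifti <- function(vol, path) {
  img <- RNifti::asNifti(unclass(vol))
  RNifti::pixdim(img) <- voxdim(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a `vol3d`
#' @param path NIfTI path.
#' @param origin optional world origin (default: centred field of view).
#' @export
read_volume_nifti <- function(path, origin = NULL) {
  img <- RNifti::readNifti(path)
  # header pixdims are single precision; snap to sub-nanometre digits
  vol3d(array(as.numeric(img), dim(img)[1:3]),
        round(RNifti::pixdim(img)[1:3], 6), origin)
}

#' Serialize a fitted object to JSON
#'
#' Handles `normalization_map`, `rigid_transform` and `tissue_model`.
#' @param x object.
#' @param path output path.
#' @export
write_model_json <- function(x, path) {
  obj <- if (inherits(x, "tissue_model")) {
    lapply(unclass(x), function(cl)
      list(mean = cl$mean, cov = as.vector(cl$cov), prior = cl$prior))
  } else unclass(x)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$report, file.path(out_dir, "group_report.csv"),
                   row.names = FALSE)
  utils::write.csv(res$pediatric$inventories,
                   file.path(out_dir, "inventories_pediatric.csv"),
                   row.names = FALSE)
  utils::write.csv(res$adult$inventories,
                   file.path(out_dir, "inventories_adult.csv"),
                   row.names = FALSE)
  for (g in c("pediatric", "adult")) {
    write_volume_nifti(res[[g]]$freq_supra,
                       file.path(out_dir, paste0("freq_supratentorial_", g, ".nii.gz")))
    write_volume_nifti(res[[g]]$freq_infra,
                       file.path(out_dir, paste0("freq_infratentorial_", g, ".nii.gz")))
    write_volume_nifti(res[[g]]$avg_t2,
                       file.path(out_dir, paste0("average_t2_", g, ".nii.gz")))
  }
  invisible(out_dir)
}
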