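#' Fit a multivariate Gaussian tissue model
#'
#' Maximum-likelihood Gaussian per class over (PD, T2, T1) feature vectors,
#' with class priors equal to the sample fractions. Near-singular class
#' covariances are ridge-regularised on the diagonal.
#'
#' @param features n x 3 numeric matrix of voxel intensities (columns PD, T2,
#'   T1).
#' @param labels length-n class labels; must include "lesion" plus at least
#'   one other tissue class (conventionally WM, GM, CSF).
#' @param min_per_class minimum samples required per class (default 10).
#' @param ridge relative ridge added when a covariance is not positive
#'   definite.
#' @return object of class `tissue_model`: per class `mean`, `cov`, `prior`.
#' @export
fit_tissue_model <- function(features, labels, min_per_class = 10, ridge = 1e-6) {
  features <- as.matrix(features)
  stopifnot(ncol(features) == 3L, nrow(features) == length(labels))
  labels <- as.character(labels)
  classes <- unique(labels)
  n <- length(labels)
  model <- list()
  for (cl in classes) {
    x <- features[labels == cl, , drop = FALSE]
    if (nrow(x) < min_per_class)
      stop("model error: class ", cl, " has ", nrow(x),
           " samples (need >= ", min_per_class, ")")
    mu <- colMeans(x)
    sg <- stats::cov(x)
    ch <- tryCatch(chol(sg), error = function(e) NULL)
    if (is.null(ch)) {
      sg <- sg + diag(ridge * mean(diag(sg)) + 1e-12, 3)
      ch <- tryCatch(chol(sg), error = function(e) NULL)
      if (is.null(ch)) stop("model error: covariance for class ", cl,
                            " is singular even after regularization")
    }
    model[[cl]] <- list(mean = mu, cov = sg, chol = ch,
                        prior = nrow(x) / n)
  }
  structure(model, class = "tissue_model")
}

# per-class Gaussian log densities for an n x 3 feature matrix
class_log_densities <- function(model, x) {
  sapply(model, function(cl) {
    z <- forwardsolve(t(cl$chol), t(sweep(x, 2, cl$mean)))
    -0.5 * colSums(z^2) - sum(log(diag(cl$chol))) - 1.5 * log(2 * pi)
  })
}

#' Posterior lesion probabilities under a tissue model
#'
#' @param model a `tissue_model` containing a "lesion" class.
#' @param x n x 3 matrix of (PD, T2, T1) intensities.
#' @return numeric vector of P(lesion | PD, T2, T1).
#' @export
lesion_posterior <- function(model, x) {
  if (!"lesion" %in% names(model)) stop("model has no lesion class")
  ld <- class_log_densities(model, x)
  lp <- sweep(ld, 2, log(vapply(model, `[[`, numeric(1), "prior")), "+")
  mx <- apply(lp, 1, max)
  p <- exp(lp - mx)
  p[, "lesion"] / rowSums(p)
}

check_normalized <- function(scan, tol = 1) {
  if (!isTRUE(scan$normalized))
    stop("precondition error: scan '", scan$id,
         "' has not been intensity-normalized")
  m <- unclass(scan$brain_mask) > 0
  mid <- attr(scan, "norm_mid") %||% 100
  for (ctr in c("pd", "t2", "t1")) {
    med <- stats::median(scan[[ctr]][m])
    if (abs(med - mid) > tol)
      stop("precondition error: ", toupper(ctr), " landmark check failed (median ",
           signif(med, 5), ", expected ", mid, ")")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bayesian multispectral T2 lesion segmentation
#'
#' Classifies each voxel inside `region_mask` as lesion when the posterior
#' probability of the lesion class under the fitted multivariate Gaussian
#' model, `pi_L N(x; mu_L, Sigma_L) / sum_c pi_c N(x; mu_c, Sigma_c)`,
#' exceeds `posterior_threshold`. Intended for the supratentorial
#' compartment on normalized, co-registered scans.
#'
#' @param scan a normalized `subject_scan`.
#' @param model a `tissue_model` from [fit_tissue_model()].
#' @param region_mask mask restricting the classification (typically the
#'   supratentorial compartment).
#' @param posterior_threshold inclusion threshold on the lesion posterior
#'   (default 0.5, the maximum a posteriori rule for a two-way decision).
#' @return binary lesion mask as a `vol3d`.
#' @export
segment_t2_lesions <- function(scan, model, region_mask, posterior_threshold = 0.5) {
  check_normalized(scan)
  stop_if_grid_mismatch(scan$t2, region_mask, "scan and region mask")
  out <- array(0, dim(scan$t2))
  ix <- which(region_mask > 0)
  if (length(ix) && posterior_threshold < 1) {
    x <- cbind(scan$pd[ix], scan$t2[ix], scan$t1[ix])
    post <- lesion_posterior(model, x)
    out[ix] <- as.numeric(post > posterior_threshold)
  }
  with_geom(scan$t2, out)
}

#' Apply reviewer edits to an automatic lesion mask
#'
#' Replaces interactive mask editing: an edit volume coded 0 = keep,
#' 1 = add, 2 = remove is merged into the automatic segmentation.
#'
#' @param auto_mask binary mask.
#' @param edits_volume integer volume on the same grid with codes 0/1/2.
#' @export
apply_manual_edits <- function(auto_mask, edits_volume) {
  stop_if_grid_mismatch(auto_mask, edits_volume, "mask and edit volume")
  e <- unclass(edits_volume)
  if (!all(e %in% c(0, 1, 2))) stop("edit volume must contain only codes 0/1/2")
  out <- (unclass(auto_mask) > 0) * 1
  out[e == 1] <- 1
  out[e == 2] <- 0
  with_geom(auto_mask, out)
}

#' Threshold-based infratentorial T2 lesion segmentation
#'
#' The multispectral classifier is not reliable below the tentorium, where a
#' simple relative-intensity rule (followed by reviewer edits via
#' [apply_manual_edits()]) stands in: voxels whose T2 intensity exceeds a
#' configured multiple of the infratentorial WM mean are marked as lesion.
#'
#' @param scan a `subject_scan`.
#' @param infratentorial_mask nonempty compartment mask.
#' @param wm_mask WM mask; supplies the reference mean and restricts the
#'   candidate voxels (lesions live in white matter; without the restriction
#'   bright subarachnoid CSF would trigger the threshold).
#' @param config list with `multiple` (default 1.3).
#' @export
segment_infratentorial_t2 <- function(scan, infratentorial_mask, wm_mask,
                                      config = list(multiple = 1.3)) {
  stop_if_grid_mismatch(scan$t2, infratentorial_mask)
  inf_ix <- unclass(infratentorial_mask) > 0
  if (!any(inf_ix)) stop("infratentorial mask is empty")
  ref_ix <- inf_ix & unclass(wm_mask) > 0
  if (!any(ref_ix)) stop("reference error: no infratentorial WM voxels")
  ref <- mean(scan$t2[ref_ix])
  out <- (ref_ix & unclass(scan$t2) > config$multiple * ref) * 1
  with_geom(scan$t2, out)
}
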