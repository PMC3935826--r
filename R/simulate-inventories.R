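rtrunc_norm <- function(n, mean, sd, lower = 0.01) pmax(stats::rnorm(n, mean, sd), lower)

rcount <- function(n, mean, sd) {
  # nonnegative integer counts with roughly the requested mean/SD
  # (negative binomial when overdispersed, Poisson otherwise)
  v <- sd^2
  if (v > mean * 1.05) {
    size <- mean^2 / (v - mean)
    stats::rnbinom(n, size = size, mu = mean)
  } else stats::rpois(n, mean)
}

#' Cohort-level inventory distribution parameters
#'
#' Study conditions for the parametric inventory simulator, taken from the
#' published cohort summaries: regional incidence probabilities, lesion
#' volume means/SDs (cm^3, unconditional over the whole group) and lesion
#' count means/SDs for the pediatric and adult RRMS groups.
#'
#' @param group "pediatric" or "adult".
#' @return named list of distribution parameters.
#' @export
inventory_params <- function(group = c("pediatric", "adult")) {
  group <- match.arg(group)
  if (group == "pediatric") list(
    p_infra_t2 = 0.759, p_brainstem_t2 = 0.621, p_pons_t2 = 0.483,
    p_supra_t1 = 0.689, p_infra_t1 = 0.586,
    supra_t2_vol = c(8.45, 1.7), infra_t2_vol = c(4.31, 2.7),
    supra_t1_vol = c(5.5, 0.92), infra_t1_vol = c(3.7, 2.5),
    supra_t2_count = c(31.8, 38.44), infra_t2_count = c(4.1, 5.6),
    pv_fraction = 0.59)
  else list(
    p_infra_t2 = 0.434, p_brainstem_t2 = 0.267, p_pons_t2 = 0.172,
    p_supra_t1 = 0.965, p_infra_t1 = 0.233,
    supra_t2_vol = c(7.94, 1.7), infra_t2_vol = c(2.08, 2.4),
    supra_t1_vol = c(6.41, 2.1), infra_t1_vol = c(1.08, 1.9),
    supra_t2_count = c(27.3, 20.91), infra_t2_count = c(1.45, 2.3),
    pv_fraction = 0.71)
}

one_subject_inventory <- function(sid, pr) {
  sup_v2 <- rtrunc_norm(1, pr$supra_t2_vol[1], pr$supra_t2_vol[2])
  inf_present <- stats::runif(1) < pr$p_infra_t2
  inf_v2 <- if (inf_present)
    rtrunc_norm(1, pr$infra_t2_vol[1] / pr$p_infra_t2, pr$infra_t2_vol[2]) else 0
  bs_present <- inf_present && stats::runif(1) < pr$p_brainstem_t2 / pr$p_infra_t2
  bs_v2 <- if (bs_present) stats::runif(1, 0.4, 0.8) * inf_v2 else 0
  pons_present <- bs_present && stats::runif(1) < pr$p_pons_t2 / pr$p_brainstem_t2
  pons_v2 <- if (pons_present) stats::runif(1, 0.5, 0.9) * bs_v2 else 0
  mid_v2 <- if (bs_present && stats::runif(1) < 0.15)
    stats::runif(1, 0.2, 0.8) * (bs_v2 - pons_v2) else 0
  med_v2 <- bs_v2 - pons_v2 - mid_v2
  cb_v2 <- inf_v2 - bs_v2
  whole_v2 <- sup_v2 + inf_v2
  pv_v2 <- pr$pv_fraction * whole_v2 * stats::runif(1, 0.9, 1.1)
  pv_v2 <- min(pv_v2, whole_v2)

  sup_c2 <- max(1L, rcount(1, pr$supra_t2_count[1], pr$supra_t2_count[2]))
  inf_c2 <- if (inf_present)
    max(1L, rcount(1, pr$infra_t2_count[1] / pr$p_infra_t2, pr$infra_t2_count[2]))
  else 0L
  bs_c2 <- if (bs_present) max(1L, round(inf_c2 * bs_v2 / max(inf_v2, 1e-9))) else 0L
  bs_c2 <- min(bs_c2, inf_c2)
  pons_c2 <- if (pons_present) max(1L, round(bs_c2 * 0.7)) else 0L
  pons_c2 <- min(pons_c2, bs_c2)
  mid_c2 <- if (mid_v2 > 0) min(1L, bs_c2 - pons_c2) else 0L
  med_c2 <- bs_c2 - pons_c2 - mid_c2
  cb_c2 <- inf_c2 - bs_c2

  sup1_present <- stats::runif(1) < pr$p_supra_t1
  sup_v1 <- if (sup1_present)
    min(rtrunc_norm(1, pr$supra_t1_vol[1] / pr$p_supra_t1, pr$supra_t1_vol[2]), sup_v2) else 0
  inf1_present <- inf_present && stats::runif(1) < pr$p_infra_t1 / pr$p_infra_t2
  inf_v1 <- if (inf1_present)
    min(rtrunc_norm(1, pr$infra_t1_vol[1] / pr$p_infra_t1, pr$infra_t1_vol[2]), inf_v2) else 0
  whole_v1 <- sup_v1 + inf_v1
  bs_v1 <- if (inf1_present && bs_present) stats::runif(1, 0.3, 0.7) * inf_v1 else 0
  pons_v1 <- if (pons_present) min(stats::runif(1, 0.5, 0.9) * bs_v1, pons_v2) else 0
  cb_v1 <- inf_v1 - bs_v1
  pv_v1 <- min(pr$pv_fraction * whole_v1, whole_v1)
  c1 <- function(v) if (v > 0) max(1L, round(v / 0.4)) else 0L

  mk <- function(modality, region, count, vol)
    data.frame(subject_id = sid, modality = modality, region = region,
               count = as.integer(count), volume_cm3 = vol)
  rbind(
    mk("T2w", "whole_brain", sup_c2 + inf_c2, whole_v2),
    mk("T2w", "supratentorial", sup_c2, sup_v2),
    mk("T2w", "infratentorial", inf_c2, inf_v2),
    mk("T2w", "brainstem", bs_c2, bs_v2),
    mk("T2w", "midbrain", mid_c2, mid_v2),
    mk("T2w", "pons", pons_c2, pons_v2),
    mk("T2w", "medulla", med_c2, med_v2),
    mk("T2w", "cerebellum", cb_c2, cb_v2),
    mk("T2w", "periventricular", NA_integer_, pv_v2),
    mk("T2w", "non_periventricular", NA_integer_, whole_v2 - pv_v2),
    mk("T1w", "whole_brain", c1(whole_v1), whole_v1),
    mk("T1w", "supratentorial", c1(sup_v1), sup_v1),
    mk("T1w", "infratentorial", c1(inf_v1), inf_v1),
    mk("T1w", "brainstem", c1(bs_v1), bs_v1),
    mk("T1w", "midbrain", 0L, 0),
    mk("T1w", "pons", c1(pons_v1), pons_v1),
    mk("T1w", "medulla", 0L, max(bs_v1 - pons_v1, 0)),
    mk("T1w", "cerebellum", c1(cb_v1), cb_v1),
    mk("T1w", "periventricular", NA_integer_, pv_v1),
    mk("T1w", "non_periventricular", NA_integer_, whole_v1 - pv_v1))
}

#' Simulate a cohort of lesion inventories parametrically
#'
#' Draws per-subject regional lesion volumes and counts directly from
#' cohort-level distributions (no imaging), preserving the inventory's
#' additivity (whole brain = supratentorial + infratentorial, brainstem =
#' sum of its parts). Used for statistical power and calibration checks of
#' the reporting battery, where simulating full image volumes would add
#' nothing.
#'
#' @param n number of subjects.
#' @param params parameter list from [inventory_params()] (fields may be
#'   overridden).
#' @param seed RNG seed.
#' @param id_prefix subject id prefix.
#' @return long inventory data frame.
#' @export
simulate_inventories <- function(n, params = inventory_params("pediatric"),
                                 seed = 1, id_prefix = "sim") {
  set.seed(seed)
  out <- lapply(seq_len(n), function(i)
    one_subject_inventory(sprintf("%s%03d", id_prefix, i), params))
  do.call(rbind, out)
}
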