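#' Cohort phantom sampler
#'
#' Returns a sampler of per-subject [phantom_spec()]s emulating one study
#' group. Each subject draws a whole-brain T2 lesion-volume target from a
#' truncated normal with the group's published mean and SD; infratentorial
#' involvement is Bernoulli at the group's incidence, with brainstem and
#' pontine involvement nested at their conditional incidences. The target
#' volume is converted to lesion counts and radii (jittered, last radius
#' adjusted to land on the target), with subregion volumes capped at what the
#' small brainstem compartments can physically hold with the one-voxel
#' separation rule.
#'
#' @param protocol a [protocol_spec()].
#' @param mean_t2lv,sd_t2lv whole-brain T2 lesion volume distribution (cm^3);
#'   defaults 12.76 / 2.7 (pediatric) or 10.03 / 3.4 (adult).
#' @param p_infra,p_brainstem,p_pons unconditional regional incidence
#'   probabilities; defaults 0.759 / 0.621 / 0.483 (pediatric) or
#'   0.434 / 0.267 / 0.172 (adult).
#' @param infra_mean,infra_sd unconditional infratentorial T2 lesion volume
#'   (cm^3); defaults 4.31 / 2.7 (pediatric) or 2.08 / 2.4 (adult).
#' @param radius_range_supra,radius_range_infra,radius_range_cerebellum
#'   lesion radius intervals (mm); the brainstem subregions take small
#'   lesions, the cerebellum larger ones (matching the few-but-large
#'   character of infratentorial lesion loads).
#' @param t1_core_fraction,bias_field_amplitude passed to [phantom_spec()].
#' @return function(seed) -> `phantom_spec`.
#' @export
cohort_sampler <- function(protocol = protocol_spec("pediatric"),
                           mean_t2lv = NULL, sd_t2lv = NULL,
                           p_infra = NULL, p_brainstem = NULL, p_pons = NULL,
                           infra_mean = NULL, infra_sd = NULL,
                           radius_range_supra = c(2.5, 6),
                           radius_range_infra = c(2, 3.2),
                           radius_range_cerebellum = c(3, 5),
                           t1_core_fraction = 0.4,
                           bias_field_amplitude = 0.2) {
  ped <- protocol$name == "pediatric"
  mean_t2lv <- mean_t2lv %||% if (ped) 12.76 else 10.03
  sd_t2lv <- sd_t2lv %||% if (ped) 2.7 else 3.4
  p_infra <- p_infra %||% if (ped) 0.759 else 0.434
  p_brainstem <- p_brainstem %||% if (ped) 0.621 else 0.267
  p_pons <- p_pons %||% if (ped) 0.483 else 0.172
  infra_mean <- infra_mean %||% if (ped) 4.31 else 2.08
  infra_sd <- infra_sd %||% if (ped) 2.7 else 2.4
  stopifnot(p_infra > 0, p_brainstem <= p_infra, p_pons <= p_brainstem)

  radii_for_volume <- function(target_cm3, range_mm, cap = Inf) {
    target <- min(target_cm3, cap) * 1000
    radii <- numeric(0)
    acc <- 0
    vol_of <- function(r) 4 / 3 * pi * r^3
    while (acc < target) {
      r <- stats::runif(1, range_mm[1], range_mm[2])
      if (acc + vol_of(r) >= target) {
        r <- min(max((3 * (target - acc) / (4 * pi))^(1 / 3), range_mm[1]),
                 range_mm[2])
        radii <- c(radii, r)
        break
      }
      radii <- c(radii, r)
      acc <- acc + vol_of(r)
    }
    radii
  }

  function(seed) {
    set.seed(seed)
    whole <- max(stats::rnorm(1, mean_t2lv, sd_t2lv), 1.5)
    has_infra <- stats::runif(1) < p_infra
    infra <- if (has_infra)
      max(stats::rnorm(1, infra_mean / p_infra, infra_sd), 0.3) else 0
    infra <- min(infra, whole - 1, 6)   # keep some supratentorial load
    has_bs <- has_infra && stats::runif(1) < p_brainstem / p_infra
    has_pons <- has_bs && stats::runif(1) < p_pons / p_brainstem
    radii <- list()
    remaining <- infra
    if (has_pons) {
      v <- min(stats::runif(1, 0.15, 0.5), remaining)
      radii$pons <- radii_for_volume(v, radius_range_infra, cap = 0.6)
      remaining <- remaining - sum(4 / 3 * pi * radii$pons^3) / 1000
    }
    if (has_bs) {
      # midbrain or medulla lesion occasionally accompanies pontine disease
      if (stats::runif(1) < 0.3) {
        reg <- sample(c("midbrain", "medulla"), 1)
        v <- min(stats::runif(1, 0.1, 0.3), max(remaining, 0.1))
        radii[[reg]] <- radii_for_volume(v, radius_range_infra, cap = 0.35)
        remaining <- remaining - sum(4 / 3 * pi * radii[[reg]]^3) / 1000
      }
      if (!has_pons && is.null(radii$midbrain) && is.null(radii$medulla)) {
        # brainstem involvement without pons: place in midbrain or medulla
        reg <- sample(c("midbrain", "medulla"), 1)
        radii[[reg]] <- radii_for_volume(0.15, radius_range_infra, cap = 0.35)
        remaining <- remaining - sum(4 / 3 * pi * radii[[reg]]^3) / 1000
      }
    }
    if (has_infra && remaining > 0.05)
      radii$cerebellum <- radii_for_volume(remaining, radius_range_cerebellum,
                                           cap = 3.5)
    # whatever the small infratentorial compartments could not hold goes
    # back to the supratentorial target, keeping whole-brain volume on spec
    realized_infra <- sum(4 / 3 * pi * unlist(radii)^3) / 1000
    radii$supratentorial <- radii_for_volume(whole - realized_infra,
                                             radius_range_supra)
    counts <- vapply(radii, length, integer(1))
    phantom_spec(protocol = protocol,
                 n_lesions_by_region = counts,
                 lesion_radius_range_mm = range(unlist(radii)),
                 t1_core_fraction = t1_core_fraction,
                 bias_field_amplitude = bias_field_amplitude,
                 seed = seed,
                 lesion_radii_by_region = radii)
  }
}

#' Generate paired subjects scanned under both protocols
#'
#' Emulates the threshold-calibration cohort: each subject carries the same
#' lesions (identical radii, counts and core fractions) imaged once under the
#' pediatric protocol and once under the adult protocol. Ground-truth T2
#' lesion masks stand in for the reviewed lesion labels, and the WM mask
#' comes from the atlas, so the pairs feed [calibrate_t1_threshold()]
#' directly.
#'
#' @param n_pairs number of paired subjects (>= 2).
#' @param seed master seed.
#' @param n_lesions lesions per subject (supratentorial).
#' @param t1_core_fraction lesion core fraction passed to the phantoms.
#' @return list of pairs, each with elements `A` (pediatric) and `B` (adult),
#'   each carrying `t1`, `t2_lesion_mask`, `wm_mask`.
#' @export
generate_calibration_pairs <- function(n_pairs = 10, seed = 1, n_lesions = 6,
                                       t1_core_fraction = 0.4) {
  stopifnot(n_pairs >= 2)
  set.seed(seed)
  pair_seeds <- sample.int(.Machine$integer.max - 1L, n_pairs)
  protos <- list(A = protocol_spec("pediatric"), B = protocol_spec("adult"))
  atlases <- lapply(protos, function(p)
    build_region_atlas(default_grid_for(p), protocol_voxdim(p)))
  lapply(seq_len(n_pairs), function(i) {
    set.seed(pair_seeds[i])
    radii <- stats::runif(n_lesions, 3, 5.5)
    out <- lapply(c("A", "B"), function(side) {
      p <- protos[[side]]
      sp <- phantom_spec(p, n_lesions_by_region = c(supratentorial = n_lesions),
                         t1_core_fraction = t1_core_fraction,
                         seed = pair_seeds[i],
                         lesion_radii_by_region = list(supratentorial = radii))
      g <- generate_subject(sp, atlas = atlases[[side]],
                            id = sprintf("cal%02d%s", i, side))
      at <- atlases[[side]]
      list(t1 = g$scan$t1, t2_lesion_mask = g$truth$t2_lesion_mask,
           wm_mask = with_geom(at$tissue,
                               as.numeric(at$tissue == TISSUE_LABELS[["WM"]])))
    })
    names(out) <- c("A", "B")
    out
  })
}

#' Generate a cohort of phantom subjects
#'
#' Per-subject seeds are drawn deterministically from the master seed, so the
#' whole cohort reproduces bit for bit. The region atlas is built once and
#' shared.
#'
#' @param n_subjects cohort size (>= 1).
#' @param spec_sampler function(seed) -> [phantom_spec()], e.g. from
#'   [cohort_sampler()].
#' @param seed master RNG seed.
#' @param id_prefix subject id prefix.
#' @return list of per-subject lists (`scan`, `truth`, `atlas`).
#' @export
generate_cohort <- function(n_subjects, spec_sampler, seed = 1,
                            id_prefix = "subj") {
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  atlas <- NULL
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    spec <- spec_sampler(subject_seeds[i])
    if (is.null(atlas) ||
        !identical(as.integer(dim(atlas$labels)), spec$grid_shape))
      atlas <- build_region_atlas(spec$grid_shape, protocol_voxdim(spec$protocol))
    out[[i]] <- generate_subject(spec, atlas = atlas,
                                 id = sprintf("%s%03d", id_prefix, i))
  }
  out
}
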