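test_that("tissue model recovers known Gaussian parameters", {
  set.seed(8)
  n <- 10000
  mu <- list(WM = c(110, 136, 100), GM = c(118, 100, 85),
             CSF = c(155, 250, 40), lesion = c(145, 190, 75))
  X <- NULL; lab <- NULL
  for (cl in names(mu)) {
    X <- rbind(X, sweep(matrix(rnorm(3 * n, sd = 3), ncol = 3), 2, mu[[cl]], "+"))
    lab <- c(lab, rep(cl, n))
  }
  m <- fit_tissue_model(X, lab)
  for (cl in names(mu)) {
    se <- 3 / sqrt(n)
    expect_true(all(abs(m[[cl]]$mean - mu[[cl]]) < 3 * se))
    expect_equal(m[[cl]]$prior, 0.25)
  }
  # duplicating every sample leaves the fit unchanged
  m2 <- fit_tissue_model(rbind(X, X), c(lab, lab))
  for (cl in names(mu)) expect_equal(m2[[cl]]$mean, m[[cl]]$mean)
  expect_error(fit_tissue_model(X[1:5, , drop = FALSE], lab[1:5]), "model error")
})

test_that("posterior rule matches a straight-line per-voxel computation", {
  model <- lq_model()
  at <- lq_atlas()
  s <- generate_subject(phantom_spec(seed = 31), atlas = at)
  sn <- norm_scan(s, at)
  sub <- as.matrix(expand.grid(30:49, 30:49, 20:39))
  lin <- sub[, 1] + (sub[, 2] - 1) * 96 + (sub[, 3] - 1) * 96 * 96
  x <- cbind(sn$pd[lin], sn$t2[lin], sn$t1[lin])
  post <- lesion_posterior(model, x)
  # independent implementation: explicit densities via solve() and det()
  dens <- sapply(model, function(cl) {
    inv <- solve(cl$cov)
    dc <- det(cl$cov)
    apply(x, 1, function(v) {
      d <- v - cl$mean
      exp(-0.5 * drop(t(d) %*% inv %*% d)) / sqrt((2 * pi)^3 * dc) * cl$prior
    })
  })
  expect_equal(post, dens[, "lesion"] / rowSums(dens), tolerance = 1e-10)
})

test_that("supratentorial Bayesian segmentation recovers phantom lesions", {
  model <- lq_model()
  at <- lq_atlas()
  dices <- vapply(41:45, function(seed) {
    s <- generate_subject(phantom_spec(seed = seed), atlas = at)
    sn <- norm_scan(s, at)
    m <- segment_t2_lesions(sn, model, at$masks$supratentorial)
    truth <- as.numeric(s$truth$t2_lesion_mask > 0 & at$masks$supratentorial > 0)
    dice_coefficient(m, vol3d(array(truth, dim(m)), voxdim(m), vox_origin(m)))
  }, numeric(1))
  expect_gte(median(dices), 0.9)
})

test_that("lesion-free phantom yields almost no false positives", {
  model <- lq_model()
  at <- lq_atlas()
  s0 <- generate_subject(phantom_spec(seed = 30,
                                      n_lesions_by_region = integer(0)),
                         atlas = at)
  m0 <- segment_t2_lesions(norm_scan(s0, at), model, at$masks$supratentorial)
  expect_lte(sum(m0) / sum(at$brain_mask), 0.001)
})

test_that("posterior threshold 1 gives an empty mask, unnormalized scans error", {
  model <- lq_model()
  at <- lq_atlas()
  s <- generate_subject(phantom_spec(seed = 32), atlas = at)
  sn <- norm_scan(s, at)
  expect_equal(sum(segment_t2_lesions(sn, model, at$masks$supratentorial, 1.0)), 0)
  expect_error(segment_t2_lesions(s$scan, model, at$masks$supratentorial),
               "precondition error")
})

test_that("manual edits add, remove, and keep voxels", {
  m <- vol3d(array(0, c(10, 10, 5)), c(1, 1, 1))
  m[1:10, 1:10, 1] <- 1   # 100-voxel mask
  e <- vol3d(array(0, c(10, 10, 5)), c(1, 1, 1))
  expect_equal(as.numeric(apply_manual_edits(m, e)), as.numeric(m))
  e[1:5, 1, 2] <- 1       # add 5
  e[1:3, 1, 1] <- 2       # remove 3
  expect_equal(sum(apply_manual_edits(m, e)), 102)
  e2 <- vol3d(array(2, c(10, 10, 5)), c(1, 1, 1))
  expect_equal(sum(apply_manual_edits(m, e2)), 0)
  bad <- vol3d(array(0, c(5, 5, 5)), c(1, 1, 1))
  expect_error(apply_manual_edits(m, bad), "geometry error")
})

test_that("infratentorial threshold segmentation detects pontine lesions", {
  at <- lq_atlas()
  s <- generate_subject(phantom_spec(n_lesions_by_region = c(pons = 1L),
                                     lesion_radius_range_mm = c(3.5, 4.5),
                                     seed = 3), atlas = at)
  wm <- lq_wm_mask()
  m <- segment_infratentorial_t2(s$scan, at$masks$infratentorial, wm)
  expect_gte(dice_coefficient(m, s$truth$t2_lesion_mask), 0.9)
  # threshold above the intensity range
  m2 <- segment_infratentorial_t2(s$scan, at$masks$infratentorial, wm,
                                  list(multiple = 10))
  expect_equal(sum(m2), 0)
  # noiseless lesion-free infratentorium
  p0 <- protocol_spec("pediatric", noise_sigma = 0,
                      texture_sigma = c(PD = 0, T2 = 0, T1 = 0))
  s0 <- generate_subject(phantom_spec(p0, n_lesions_by_region = integer(0),
                                      seed = 2), atlas = at)
  expect_equal(sum(segment_infratentorial_t2(s0$scan, at$masks$infratentorial, wm)), 0)
})

test_that("NAWM reference returns the WM mean and falls back when degenerate", {
  at <- lq_atlas()
  wm <- lq_wm_mask()
  p0 <- protocol_spec("pediatric", noise_sigma = 0,
                      texture_sigma = c(PD = 0, T2 = 0, T1 = 0))
  s0 <- generate_subject(phantom_spec(p0, seed = 4), atlas = at)
  expect_equal(nawm_reference_intensity(s0$scan$t1, wm,
                                        s0$truth$t2_lesion_mask, 5), 100)
  # noisy textureless phantom: the ring holds thousands of voxels with iid
  # noise, so the reference sits tightly on the configured WM mean
  pn <- protocol_spec("pediatric", texture_sigma = c(PD = 0, T2 = 0, T1 = 0))
  s <- generate_subject(phantom_spec(pn, seed = 4), atlas = at)
  ref <- nawm_reference_intensity(s$scan$t1, wm, s$truth$t2_lesion_mask, 5)
  expect_lt(abs(ref - 100), 0.2)
  # no WM in the 1 mm ring around the lesion (the only other WM is a far
  # island): the global-NAWM fallback engages with a warning
  d <- c(12, 12, 12)
  t1s <- vol3d(array(90, d), c(1, 1, 1))
  les2 <- vol3d(array(0, d), c(1, 1, 1)); les2[4:6, 4:6, 4:6] <- 1
  wm2 <- vol3d(array(0, d), c(1, 1, 1)); wm2[4:6, 4:6, 4:6] <- 1
  wm2[11, 11, 11] <- 1
  t1s[11, 11, 11] <- 77
  expect_warning(ref2 <- nawm_reference_intensity(t1s, wm2, les2, ring_mm = 1),
                 "falling back")
  expect_equal(ref2, 77)
})

test_that("T1 threshold rule: inclusion at the calibrated fractions", {
  # a lesion voxel at 0.84 x NAWM: included at 0.85, excluded at 0.83
  d <- c(12, 12, 12)
  t1 <- vol3d(array(100, d), c(1, 1, 1))
  wm <- vol3d(array(1, d), c(1, 1, 1))
  les <- vol3d(array(0, d), c(1, 1, 1))
  les[6, 6, 6] <- 1
  t1[6, 6, 6] <- 84
  m85 <- segment_t1_hypointense(t1, les, wm, t1_threshold_config(0.85))
  m83 <- segment_t1_hypointense(t1, les, wm, t1_threshold_config(0.83))
  expect_equal(sum(m85), 1)
  expect_equal(sum(m83), 0)
  expect_error(t1_threshold_config(1.2), "configuration error")
  # a tiny fraction empties the mask
  m0 <- segment_t1_hypointense(t1, les, wm, t1_threshold_config(0.01))
  expect_equal(sum(m0), 0)
})

test_that("T1 mask is a subset of the T2 mask and monotone in the fraction", {
  at <- lq_atlas()
  wm <- lq_wm_mask()
  s <- generate_subject(phantom_spec(seed = 33), atlas = at)
  vols <- vapply(seq(0.7, 0.9, by = 0.05), function(f) {
    m <- segment_t1_hypointense(s$scan$t1, s$truth$t2_lesion_mask, wm,
                                t1_threshold_config(f))
    expect_true(all(as.numeric(s$truth$t2_lesion_mask)[as.numeric(m) > 0] > 0))
    sum(m)
  }, numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("T1 lesion volume recovery on default-contrast phantoms", {
  at <- lq_atlas()
  wm <- lq_wm_mask()
  errs <- vapply(51:55, function(seed) {
    s <- generate_subject(phantom_spec(seed = seed, t1_core_fraction = 0.4),
                          atlas = at)
    m <- segment_t1_hypointense(s$scan$t1, s$truth$t2_lesion_mask, wm,
                                t1_threshold_config(0.85))
    abs(sum(m) - sum(s$truth$t1_lesion_mask)) / sum(s$truth$t1_lesion_mask)
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("cross-protocol threshold calibration", {
  pairs <- lq_fixture("cal_pairs", function() generate_calibration_pairs(10, seed = 42))
  # self-calibration returns the reference fraction
  self <- lapply(pairs, function(p) list(A = p$A, B = p$A))
  cs <- calibrate_t1_threshold(self, 0.85)
  expect_lt(abs(cs$fraction - 0.85), 0.005)
  # the constructed pediatric/adult pair equates 0.85 with 0.83
  cal <- calibrate_t1_threshold(pairs, 0.85)
  expect_lt(abs(cal$fraction - 0.83), 0.005)
  expect_true(all(c("fraction", "median_diff_cm3") %in%
                  c("fraction", names(cal$curve)[2])))
  # per-subject volume curves are non-decreasing in the fraction
  md <- cal$curve$median_diff_cm3
  expect_true(all(diff(md) >= 0))
  # non-overlapping volume curves: B has no T1 signal below any threshold
  dark <- lapply(pairs[1:2], function(p) {
    B <- p$B
    B$t1 <- vol3d(array(1000, dim(B$t1)), voxdim(B$t1), vox_origin(B$t1))
    list(A = p$A, B = B)
  })
  expect_error(calibrate_t1_threshold(dark, 0.85), "calibration error")
})
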