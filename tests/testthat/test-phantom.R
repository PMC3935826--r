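test_that("atlas base labels partition the brain and derived masks add up", {
  at <- lq_atlas()
  lab <- as.integer(at$labels)
  brain <- as.numeric(at$brain_mask) > 0
  expect_true(all((lab > 0) == brain))
  # every brain voxel carries exactly one base label; supra + infra = brain
  # minus ventricles
  expect_equal(sum(at$masks$supratentorial) + sum(at$masks$infratentorial) +
                 sum(at$masks$ventricles), sum(brain))
  expect_equal(sum(at$masks$brainstem),
               sum(at$masks$midbrain) + sum(at$masks$pons) + sum(at$masks$medulla))
  expect_equal(sum(at$masks$infratentorial),
               sum(at$masks$brainstem) + sum(at$masks$cerebellum))
  expect_equal(sum(at$masks$supratentorial * at$masks$infratentorial), 0)
  expect_equal(sum(at$masks$periventricular) + sum(at$masks$non_periventricular),
               sum(brain))
})

test_that("periventricular mask at distance zero is the ventricle mask", {
  at0 <- build_region_atlas(periventricular_mm = 0)
  expect_equal(as.numeric(at0$masks$periventricular),
               as.numeric(at0$masks$ventricles))
})

test_that("a too-small grid raises a sizing error", {
  expect_error(build_region_atlas(c(20L, 20L, 10L), c(0.98, 0.98, 2)),
               "sizing error")
})

test_that("noiseless lesion-free phantom has exactly constant tissue classes", {
  p <- protocol_spec("pediatric", noise_sigma = 0,
                     texture_sigma = c(PD = 0, T2 = 0, T1 = 0))
  s <- generate_subject(phantom_spec(p, n_lesions_by_region = integer(0),
                                     bias_field_amplitude = 0, seed = 1),
                        atlas = lq_atlas())
  at <- lq_atlas()
  for (cls in c("WM", "GM", "CSF")) {
    ix <- as.integer(at$tissue) == TISSUE_LABELS[[cls]]
    expect_equal(unique(s$scan$t2[ix]), p$tissue_means[cls, "T2"])
    expect_equal(unique(s$scan$pd[ix]), p$tissue_means[cls, "PD"])
    expect_equal(unique(s$scan$t1[ix]), p$tissue_means[cls, "T1"])
  }
})

test_that("lesion placement respects the requested region", {
  s <- generate_subject(phantom_spec(n_lesions_by_region = c(pons = 1L),
                                     lesion_radius_range_mm = c(3.5, 4.5),
                                     seed = 3),
                        atlas = lq_atlas())
  expect_equal(s$truth$lesions$region, "pons")
  les <- as.numeric(s$truth$t2_lesion_mask) > 0
  expect_true(all(as.numeric(lq_atlas()$masks$pons)[les] > 0))
})

test_that("identical spec and seed reproduce the subject bit for bit", {
  sp <- phantom_spec(seed = 7)
  a <- generate_subject(sp, atlas = lq_atlas())
  b <- generate_subject(sp, atlas = lq_atlas())
  expect_identical(as.numeric(a$scan$t2), as.numeric(b$scan$t2))
  expect_identical(as.numeric(a$truth$t1_lesion_mask),
                   as.numeric(b$truth$t1_lesion_mask))
})

test_that("ground truth bookkeeping: T1 subset of T2, voxel counts add up", {
  for (seed in c(5, 23)) {
    s <- generate_subject(phantom_spec(seed = seed), atlas = lq_atlas())
    t1 <- as.numeric(s$truth$t1_lesion_mask) > 0
    t2 <- as.numeric(s$truth$t2_lesion_mask) > 0
    expect_true(all(t2[t1]))
    expect_equal(sum(s$truth$lesions$n_voxels), sum(t2))
    expect_equal(sum(s$truth$lesions$volume_mm3),
                 sum(t2) * voxel_volume_mm3(s$truth$t2_lesion_mask))
  }
})

test_that("unplaceable lesions raise a placement error", {
  expect_error(
    generate_subject(phantom_spec(n_lesions_by_region = c(medulla = 30L),
                                  lesion_radius_range_mm = c(3, 3.2), seed = 2),
                     atlas = lq_atlas()),
    "placement error")
})

test_that("cohort generation is deterministic and sized correctly", {
  sampler <- cohort_sampler(protocol_spec("pediatric"),
                            bias_field_amplitude = 0)
  one <- generate_cohort(1, sampler, seed = 4)
  expect_length(one, 1)
  a <- generate_cohort(2, sampler, seed = 4)
  b <- generate_cohort(2, sampler, seed = 4)
  expect_identical(as.numeric(a[[2]]$scan$t2), as.numeric(b[[2]]$scan$t2))
})

test_that("cohort infratentorial incidence matches the generating probability", {
  sampler <- cohort_sampler(protocol_spec("pediatric"),
                            bias_field_amplitude = 0)
  coh <- generate_cohort(29, sampler, seed = 11)
  has_infra <- vapply(coh, function(s)
    any(s$truth$lesions$region != "supratentorial"), logical(1))
  # binomial 95% CI for p = 0.759 at n = 29
  ci <- qbinom(c(0.025, 0.975), 29, 0.759) / 29
  expect_gte(mean(has_infra), ci[1])
  expect_lte(mean(has_infra), ci[2])
})

test_that("cohort whole-brain T2 lesion volume hits the configured target", {
  sampler <- cohort_sampler(protocol_spec("pediatric"),
                            bias_field_amplitude = 0)
  coh <- generate_cohort(50, sampler, seed = 12)
  t2lv <- vapply(coh, function(s) sum(s$truth$lesions$volume_mm3) / 1000,
                 numeric(1))
  se <- sd(t2lv) / sqrt(length(t2lv))
  expect_lt(abs(mean(t2lv) - 12.76), 3 * se)
})
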