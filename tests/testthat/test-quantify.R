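test_that("component labeling agrees with an independent flood-fill oracle", {
  set.seed(17)
  for (rep in 1:20) {
    m <- array(as.numeric(runif(20^3) < 0.1), c(20, 20, 20))
    for (conn in c(6, 18, 26)) {
      lb <- label_lesions(m, conn)
      fl <- flood_label(m, conn)
      expect_equal(length(lb$sizes), max(fl))
      expect_true(same_partition(unclass(lb$labels), fl, which(m > 0)))
    }
  }
})

test_that("clusters separated by one empty voxel are distinct lesions", {
  m <- array(0, c(10, 10, 10))
  m[2:3, 2:3, 2] <- 1
  m[2:3, 2:3, 4] <- 1   # one empty plane between
  expect_length(label_lesions(m)$sizes, 2)
  m2 <- array(0, c(10, 10, 10))
  m2[2:3, 2:3, 2:3] <- 1
  m2[4, 4, 4] <- 1      # corner-touching: one lesion under 26-connectivity
  expect_length(label_lesions(m2, 26)$sizes, 1)
  expect_length(label_lesions(m2, 6)$sizes, 2)
  expect_length(label_lesions(array(0, c(5, 5, 5)))$sizes, 0)
  expect_error(label_lesions(array(2, c(3, 3, 3))), "domain error")
})

test_that("minimum size filter drops small components from count and volume", {
  m <- array(0, c(20, 20, 3))
  m[1:2, 1, 1] <- 1      # size 2
  m[5:7, 1, 1] <- 1      # size 3
  m[10:14, 1, 1] <- 1    # size 5
  comp <- label_lesions(m)
  f <- filter_min_size(comp, 3)
  expect_length(f$sizes, 2)
  expect_equal(sum(f$sizes), 8)
  expect_equal(sort(unique(as.integer(f$labels[f$labels > 0]))), 1:2)
  expect_identical(filter_min_size(comp, 1)$sizes, comp$sizes)
  expect_length(filter_min_size(label_lesions(array(diag(1, 5)[, , drop = FALSE],
                                                    c(5, 5, 1)), 6), 3)$sizes, 0)
  expect_error(filter_min_size(comp, 0), "configuration error")
})

test_that("inventory equals ground truth when fed ground-truth masks", {
  at <- lq_atlas()
  s <- generate_subject(
    phantom_spec(seed = 21,
                 n_lesions_by_region = c(supratentorial = 6L, pons = 1L,
                                         cerebellum = 2L, midbrain = 1L)),
    atlas = at)
  inv <- regional_inventory(s$truth$t2_lesion_mask, s$truth$t1_lesion_mask, at,
                            subject_id = "s21")
  cnt <- function(r) inv$count[inv$region == r & inv$modality == "T2w"]
  truth_counts <- table(factor(s$truth$lesions$region,
                               levels = c("supratentorial", "cerebellum",
                                          "midbrain", "pons", "medulla")))
  expect_equal(cnt("supratentorial"), unname(truth_counts["supratentorial"]))
  expect_equal(cnt("pons"), unname(truth_counts["pons"]))
  expect_equal(cnt("cerebellum"), unname(truth_counts["cerebellum"]))
  expect_equal(cnt("whole_brain"), nrow(s$truth$lesions))
  vol <- function(r) inv$volume_cm3[inv$region == r & inv$modality == "T2w"]
  expect_equal(vol("whole_brain"), sum(s$truth$lesions$volume_mm3) / 1000)
  # additivity at machine precision
  expect_equal(vol("supratentorial") + vol("infratentorial"), vol("whole_brain"))
  expect_equal(vol("brainstem"), vol("midbrain") + vol("pons") + vol("medulla"))
  expect_equal(vol("periventricular") + vol("non_periventricular"),
               vol("whole_brain"))
  expect_equal(cnt("whole_brain"), cnt("supratentorial") + cnt("infratentorial"))
})

test_that("volume conversion uses the voxel volume in cubic mm", {
  # 100 voxels at 0.98 x 0.98 x 3 mm = 0.28812 cm^3
  at3 <- lq_fixture("atlas3", function()
    build_region_atlas(c(96L, 96L, 40L), c(0.98, 0.98, 3)))
  wm <- which(as.integer(at3$tissue) == 1 &
              as.integer(at3$labels) == REGION_LABELS[["supratentorial"]])
  m <- array(0, dim(at3$labels)); m[wm[1:100]] <- 1
  mv <- vol3d(m, c(0.98, 0.98, 3))
  inv <- regional_inventory(mv, vol3d(array(0, dim(m)), c(0.98, 0.98, 3)), at3)
  expect_equal(inv$volume_cm3[inv$region == "whole_brain" & inv$modality == "T2w"],
               100 * 2.8812 / 1000)
})

test_that("a lesion straddling the tentorium is counted once, by voxel majority", {
  at <- lq_atlas()
  lab <- as.integer(at$labels)
  d <- dim(at$labels)
  # find a column crossing the tentorium inside the brainstem footprint
  zs <- which(apply(array(lab, d), 3, function(sl) any(sl == REGION_LABELS[["pons"]] |
                                                       sl == REGION_LABELS[["midbrain"]])))
  # boundary: last infratentorial slice and first supratentorial above it
  ztop <- max(which(apply(array(lab, d), 3, function(sl)
    any(sl == REGION_LABELS[["midbrain"]]))))
  col <- which(array(lab, d)[, , ztop] == REGION_LABELS[["midbrain"]] &
               array(lab, d)[, , ztop + 1] == REGION_LABELS[["supratentorial"]],
               arr.ind = TRUE)[1, ]
  m <- array(0, d)
  m[col[1], col[2], (ztop - 1):ztop] <- 1       # 2 voxels infratentorial
  m[col[1], col[2], (ztop + 1):(ztop + 3)] <- 1 # 3 voxels supratentorial
  mv <- vol3d(m, voxdim(at$labels), vox_origin(at$labels))
  inv <- regional_inventory(mv, vol3d(array(0, d), voxdim(mv), vox_origin(mv)), at)
  cnt <- function(r) inv$count[inv$region == r & inv$modality == "T2w"]
  vol <- function(r) inv$volume_cm3[inv$region == r & inv$modality == "T2w"]
  expect_equal(cnt("whole_brain"), 1)
  expect_equal(cnt("supratentorial"), 1)  # 3 of 5 voxels above the tentorium
  expect_equal(cnt("infratentorial"), 0)
  expect_equal(vol("supratentorial"), 3 * voxel_volume_mm3(mv) / 1000)
  expect_equal(vol("infratentorial"), 2 * voxel_volume_mm3(mv) / 1000)
})

test_that("template transform: identity no-op, translation shift, round-trip", {
  at <- lq_atlas()
  s <- generate_subject(phantom_spec(seed = 22), atlas = at)
  m <- s$truth$t2_lesion_mask
  expect_identical(as.numeric(to_template(m, diag(4))), as.numeric(m))
  # pure translation by exactly two in-plane voxels
  tr <- diag(4); tr[1, 4] <- 2 * 0.98
  shifted <- to_template(m, tr, method = "nearest")
  expect_equal(sum(shifted), sum(m) - sum(m[(dim(m)[1] - 1):dim(m)[1], , ]))
  expect_equal(as.numeric(shifted[3:96, , ]), as.numeric(m[1:94, , ]))
  # invertible affine round trip keeps Dice high for a >=100 voxel mask
  A <- diag(4)
  A[1:3, 1:3] <- rotation_scale <- diag(c(1.03, 0.98, 1)) %*%
    matrix(c(cos(0.05), sin(0.05), 0, -sin(0.05), cos(0.05), 0, 0, 0, 1), 3)
  A[1:3, 4] <- c(1.7, -2.2, 0.9)
  fwd <- to_template(m, A, method = "nearest")
  back <- to_template(fwd, solve(A), method = "nearest")
  expect_gte(dice_coefficient(m, back), 0.95)
  expect_error(to_template(m, NULL), "configuration error")
})

test_that("lesion frequency maps average subject masks over a compartment", {
  d <- c(10, 10, 4)
  comp <- vol3d(array(1, d), c(1, 1, 1))
  m1 <- vol3d(array(0, d), c(1, 1, 1)); m1[2:3, 2, 1] <- 1
  m2 <- vol3d(array(0, d), c(1, 1, 1)); m2[3:4, 2, 1] <- 1
  expect_equal(as.numeric(lesion_frequency_map(list(m1), comp)),
               as.numeric(m1))
  fm <- lesion_frequency_map(list(m1, m2), comp)
  expect_equal(fm[3, 2, 1], 1)    # both subjects lesioned here
  expect_equal(fm[2, 2, 1], 0.5)  # only subject 1
  expect_equal(fm[4, 2, 1], 0.5)  # only subject 2
  expect_equal(sort(unique(as.numeric(fm))), c(0, 0.5, 1))
  # conservation: sum(map) * n = total subject-lesion voxel incidences
  expect_equal(sum(fm) * 2, sum(m1) + sum(m2))
  expect_error(lesion_frequency_map(list(), comp), "domain error")
  # values clipped to the compartment
  comp2 <- vol3d(array(0, d), c(1, 1, 1)); comp2[2, 2, 1] <- 1
  expect_equal(sum(lesion_frequency_map(list(m1, m2), comp2) > 0), 1)
})

test_that("average anatomy is the voxelwise mean", {
  d <- c(8, 8, 2)
  a <- vol3d(array(0, d), c(1, 1, 1))
  b <- vol3d(array(10, d), c(1, 1, 1))
  expect_equal(unique(as.numeric(average_anatomy(list(a, b)))), 5)
  expect_equal(as.numeric(average_anatomy(list(b))), as.numeric(b))
  set.seed(9)
  vols <- lapply(1:4, function(i) vol3d(array(rnorm(prod(d)), d), c(1, 1, 1)))
  avg <- average_anatomy(vols)
  brute <- (as.numeric(vols[[1]]) + as.numeric(vols[[2]]) +
            as.numeric(vols[[3]]) + as.numeric(vols[[4]])) / 4
  expect_equal(as.numeric(avg), brute)
})
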