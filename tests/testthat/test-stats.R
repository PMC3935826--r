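test_that("log-shift transform: closed forms and monotonicity", {
  expect_equal(log_shift_transform(0, 1), 0)
  expect_equal(log_shift_transform(c(0, exp(1) - 1), 1), c(0, 1))
  set.seed(1)
  x <- rexp(50)
  expect_equal(rank(log_shift_transform(x, 0.5)), rank(x))
  expect_error(log_shift_transform(-2, 1), "domain error")
})

test_that("t-test conventions: identical samples, degenerate inputs", {
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  r <- two_sample_t(c(5, 5, 5), c(5, 5, 5))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_error(two_sample_t(c(5, 5), c(7, 7)), "degenerate")
  # matches stats::t.test
  set.seed(2); a <- rnorm(20); b <- rnorm(20, 0.5)
  expect_equal(two_sample_t(a, b)$p, t.test(a, b, var.equal = TRUE)$p.value)
  expect_equal(two_sample_t(a, b, equal_variance = FALSE)$p, t.test(a, b)$p.value)
})

test_that("Mann-Whitney: exact enumeration, exact distribution, ties", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1 / 3)   # 2 of the 6 arrangements are as extreme
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(mann_whitney_u(rep(4, 5), rep(4, 6))$p, 1)
  # tie-free medium samples match the exact wilcox.test
  set.seed(3); a <- rnorm(29); b <- rnorm(29)
  expect_equal(mann_whitney_u(a, b)$p, wilcox.test(a, b, exact = TRUE)$p.value)
  # tied large-ish samples: normal approximation with tie correction
  set.seed(4); ta <- sample(1:5, 30, TRUE); tb <- sample(1:5, 30, TRUE)
  expect_equal(mann_whitney_u(ta, tb)$p,
               wilcox.test(ta, tb, exact = FALSE, correct = TRUE)$p.value)
  # a monotone transform cannot change the decision
  expect_equal(mann_whitney_u(log_shift_transform(abs(a), 1),
                              log_shift_transform(abs(b), 1))$p,
               mann_whitney_u(abs(a), abs(b))$p)
})

test_that("Fisher's exact test: conventions and cross-checks", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)
  # group-size matching table reported for the two cohorts
  sex <- matrix(c(23, 6, 21, 8), 2, byrow = TRUE)
  expect_equal(round(fisher_exact_2x2(sex)$p, 2), 0.76)
  # transpose symmetry and agreement with both oracles on random tables
  set.seed(5)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8), 2)
    p <- fisher_exact_2x2(tab)$p
    expect_equal(p, fisher_oracle(tab), tolerance = 1e-12)
    expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-9)
    expect_equal(p, fisher_exact_2x2(t(tab))$p, tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "domain error")
  expect_equal(fisher_exact_2x2(matrix(c(0, 3, 0, 4), 2))$p, 1)
})

test_that("type-I error of both tests is near nominal under the null", {
  set.seed(6)
  R <- 3000
  pt <- numeric(R); pm <- numeric(R)
  for (r in 1:R) {
    x <- rnorm(29); y <- rnorm(29)
    pt[r] <- two_sample_t(x, y)$p
    pm[r] <- mann_whitney_u(x, y)$p
  }
  mc <- 3 * sqrt(0.05 * 0.95 / R)
  expect_lt(abs(mean(pt < 0.05) - 0.05), 0.005 + mc)
  expect_lt(abs(mean(pm < 0.05) - 0.05), 0.005 + mc)
})

test_that("incidence tables count lesion-positive subjects per group", {
  i1 <- simulate_inventories(12, inventory_params("pediatric"), seed = 7, "p")
  i2 <- simulate_inventories(15, inventory_params("adult"), seed = 8, "a")
  tab <- incidence_table(i1, i2, "infratentorial", "T2w")
  expect_equal(rowSums(tab), c(group1 = 12, group2 = 15))
  expect_true(all(tab >= 0))
  lesion_free <- simulate_inventories(5, inventory_params("adult"), seed = 9, "z")
  lesion_free$count <- 0L
  tab0 <- incidence_table(lesion_free, lesion_free, "pons", "T2w")
  expect_equal(as.vector(tab0), c(0, 0, 5, 5))
  expect_error(incidence_table(i1, i2, "thalamus", "T2w"), "key error")
})

test_that("group incidence difference at the published rates is detectable", {
  # pediatric 75.9% vs adult 43.4% infratentorial incidence, n = 29 + 29:
  # Fisher's exact test rejects in the majority of replicates
  set.seed(10)
  hits <- 0
  for (r in 1:200) {
    a <- rbinom(1, 29, 0.759); b <- rbinom(1, 29, 0.434)
    tab <- matrix(c(a, 29 - a, b, 29 - b), 2, byrow = TRUE)
    if (fisher_exact_2x2(tab)$p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 200, 0.5)
})

test_that("identical cohorts produce an all-null report of schema length", {
  inv <- simulate_inventories(10, inventory_params("pediatric"), seed = 11, "s")
  rep <- group_report(inv, inv)
  expect_equal(nrow(rep), nrow(report_schema()))
  expect_true(all(rep$p[!is.na(rep$p)] == 1))
  expect_true(!any(rep$significant))
  expect_error(group_report(inv[inv$region != "pons", ], inv), "report error")
})

test_that("an infratentorial volume difference is flagged with high probability", {
  mkp <- function(m, s) {
    p <- inventory_params("pediatric")
    p$p_infra_t2 <- 1; p$p_brainstem_t2 <- 0.818; p$p_pons_t2 <- 0.636
    p$infra_t2_vol <- c(m, s)
    p
  }
  p1 <- mkp(4.31, 2.7); p2 <- mkp(2.08, 2.4)
  infra_hit <- 0; supra_hit <- 0
  n_seeds <- 60
  for (sd in seq_len(n_seeds)) {
    i1 <- simulate_inventories(29, p1, seed = 1000 + sd, id_prefix = "a")
    i2 <- simulate_inventories(29, p2, seed = 5000 + sd, id_prefix = "b")
    rep <- group_report(i1, i2)
    infra_hit <- infra_hit +
      rep$significant[rep$variable == "infratentorial T2w volume"]
    supra_hit <- supra_hit +
      rep$significant[rep$variable == "supratentorial T2w volume"]
  }
  # detection well above chance at the published effect size (power is
  # capped below ~0.85 by the zero-truncation of volumes); the unchanged
  # supratentorial distribution stays at the nominal false-positive rate
  expect_gte(infra_hit / n_seeds, 0.70)
  expect_lte(supra_hit / n_seeds, 0.15)
})
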