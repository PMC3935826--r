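#' Log-shift transform for skewed nonnegative variables
#'
#' `log(value + constant)`, applied before parametric testing of lesion
#' volumes to better approximate normality. Strictly monotone, so rank-based
#' decisions are unaffected.
#'
#' @param values numeric vector.
#' @param constant positive shift (default 1, in the units of `values`).
#' @export
log_shift_transform <- function(values, constant = 1) {
  if (any(values + constant <= 0))
    stop("domain error: value + constant must be positive")
  log(values + constant)
}

#' Two-sample Student's t-test
#'
#' Pooled-variance Student's t by default; Welch via `equal_variance =
#' FALSE`. Two identical constant samples return t = 0, p = 1 by convention;
#' constant samples with different means are a degenerate input.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param equal_variance pooled (TRUE, default) or Welch.
#' @return list with `statistic` (t), `df`, `p` (two-sided).
#' @export
two_sample_t <- function(a, b, equal_variance = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, df = length(a) + length(b) - 2, p = 1))
    stop("degenerate input: both groups constant with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = equal_variance)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

mw_u_statistic <- function(a, b) {
  r <- rank(c(a, b))   # midranks for ties
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test
#'
#' U from rank sums with midranks for ties. For small samples
#' (n1 + n2 <= `exact_max`) the two-sided p is computed by exact enumeration
#' of all group assignments (valid under ties as well); for larger tie-free
#' samples up to 50 per group the exact null distribution of U is used (the
#' convention of `wilcox.test`, which keeps the test's size close to nominal
#' where the continuity-corrected normal approximation is conservative);
#' otherwise the normal approximation with tie correction and continuity
#' correction applies. The two-sided exact p is the probability of a U at
#' least as far from its null mean n1 n2 / 2 as observed. All values
#' identical gives p = 1.
#'
#' @param a,b numeric vectors (each n >= 1).
#' @param exact_max combined size at or below which enumeration is used.
#' @return list with `statistic` (U for sample `a`), `p`, `method`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 12) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  n1 <- length(a); n2 <- length(b)
  u <- mw_u_statistic(a, b)
  mu <- n1 * n2 / 2
  pool <- c(a, b)
  if (length(unique(pool)) == 1L)
    return(list(statistic = u, p = 1, method = "degenerate"))
  has_ties <- anyDuplicated(pool) > 0
  if (n1 + n2 <= exact_max) {
    picks <- utils::combn(n1 + n2, n1)
    r <- rank(pool)
    us <- apply(picks, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    return(list(statistic = u, p = p, method = "exact"))
  }
  if (!has_ties && n1 <= 50 && n2 <= 50) {
    p <- min(1, 2 * min(stats::pwilcox(u, n1, n2),
                        1 - stats::pwilcox(u - 1, n1, n2)))
    return(list(statistic = u, p = p, method = "exact-distribution"))
  }
  n <- n1 + n2
  ties <- table(pool)
  tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tie_corr))
  z <- (u - mu - sign(u - mu) * 0.5) / sigma
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = u, p = p, method = "normal")
}

#' Fisher's exact test for a 2 x 2 table (two-sided)
#'
#' Point-probability convention: the two-sided p sums the hypergeometric
#' probabilities of every table with the same margins whose point probability
#' does not exceed the observed table's (within a 1e-7 relative tolerance
#' absorbing floating-point ties).
#'
#' @param table 2 x 2 matrix of nonnegative integer counts, rows = groups,
#'   columns = with/without.
#' @return list with `p` and `odds_ratio` (sample).
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)))
  if (any(table < 0)) stop("domain error: negative counts")
  if (any(table != round(table))) stop("domain error: counts must be integers")
  a <- table[1, 1]; b <- table[1, 2]; cc <- table[2, 1]; dd <- table[2, 2]
  n1 <- a + b; n2 <- cc + dd; K <- a + cc
  if (n1 + n2 == 0) stop("domain error: empty table")
  if (n1 == 0 || n2 == 0 || K == 0 || K == n1 + n2)
    return(list(p = 1, odds_ratio = NA_real_))
  ks <- max(0, K - n2):min(n1, K)
  probs <- stats::dhyper(ks, n1, n2, K)
  p_obs <- stats::dhyper(a, n1, n2, K)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  if (1 - p < 1e-12) p <- 1   # full-support sums accumulate to 1 - epsilon
  or <- if (b * cc > 0) (a * dd) / (b * cc) else Inf
  list(p = p, odds_ratio = or)
}

inv_values <- function(inventories, region, modality,
                       what = c("volume_cm3", "count")) {
  what <- match.arg(what)
  sel <- inventories$region == region & inventories$modality == modality
  if (!any(sel)) stop("key error: region '", region, "' / modality '",
                      modality, "' absent from inventory")
  x <- inventories[sel, ]
  x <- x[order(x$subject_id), ]
  stats::setNames(x[[what]], x$subject_id)
}

#' Lesion incidence contingency table for two groups
#'
#' @param inventories_g1,inventories_g2 long inventory data frames (rows:
#'   subject x region x modality), e.g. rbind of [regional_inventory()]
#'   outputs.
#' @param region,modality which cell of the inventory defines "having a
#'   lesion" (count > 0).
#' @return 2 x 2 integer matrix, rows = groups, columns = with/without.
#' @export
incidence_table <- function(inventories_g1, inventories_g2, region, modality) {
  c1 <- inv_values(inventories_g1, region, modality, "count")
  c2 <- inv_values(inventories_g2, region, modality, "count")
  matrix(c(sum(c1 > 0), sum(c1 == 0), sum(c2 > 0), sum(c2 == 0)),
         2, 2, byrow = TRUE,
         dimnames = list(c("group1", "group2"), c("with", "without")))
}

#' Default group-report row schema
#'
#' Mirrors the structure of the published comparison table: incidence rows
#' tested with Fisher's exact test; lesion volumes with Student's t on
#' log-shifted values (infratentorial volumes with Mann-Whitney);
#' per-subject T1:T2 volume ratios with t; periventricular /
#' non-periventricular volumes with Mann-Whitney; lesion counts with t.
#' @export
report_schema <- function() {
  rbind(
    data.frame(type = "incidence", modality = c("T2w", "T1w", "T2w", "T1w", "T2w", "T2w"),
               region = c("supratentorial", "supratentorial", "infratentorial",
                          "infratentorial", "brainstem", "pons"),
               test = "fisher"),
    data.frame(type = "volume", modality = c("T2w", "T1w", "T2w", "T1w"),
               region = c("whole_brain", "whole_brain", "supratentorial", "supratentorial"),
               test = "t_log"),
    data.frame(type = "volume", modality = c("T2w", "T1w"),
               region = "infratentorial", test = "mw"),
    data.frame(type = "ratio", modality = "T1w:T2w",
               region = c("supratentorial", "infratentorial"), test = "t_raw"),
    data.frame(type = "volume", modality = "T2w",
               region = c("periventricular", "non_periventricular"), test = "mw"),
    data.frame(type = "count", modality = "T2w",
               region = c("supratentorial", "infratentorial", "whole_brain"),
               test = "t_log"))
}

report_one_row <- function(row, inv1, inv2, alpha, log_constant) {
  get2 <- function(inv) switch(row$type,
    incidence = inv_values(inv, row$region, row$modality, "count") > 0,
    volume = inv_values(inv, row$region, row$modality, "volume_cm3"),
    count = inv_values(inv, row$region, row$modality, "count"),
    ratio = {
      t1 <- inv_values(inv, row$region, "T1w", "volume_cm3")
      t2 <- inv_values(inv, row$region, "T2w", "volume_cm3")
      r <- ifelse(t2 > 0, t1 / t2, NA_real_)
      r[!is.na(r)]
    })
  x1 <- get2(inv1); x2 <- get2(inv2)
  need <- if (row$test %in% c("t_log", "t_raw")) 2L else 1L
  if (row$test != "fisher" && (length(x1) < need || length(x2) < need)) {
    return(data.frame(variable = paste(row$region, row$modality, row$type),
                      type = row$type, region = row$region,
                      modality = row$modality,
                      group1 = sprintf("n=%d", length(x1)),
                      group2 = sprintf("n=%d", length(x2)),
                      test = row$test, statistic = NA_real_, p = NA_real_,
                      significant = FALSE))
  }
  if (row$test == "fisher") {
    tab <- matrix(c(sum(x1), sum(!x1), sum(x2), sum(!x2)), 2, 2, byrow = TRUE)
    res <- fisher_exact_2x2(tab)
    stat <- res$odds_ratio; p <- res$p
    s1 <- sprintf("%d (%.1f%%)", sum(x1), 100 * mean(x1))
    s2 <- sprintf("%d (%.1f%%)", sum(x2), 100 * mean(x2))
  } else {
    if (row$test == "t_log") {
      ht <- two_sample_t(log_shift_transform(x1, log_constant),
                         log_shift_transform(x2, log_constant))
      stat <- ht$statistic; p <- ht$p
    } else if (row$test == "t_raw") {
      ht <- two_sample_t(x1, x2)
      stat <- ht$statistic; p <- ht$p
    } else {
      ht <- mann_whitney_u(x1, x2)
      stat <- ht$statistic; p <- ht$p
    }
    s1 <- sprintf("%.2f (%.2f)", mean(x1), stats::sd(x1))
    s2 <- sprintf("%.2f (%.2f)", mean(x2), stats::sd(x2))
  }
  data.frame(variable = paste(row$region, row$modality, row$type),
             type = row$type, region = row$region, modality = row$modality,
             group1 = s1, group2 = s2, test = row$test,
             statistic = unname(stat), p = unname(p),
             significant = p < alpha)
}

#' Group comparison report (published-table shape)
#'
#' Runs the full statistical battery over two cohorts' lesion inventories:
#' one row per entry of the row schema, each with group summaries, the test
#' used, its statistic and two-sided p, and a significance flag at `alpha`.
#' No multiplicity correction is applied (the comparisons are treated as
#' pre-specified).
#'
#' @param inventories_g1,inventories_g2 long inventory data frames for the
#'   two groups.
#' @param schema row schema data frame (default [report_schema()]).
#' @param alpha significance threshold (default 0.05).
#' @param log_constant shift used by the log transform (default 1 cm^3).
#' @return data frame of class `group_report`.
#' @export
group_report <- function(inventories_g1, inventories_g2,
                         schema = report_schema(), alpha = 0.05,
                         log_constant = 1) {
  if (!nrow(inventories_g1) || !nrow(inventories_g2))
    stop("both cohorts must be nonempty")
  missing1 <- setdiff(unique(schema$region), unique(inventories_g1$region))
  if (length(missing1))
    stop("report error: regions missing from inventories: ",
         paste(missing1, collapse = ", "))
  rows <- lapply(seq_len(nrow(schema)), function(i)
    report_one_row(schema[i, ], inventories_g1, inventories_g2,
                   alpha, log_constant))
  out <- do.call(rbind, rows)
  class(out) <- c("group_report", "data.frame")
  out
}
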