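# independent oracles and shared fixtures for the test suite

# stack-based flood fill, written independently of the igraph-backed
# component labeling it cross-checks
flood_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  deg <- rowSums(abs(off))
  off <- switch(as.character(connectivity),
                "6" = off[deg == 1, , drop = FALSE],
                "18" = off[deg >= 1 & deg <= 2, , drop = FALSE],
                "26" = off[deg >= 1, , drop = FALSE])
  lab <- array(0L, d)
  cur <- 0L
  s1 <- d[1]; s2 <- d[1] * d[2]
  for (start in which(mask > 0)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    stack <- integer(512); stack[1] <- start; top <- 1L
    lab[start] <- cur
    while (top > 0L) {
      v <- stack[top]; top <- top - 1L
      i <- ((v - 1L) %% s1) + 1L
      j <- (((v - 1L) %/% s1) %% d[2]) + 1L
      k <- ((v - 1L) %/% s2) + 1L
      for (r in seq_len(nrow(off))) {
        ni <- i + off[r, 1]; nj <- j + off[r, 2]; nk <- k + off[r, 3]
        if (ni < 1L || ni > d[1] || nj < 1L || nj > d[2] || nk < 1L || nk > d[3]) next
        nv <- ni + (nj - 1L) * s1 + (nk - 1L) * s2
        if (mask[nv] > 0 && lab[nv] == 0L) {
          lab[nv] <- cur
          top <- top + 1L
          if (top > length(stack)) stack <- c(stack, integer(length(stack)))
          stack[top] <- nv
        }
      }
    }
  }
  lab
}

# two partitions of the same foreground agree up to relabeling
same_partition <- function(lab_a, lab_b, fg) {
  length(unique(paste(lab_a[fg], lab_b[fg]))) ==
    length(unique(lab_a[fg])) &&
    length(unique(lab_a[fg])) == length(unique(lab_b[fg]))
}

# straight-line log-factorial hypergeometric enumeration for the two-sided
# Fisher p (point-probability convention)
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ]); K <- sum(tab[, 1])
  N <- n1 + n2
  lp <- function(k)
    lgamma(n1 + 1) - lgamma(k + 1) - lgamma(n1 - k + 1) +
    lgamma(n2 + 1) - lgamma(K - k + 1) - lgamma(n2 - K + k + 1) -
    (lgamma(N + 1) - lgamma(K + 1) - lgamma(N - K + 1))
  ks <- max(0, K - n2):min(n1, K)
  lps <- vapply(ks, lp, numeric(1))
  min(1, sum(exp(lps)[lps <= lp(a) + log(1 + 1e-7)]))
}

# normalize all three contrasts of a generated subject in place
norm_scan <- function(subject, atlas) {
  out <- subject$scan
  for (ctr in c("pd", "t2", "t1"))
    out[[ctr]] <- normalize_intensity(out[[ctr]], atlas$brain_mask)$volume
  out$normalized <- TRUE
  out
}

# shared fixtures, built once per test run
.lq_cache <- new.env(parent = emptyenv())

lq_fixture <- function(name, builder) {
  if (is.null(.lq_cache[[name]])) .lq_cache[[name]] <- builder()
  .lq_cache[[name]]
}

lq_atlas <- function() lq_fixture("atlas", function() build_region_atlas())

# a tissue model fitted on a dedicated training phantom (native pediatric
# grid, ground-truth labels)
lq_model <- function() lq_fixture("model", function() {
  at <- lq_atlas()
  tr <- generate_subject(
    phantom_spec(seed = 100,
                 n_lesions_by_region = c(supratentorial = 10L,
                                         cerebellum = 2L, pons = 1L)),
    atlas = at)
  trn <- norm_scan(tr, at)
  tis <- as.integer(at$tissue)
  lab <- rep(NA_character_, length(tis))
  lab[tis == 1] <- "WM"; lab[tis == 2] <- "GM"; lab[tis == 3] <- "CSF"
  lab[as.numeric(tr$truth$t2_lesion_mask) > 0] <- "lesion"
  keep <- !is.na(lab)
  fit_tissue_model(cbind(trn$pd[keep], trn$t2[keep], trn$t1[keep]), lab[keep])
})

lq_wm_mask <- function() {
  at <- lq_atlas()
  vol3d(array(as.numeric(at$tissue == 1), dim(at$tissue)),
        attr(at$tissue, "voxdim"), attr(at$tissue, "origin"))
}
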