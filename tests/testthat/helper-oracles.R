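# Independent oracles used across the suite. These deliberately take a
# different computational route than the package so that agreement is
# evidence of correctness, not of shared code.

# --- Weir-Cockerham Fst via the gametic analysis of variance ----------------
# The package computes theta from the closed-form variance components in
# terms of (n_i, p_i, h_i). This oracle instead reconstructs individual
# allele dosages from genotype class counts and computes the observed mean
# squares of the nested gamete-in-individual-in-population ANOVA, then
# a = (MSP - MSI) / (2 n_c), b = (MSI - MSG) / 2, c = MSG.
wc_fst_anova_oracle <- function(hom1_1, het_1, hom2_1, hom1_2, het_2, hom2_2) {
  dosages <- list(
    c(rep(0, hom1_1), rep(1, het_1), rep(2, hom2_1)),
    c(rep(0, hom1_2), rep(1, het_2), rep(2, hom2_2))
  )
  n <- lengths(dosages)
  r <- 2
  n_tot <- sum(n)
  ybar_i <- vapply(dosages, function(x) mean(x) / 2, numeric(1))
  ybar <- sum(n * ybar_i) / n_tot

  ssp <- 2 * sum(n * (ybar_i - ybar)^2)
  ssi <- 2 * sum(unlist(purrr::map2(dosages, ybar_i,
                                    function(x, m) (x / 2 - m)^2)))
  # a heterozygote's two gametes are 0 and 1: within-individual SS = 0.5
  ssg <- (het_1 + het_2) / 2

  msp <- ssp / (r - 1)
  msi <- ssi / (n_tot - r)
  msg <- ssg / n_tot

  n_bar <- n_tot / r
  n_c <- (n_tot - sum(n^2) / n_tot) / (r - 1)
  a <- (msp - msi) / (2 * n_c)
  b <- (msi - msg) / 2
  cc <- msg
  a / (a + b + cc)
}

# Wraps genotype class counts into the count tibbles the package consumes.
counts_from_classes <- function(hom1, het, hom2, snp_id = "s1") {
  tibble::tibble(chrom = "1", bp = seq_along(hom1), snp_id = snp_id,
                 n_called = hom1 + het + hom2,
                 count2 = het + 2 * hom2, het_count = het)
}

# --- XP-EHH by exhaustive pair enumeration ----------------------------------
# Identity over the window is decided by comparing full haplotype segments as
# strings, pair by pair, instead of the package's incremental group
# refinement; integration conventions (shared pooled stopping, included
# crossing step, gap cap, max extension) are the statistic's definition and
# are therefore shared.
pair_ehh <- function(h, cols) {
  n <- nrow(h)
  seg <- apply(h[, cols, drop = FALSE], 1, paste, collapse = "")
  pairs <- utils::combn(n, 2)
  mean(seg[pairs[1, ]] == seg[pairs[2, ]])
}

xpehh_pair_oracle <- function(ht, hr, pos, cutoff = 0.05,
                              max_extend = 1e6, gap_cap = 2e5) {
  S <- length(pos)
  hp <- rbind(ht, hr)
  ihh_t <- numeric(S)
  ihh_r <- numeric(S)
  for (core in seq_len(S)) {
    for (dir in c(-1L, 1L)) {
      et <- 1; er <- 1
      prev <- 0
      j <- core + dir
      while (j >= 1 && j <= S) {
        dist <- abs(pos[j] - pos[core])
        if (dist > max_extend) break
        cols <- min(core, j):max(core, j)
        et2 <- pair_ehh(ht, cols)
        er2 <- pair_ehh(hr, cols)
        ep2 <- pair_ehh(hp, cols)
        w <- min(dist - prev, gap_cap)
        ihh_t[core] <- ihh_t[core] + w * (et + et2) / 2
        ihh_r[core] <- ihh_r[core] + w * (er + er2) / 2
        et <- et2; er <- er2; prev <- dist
        if (ep2 < cutoff || ep2 <= 0) break
        j <- j + dir
      }
    }
  }
  tibble::tibble(ihh_target = ihh_t, ihh_reference = ihh_r,
                 xpehh_raw = ifelse(ihh_t > 0 & ihh_r > 0,
                                    log(ihh_t / ihh_r), NA_real_))
}

# --- small fixture builders -------------------------------------------------
toy_map <- function(bp, chrom = "1") {
  tibble::tibble(chrom = chrom, bp = bp,
                 snp_id = paste0("s", seq_along(bp)),
                 allele1 = "A", allele2 = "G")
}

toy_hap_panel <- function(mat, bp = seq_len(ncol(mat)) * 1000L, chrom = "1") {
  haplotype_panel(toy_map(bp, chrom), mat,
                  paste0("ind", seq_len(nrow(mat) / 2)))
}

random_hap_panel <- function(n_hap, n_snp, seed, spacing = 1e4) {
  set.seed(seed)
  mat <- matrix(rbinom(n_hap * n_snp, 1, runif(n_snp, 0.2, 0.8)[rep(1:n_snp, each = n_hap)]),
                nrow = n_hap)
  toy_hap_panel(mat, bp = as.integer(seq_len(n_snp)) * as.integer(spacing))
}
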