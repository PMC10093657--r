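#' Per-SNP allele counts for one population
#'
#' Tallies, per SNP, the number of diploid samples with a non-missing call,
#' the number of allele2 copies, and the heterozygote count. Missing
#' genotypes are excluded from every count, so they never enter a frequency
#' denominator downstream.
#'
#' @param panel A [snp_panel()].
#' @param pop_spec Optional sample-to-group table; with `group`, the panel is
#'   first restricted via [subset_samples()].
#' @param group Optional group label.
#' @return A tibble with `chrom`, `bp`, `snp_id`, `n_called`, `count2`,
#'   `het_count`.
#' @export
count_alleles <- function(panel, pop_spec = NULL, group = NULL) {
  if (!is.null(group)) panel <- subset_samples(panel, pop_spec, group)
  g <- panel$genotypes
  tibble::tibble(
    chrom = panel$map$chrom, bp = panel$map$bp, snp_id = panel$map$snp_id,
    n_called = colSums(!is.na(g)),
    count2 = colSums(g, na.rm = TRUE),
    het_count = colSums(g == 1L, na.rm = TRUE)
  )
}

#' Per-SNP Weir-Cockerham Fst between two populations
#'
#' The two-population moment estimator theta = a / (a + b + c) built from the
#' among-population (a), among-individual-within-population (b) and
#' within-individual (c) variance components, computed per SNP from observed
#' sample sizes, allele2 frequencies and heterozygote frequencies. Negative
#' estimates are retained as computed — the composite index consumes ranks,
#' and clamping at zero would create mass ties. A site is invalid when it is
#' monomorphic across both populations (the estimator is 0/0) or when either
#' population has fewer than two called samples.
#'
#' @param counts_t,counts_r [count_alleles()] tibbles for the target and
#'   reference populations over the same SNP map.
#' @return A tibble with `chrom`, `bp`, `snp_id`, `fst`, `valid_fst`.
#' @export
weir_cockerham_fst <- function(counts_t, counts_r) {
  if (!identical(counts_t$snp_id, counts_r$snp_id)) {
    stop("SNP maps of the two populations do not match", call. = FALSE)
  }
  n1 <- counts_t$n_called; n2 <- counts_r$n_called
  p1 <- counts_t$count2 / (2 * n1); p2 <- counts_r$count2 / (2 * n2)
  h1 <- counts_t$het_count / n1; h2 <- counts_r$het_count / n2

  r <- 2
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)

  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2

  denom <- a + b + cc
  total2 <- counts_t$count2 + counts_r$count2
  total_called <- 2 * (n1 + n2)
  mono <- total2 == 0 | total2 == total_called
  valid <- !mono & n1 >= 2 & n2 >= 2 & is.finite(denom) & denom != 0
  fst <- ifelse(valid, a / denom, NA_real_)
  tibble::tibble(chrom = counts_t$chrom, bp = counts_t$bp,
                 snp_id = counts_t$snp_id, fst = fst, valid_fst = valid)
}

#' Assign ancestral alleles from an outgroup panel
#'
#' The strictly major allele of the outgroup (ancestral-role) population is
#' taken as the ancestral allele at each SNP; the other allele is derived.
#' An exact 50/50 frequency or a SNP with no outgroup calls leaves the site
#' unresolved — excluded from the deltaDAF ranking — rather than broken
#' arbitrarily.
#'
#' @param outgroup_counts [count_alleles()] tibble for the outgroup panel.
#' @return A tibble with `snp_id`, `ancestral` (`"allele1"`, `"allele2"` or
#'   `NA`), `derived`, and `source = "outgroup_major"`.
#' @export
assign_ancestral <- function(outgroup_counts) {
  freq2 <- outgroup_counts$count2 / (2 * outgroup_counts$n_called)
  ancestral <- dplyr::case_when(
    outgroup_counts$n_called == 0 ~ NA_character_,
    freq2 > 0.5 ~ "allele2",
    freq2 < 0.5 ~ "allele1",
    TRUE ~ NA_character_
  )
  derived <- dplyr::case_when(
    ancestral == "allele1" ~ "allele2",
    ancestral == "allele2" ~ "allele1",
    TRUE ~ NA_character_
  )
  tibble::tibble(snp_id = outgroup_counts$snp_id, ancestral = ancestral,
                 derived = derived, source = "outgroup_major")
}

#' Agreement between two outgroup panels on the major allele
#'
#' Companion report for validating the ancestral assignment against a second
#' outgroup (for dogs, e.g. wolves vs an ancient breed): the fraction of SNPs
#' at which the two panels resolve the same major allele, among SNPs resolved
#' in both. Purely diagnostic; it never gates the assignment.
#'
#' @param counts_a,counts_b [count_alleles()] tibbles over the same SNP map.
#' @return A one-row tibble with `n_both_resolved` and `agreement`.
#' @export
compare_ancestral_panels <- function(counts_a, counts_b) {
  a <- assign_ancestral(counts_a)
  b <- assign_ancestral(counts_b)
  both <- !is.na(a$ancestral) & !is.na(b$ancestral)
  tibble::tibble(n_both_resolved = sum(both),
                 agreement = mean(a$ancestral[both] == b$ancestral[both]))
}

#' Derived allele frequency difference (deltaDAF) between two populations
#'
#' Computes, per SNP, the derived allele frequency in target and reference —
#' derived being the allele opposite the outgroup major allele — and their
#' difference `DAF_target - DAF_reference`. Frequencies are taken over
#' non-missing calls only. A SNP is invalid when the ancestral state is
#' unresolved or either population has zero calls.
#'
#' @param counts_t,counts_r [count_alleles()] tibbles for target and
#'   reference.
#' @param assignment An [assign_ancestral()] tibble.
#' @return A tibble with `chrom`, `bp`, `snp_id`, `daf_target`,
#'   `daf_reference`, `ddaf`, `valid_ddaf`.
#' @export
delta_daf <- function(counts_t, counts_r, assignment) {
  if (!identical(counts_t$snp_id, counts_r$snp_id) ||
      !identical(counts_t$snp_id, assignment$snp_id)) {
    stop("SNP maps do not match", call. = FALSE)
  }
  f2_t <- counts_t$count2 / (2 * counts_t$n_called)
  f2_r <- counts_r$count2 / (2 * counts_r$n_called)
  derived2 <- assignment$derived == "allele2"
  daf_t <- ifelse(derived2, f2_t, 1 - f2_t)
  daf_r <- ifelse(derived2, f2_r, 1 - f2_r)
  valid <- !is.na(assignment$derived) & counts_t$n_called > 0 & counts_r$n_called > 0
  tibble::tibble(chrom = counts_t$chrom, bp = counts_t$bp,
                 snp_id = counts_t$snp_id,
                 daf_target = ifelse(valid, daf_t, NA_real_),
                 daf_reference = ifelse(valid, daf_r, NA_real_),
                 ddaf = ifelse(valid, daf_t - daf_r, NA_real_),
                 valid_ddaf = valid)
}

#' Z-score a deltaDAF vector
#'
#' Centers and scales the valid deltaDAF values to mean 0 and sd 1 (sample
#' standard deviation, denominator n - 1). The transform is strictly
#' monotone, so it never changes the fractional ranks that enter the
#' composite index; it is applied for comparability of the reported
#' per-component tracks.
#'
#' @param ddaf Numeric vector.
#' @param valid Logical vector; defaults to non-NA entries.
#' @return Numeric vector of the same length; invalid entries stay `NA`.
#' @export
zscore_ddaf <- function(ddaf, valid = !is.na(ddaf)) {
  x <- ddaf[valid]
  if (length(x) < 2) stop("need at least two valid values", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("zero variance in deltaDAF values", call. = FALSE)
  out <- rep(NA_real_, length(ddaf))
  out[valid] <- (x - mean(x)) / s
  out
}
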