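# Deterministic panel fixtures built in code.

# A panel with planted QC violations: one sample with 12% missing calls, one
# SNP carrying a single allele2 copy (MAF 1/198 after the bad sample is
# dropped), and SNPs on non-autosomal chromosomes 39 and 41.
make_qc_panel <- function() {
  set.seed(99)
  n <- 100
  snps <- tibble::tibble(
    chrom = c(rep("1", 20), rep("2", 2), rep("39", 2), "41"),
    bp = c(seq(1e5, 2e6, length.out = 20), 1e5, 2e5, 1e5, 2e5, 1e5),
    snp_id = sprintf("q%02d", 1:25),
    allele1 = "A", allele2 = "G"
  )
  g <- matrix(rbinom(n * 25, 2, 0.5), nrow = n)
  rare <- 5L  # planted low-MAF SNP, on chromosome 1
  g[, rare] <- 0L
  g[2, rare] <- 1L  # exactly one allele2 copy, in a sample that survives QC
  bad_sample <- 1L  # 3 of 25 = 12% missing
  g[bad_sample, c(10L, 15L, 20L)] <- NA_integer_
  panel <- snp_panel(snps, g, sprintf("s%03d", 1:n))
  list(panel = panel, bad_sample = "s001", rare_snp = "q05",
       off_chrom_snps = snps$snp_id[snps$chrom %in% c("39", "41")])
}

# Small polymorphic panel with alphabetical allele pairs (both alleles
# observed at every SNP) so PLINK text round-trips are exact.
make_roundtrip_panel <- function() {
  map <- tibble::tibble(
    chrom = c("1", "1", "2", "2", "3"),
    bp = c(100L, 250L, 90L, 400L, 10L),
    snp_id = paste0("rt", 1:5),
    allele1 = c("A", "C", "A", "G", "C"),
    allele2 = c("G", "T", "C", "T", "G")
  )
  g <- rbind(c(0L, 1L, 2L, 1L, 0L),
             c(1L, 2L, 0L, NA, 1L),
             c(2L, 0L, 1L, 0L, 2L),
             c(0L, 1L, 1L, 2L, 1L))
  snp_panel(map, g, paste0("dog", 1:4))
}

make_toy_hap_fixture <- function() {
  map <- tibble::tibble(chrom = "1", bp = c(100L, 200L, 300L),
                        snp_id = c("v1", "v2", "v3"),
                        allele1 = c("A", "C", "G"), allele2 = c("G", "T", "A"))
  haps <- rbind(c(0L, 1L, 0L), c(1L, 0L, 0L),
                c(0L, 0L, 1L), c(1L, 1L, 1L),
                c(0L, 1L, 1L), c(0L, 0L, 0L),
                c(1L, 1L, 0L), c(1L, 0L, 1L))
  haplotype_panel(map, haps, paste0("ind", 1:4))
}
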