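write_toy_plink <- function(dir) {
  map <- c("1\ts1\t0\t100", "1\ts2\t0\t200", "2\ts3\t0\t150")
  ped <- c("fam1 ind1 0 0 0 -9 A A A G C C",
           "fam2 ind2 0 0 0 -9 A G 0 0 C T")
  writeLines(map, file.path(dir, "toy.map"))
  writeLines(ped, file.path(dir, "toy.ped"))
  file.path(dir, c("toy.map", "toy.ped"))
}

test_that("PLINK text reading decodes a toy fixture, '0 0' becomes missing", {
  dir <- withr::local_tempdir()
  paths <- write_toy_plink(dir)
  panel <- read_plink_text(paths[1], paths[2])
  expect_s3_class(panel, "snp_panel")
  expect_identical(panel$sample_ids, c("ind1", "ind2"))
  expect_identical(panel$map$snp_id, c("s1", "s2", "s3"))
  expect_identical(panel$map$allele1, c("A", "A", "C"))
  expect_identical(panel$map$allele2, c("G", "G", "T"))
  expect_identical(panel$genotypes,
                   matrix(c(0L, 1L, 1L, NA, 0L, 1L), nrow = 2))
})

test_that("PLINK reading rejects triallelic sites and ragged lines", {
  dir <- withr::local_tempdir()
  writeLines(c("1\ts1\t0\t100"), file.path(dir, "bad.map"))
  writeLines(c("f1 i1 0 0 0 -9 A C", "f2 i2 0 0 0 -9 G G"),
             file.path(dir, "bad.ped"))
  expect_error(read_plink_text(file.path(dir, "bad.map"),
                               file.path(dir, "bad.ped")),
               "s1")
  writeLines(c("f1 i1 0 0 0 -9 A A", "f2 i2 0 0 0 -9 A"),
             file.path(dir, "ragged.ped"))
  expect_error(read_plink_text(file.path(dir, "bad.map"),
                               file.path(dir, "ragged.ped")),
               "ragged ped line 2")
})

test_that("PLINK text write/read round-trip is lossless", {
  panel <- make_roundtrip_panel()
  dir <- withr::local_tempdir()
  write_plink_text(panel, file.path(dir, "rt.map"), file.path(dir, "rt.ped"))
  back <- read_plink_text(file.path(dir, "rt.map"), file.path(dir, "rt.ped"))
  expect_identical(back$map, panel$map)
  expect_identical(back$genotypes, panel$genotypes)
  expect_identical(back$sample_ids, panel$sample_ids)
})

test_that("phased VCF write/read round-trip is the identity", {
  haps <- make_toy_hap_fixture()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_phased_vcf(haps, path)
  back <- read_phased_vcf(path)
  expect_identical(back$map, haps$map)
  expect_identical(back$haplotypes, haps$haplotypes)
  expect_identical(back$sample_ids, haps$sample_ids)
})

test_that("phased VCF reader maps 0|1 to the sample's two haplotype rows", {
  haps <- make_toy_hap_fixture()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_phased_vcf(haps, path)
  back <- read_phased_vcf(path)
  # sample 1 at first site was written from rows 1 and 2
  expect_identical(back$haplotypes[1:2, 1], haps$haplotypes[1:2, 1])
})

test_that("unphased or missing GT fields are rejected with the record named", {
  base <- c("##fileformat=VCFv4.2",
            "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(base, "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0|1\t0/1"), path)
  expect_error(read_phased_vcf(path), "unphased genotype.*v1")
  writeLines(c(base, "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0|1\t.|."), path)
  expect_error(read_phased_vcf(path), "missing genotype")
  writeLines(c(base, "1\t100\tv1\tA\tG,T\t.\tPASS\t.\tGT\t0|1\t0|2"), path)
  expect_error(read_phased_vcf(path), "multiallelic")
})

test_that("filter_qc removes exactly the planted violations, in the fixed order", {
  fx <- make_qc_panel()
  out <- filter_qc(fx$panel, max_sample_missing = 0.1, min_maf = 0.01,
                   keep_chroms = as.character(1:38))
  expect_false(fx$bad_sample %in% out$sample_ids)
  expect_false(fx$rare_snp %in% out$map$snp_id)
  expect_false(any(fx$off_chrom_snps %in% out$map$snp_id))
  # and nothing else went
  expect_identical(length(out$sample_ids), length(fx$panel$sample_ids) - 1L)
  expect_identical(nrow(out$map),
                   nrow(fx$panel$map) - 1L - length(fx$off_chrom_snps))
})

test_that("filter_qc is idempotent and never mutates its input", {
  fx <- make_qc_panel()
  before <- fx$panel$genotypes
  once <- filter_qc(fx$panel, keep_chroms = as.character(1:38))
  twice <- filter_qc(once, keep_chroms = as.character(1:38))
  expect_identical(once, twice)
  expect_identical(fx$panel$genotypes, before)
  tiny <- snp_panel(tibble::tibble(chrom = "39", bp = 1L, snp_id = "x",
                                   allele1 = "A", allele2 = "G"),
                    matrix(1L, 1, 1), "s1")
  expect_error(filter_qc(tiny, keep_chroms = as.character(1:38)),
               "no data after QC")
})

test_that("harmonize_alleles resolves flips and swaps, drops ambiguous sites", {
  map_a <- tibble::tibble(chrom = "1", bp = c(100L, 200L, 300L),
                          snp_id = c("h1", "h2", "h3"),
                          allele1 = c("A", "A", "A"),
                          allele2 = c("G", "G", "T"))
  map_b <- map_a
  map_b$allele1 <- c("T", "G", "A")  # h1 flipped, h2 swapped, h3 ambiguous
  map_b$allele2 <- c("C", "A", "T")
  ga <- matrix(c(0L, 1L, 2L), nrow = 1)
  gb <- matrix(c(0L, 1L, 2L), nrow = 1)
  res <- harmonize_alleles(snp_panel(map_a, ga, "x"), snp_panel(map_b, gb, "y"))
  rep <- res$flip_report
  expect_identical(rep$action[rep$snp_id == "h1"], "flipped")
  expect_identical(rep$action[rep$snp_id == "h2"], "swapped")
  expect_identical(rep$action[rep$snp_id == "h3"], "dropped_ambiguous")
  expect_identical(res$panel_b$map$allele1, c("A", "A"))
  expect_identical(res$panel_b$map$allele2, c("G", "G"))
  # flip leaves codes alone, swap recodes 2 - g
  expect_identical(res$panel_b$genotypes[1, ], c(0L, 1L))
})

test_that("harmonization restores exact frequency agreement on 500 randomized sites", {
  set.seed(7)
  n_snp <- 500
  pairs <- list(c("A", "G"), c("A", "C"), c("C", "A"), c("G", "T"), c("T", "G"))
  al <- pairs[sample.int(length(pairs), n_snp, replace = TRUE)]
  map_a <- tibble::tibble(chrom = "1", bp = seq_len(n_snp) * 100L,
                          snp_id = sprintf("r%03d", seq_len(n_snp)),
                          allele1 = purrr::map_chr(al, 1),
                          allele2 = purrr::map_chr(al, 2))
  g <- matrix(rbinom(20 * n_snp, 2, 0.4), nrow = 20)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  map_b <- map_a
  gb <- g
  action <- sample(c("none", "flip", "swap", "flip_swap"), n_snp, replace = TRUE)
  for (j in seq_len(n_snp)) {
    a1 <- map_a$allele1[j]; a2 <- map_a$allele2[j]
    if (action[j] %in% c("flip", "flip_swap")) {
      a1 <- unname(comp[a1]); a2 <- unname(comp[a2])
    }
    if (action[j] %in% c("swap", "flip_swap")) {
      tmp <- a1; a1 <- a2; a2 <- tmp
      gb[, j] <- 2L - gb[, j]
    }
    map_b$allele1[j] <- a1; map_b$allele2[j] <- a2
  }
  res <- harmonize_alleles(snp_panel(map_a, g, paste0("a", 1:20)),
                           snp_panel(map_b, gb, paste0("b", 1:20)))
  expect_equal(nrow(res$flip_report), n_snp)
  expect_true(all(res$flip_report$action != "dropped_mismatch"))
  fa <- colMeans(res$panel_a$genotypes) / 2
  fb <- colMeans(res$panel_b$genotypes) / 2
  expect_identical(fa, fb)
})

test_that("subset_samples keeps group members in order, errors on unknown group", {
  sim <- simulate_panel(sim_config(n_snps = 50, n_target = 5, n_reference = 3,
                                   n_ancestral = 2, chrom_lengths = c("1" = 1e6),
                                   seed = 5))
  all_geno <- rbind(sim$panels$target$genotypes, sim$panels$reference$genotypes,
                    sim$panels$ancestral$genotypes)
  combined <- snp_panel(sim$panels$target$map, all_geno, sim$pop_spec$sample_id)
  tgt <- subset_samples(combined, sim$pop_spec, "target")
  expect_identical(tgt$sample_ids, sim$panels$target$sample_ids)
  expect_identical(tgt$genotypes, sim$panels$target$genotypes)
  everyone <- sim$pop_spec
  everyone$group <- "all"
  expect_identical(subset_samples(combined, everyone, "all")$genotypes,
                   combined$genotypes)
  expect_error(subset_samples(combined, sim$pop_spec, "wolves"), "unknown group")
  # haplotype panels subset by sample pairs of rows
  htgt <- subset_samples(sim$haplotypes$target, sim$pop_spec, "target")
  expect_identical(htgt$haplotypes, sim$haplotypes$target$haplotypes)
})

test_that("pop spec TSV round-trips and rejects duplicated samples", {
  spec <- tibble::tibble(sample_id = c("a", "b"), group = c("g1", "g2"),
                         role = c("target", "reference"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pop_spec(spec, path)
  expect_identical(read_pop_spec(path), spec)
  writeLines(c("sample_id\tgroup\trole", "a\tg1\ttarget", "a\tg2\treference"),
             path)
  expect_error(read_pop_spec(path), "exactly one group")
})
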