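mk_track <- function(bp, css_smooth, significant, chrom = "1") {
  tibble::tibble(chrom = chrom, bp = bp, snp_id = paste0("t", seq_along(bp)),
                 css_smooth = css_smooth, significant = significant)
}

test_that("regions merge significant SNPs within the gap and never across it", {
  track <- mk_track(c(10.1e6, 10.3e6, 10.4e6, 25.0e6),
                    c(3, 3.2, 3.1, 2.9), rep(TRUE, 4))
  regions <- call_regions(track, merge_gap_bp = 1e6)
  expect_equal(nrow(regions), 2)
  expect_equal(regions$start_bp, c(10.1e6, 25.0e6))
  expect_equal(regions$end_bp, c(10.4e6, 25.0e6))
  expect_equal(regions$n_significant, c(3L, 1L))

  one <- call_regions(mk_track(5e6, 2.5, TRUE))
  expect_equal(nrow(one), 1)
  expect_equal(one$n_significant, 1L)

  none <- call_regions(mk_track(5e6, 2.5, FALSE))
  expect_equal(nrow(none), 0)
})

test_that("region averages use significant SNPs only; n_snps counts all in span", {
  track <- mk_track(c(1e6, 1.5e6, 2e6), c(2.4, 9.9, 2.6),
                    c(TRUE, FALSE, TRUE))
  regions <- call_regions(track, merge_gap_bp = 1.5e6)
  expect_equal(nrow(regions), 1)
  expect_equal(regions$avg_css, 2.5)
  expect_equal(regions$n_snps, 3L)
  expect_equal(regions$n_significant, 2L)
})

test_that("regions never span chromosomes; merging is idempotent; counts add up", {
  sim <- simulate_panel(sim_config(n_snps = 3000,
                                   chrom_lengths = c("1" = 1.5e7, "2" = 1.5e7),
                                   sweeps = sweep_spec("1", 6e6, 8e6, 0.9),
                                   seed = 113))
  scan <- run_scan(sim$panels$target, sim$panels$reference, sim$panels$ancestral,
                   sim$haplotypes$target, sim$haplotypes$reference)
  regions <- scan$regions
  track <- scan$snps
  expect_equal(sum(regions$n_significant), sum(track$significant))
  for (i in seq_len(nrow(regions))) {
    expect_true(all(track$chrom[track$significant &
                                  track$bp >= regions$start_bp[i] &
                                  track$bp <= regions$end_bp[i] &
                                  track$chrom == regions$chrom[i]] ==
                      regions$chrom[i]))
  }
  again <- call_regions(track, merge_gap_bp = 1e6)
  expect_equal(tibble::as_tibble(again), tibble::as_tibble(regions))
  # every region's average sits at or above the realised threshold
  thr <- min(track$css_smooth[track$significant])
  expect_true(all(regions$avg_css >= thr))
})

test_that("gene overlap honours containment, flanks and chromosomes", {
  regions <- call_regions(mk_track(c(10e6, 12e6), c(3, 3.1), c(TRUE, TRUE)),
                          merge_gap_bp = 3e6)
  genes <- tibble::tibble(
    gene_id = c("inside", "downstream", "other_chrom"),
    chrom = c("1", "1", "2"),
    start_bp = c(11.5e6, 12.5e6, 11.5e6),
    end_bp = c(11.8e6, 12.9e6, 11.8e6),
    biotype = c("protein_coding", "lncRNA", "protein_coding")
  )
  hit0 <- overlap_genes(regions, genes, flank_bp = 0)
  expect_identical(hit0$genes[[1]]$gene_id, "inside")
  hit1 <- overlap_genes(regions, genes, flank_bp = 1e6)
  expect_setequal(hit1$genes[[1]]$gene_id, c("inside", "downstream"))
  expect_match(hit1$gene_summary[1], "2 genes")
  expect_match(hit1$gene_summary[1], "1 protein_coding")
  bad <- genes; bad$end_bp[1] <- bad$start_bp[1] - 10
  expect_error(overlap_genes(regions, bad), "inside")
})

test_that("flank-0 overlap agrees with a brute-force all-pairs check", {
  set.seed(127)
  regions <- tibble::tibble(
    chrom = sample(c("1", "2"), 20, replace = TRUE),
    start_bp = sample.int(5e7, 20)
  )
  regions$end_bp <- regions$start_bp + sample.int(3e6, 20)
  regions$avg_css <- 3; regions$n_significant <- 1L; regions$n_snps <- 1L
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:200),
    chrom = sample(c("1", "2"), 200, replace = TRUE),
    start_bp = sample.int(5.2e7, 200)
  )
  genes$end_bp <- genes$start_bp + sample.int(2e5, 200)
  genes$biotype <- NA_character_
  got <- overlap_genes(regions, genes, flank_bp = 0)
  for (i in seq_len(nrow(regions))) {
    expected <- character(0)
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] == regions$chrom[i] &&
          max(genes$start_bp[j], regions$start_bp[i]) <=
            min(genes$end_bp[j], regions$end_bp[i])) {
        expected <- c(expected, genes$gene_id[j])
      }
    }
    expect_setequal(got$genes[[i]]$gene_id, expected)
  }
})

test_that("gene annotation readers normalise BED and GFF3 coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t999\t2000\tgeneA", "2\t0\t500\tgeneB"), bed)
  gb <- read_gene_annotation(bed)
  expect_equal(gb$start_bp[gb$gene_id == "geneA"], 1000)
  expect_equal(gb$end_bp[gb$gene_id == "geneA"], 2000)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("1", "ens", "gene", "1000", "2000", ".", "+", ".",
                     "ID=gene:ENSCAFG1;Name=geneA;biotype=protein_coding",
                     sep = "\t")), gff)
  gg <- read_gene_annotation(gff)
  expect_equal(gg$start_bp, 1000)
  expect_equal(gg$end_bp, 2000)
  expect_identical(gg$gene_id, "geneA")
  expect_identical(gg$biotype, "protein_coding")
})

test_that("region table prints Mb spans with exact machine columns", {
  regions <- tibble::tibble(chrom = "8", start_bp = 56550000, end_bp = 60350000,
                            avg_css = 2.5678, n_significant = 231L,
                            n_snps = 255L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_region_table(regions, path)
  lines <- readLines(path)
  expect_equal(length(lines), 2)
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_identical(fields[1:5], c("8", "56.55-60.35 Mb", "2.57", "231", "255"))
  expect_identical(fields[6:7], c("56550000", "60350000"))

  empty <- call_regions(mk_track(1e6, 1, FALSE))
  write_region_table(empty, path)
  expect_equal(length(readLines(path)), 1)

  two <- tibble::tibble(chrom = "18", start_bp = c(3e7, 1e7),
                        end_bp = c(3.1e7, 1.1e7), avg_css = 2,
                        n_significant = 1L, n_snps = 1L)
  write_region_table(dplyr::arrange(two, start_bp), path)
  body <- readLines(path)[-1]
  expect_true(grepl("^18\t10\\.00", body[1]) && grepl("^18\t30\\.00", body[2]))
})

test_that("run_scan is deterministic and writes its TSV outputs", {
  sim <- simulate_panel(sim_config(n_snps = 400, n_target = 12, n_reference = 12,
                                   n_ancestral = 8, chrom_lengths = c("1" = 4e6),
                                   seed = 7))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run <- function(dir) {
    run_scan(sim$panels$target, sim$panels$reference, sim$panels$ancestral,
             sim$haplotypes$target, sim$haplotypes$reference, out_dir = dir)
  }
  run(d1); run(d2)
  for (f in c("css_snps.tsv", "css_regions.tsv", "params.tsv")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("stage failures propagate with the stage named", {
  sim <- simulate_panel(sim_config(n_snps = 100, n_target = 6, n_reference = 6,
                                   n_ancestral = 4, chrom_lengths = c("1" = 1e6),
                                   seed = 9))
  broken <- sim$panels$reference
  broken$map$bp <- broken$map$bp + 1L
  expect_error(run_scan(sim$panels$target, broken, sim$panels$ancestral,
                        sim$haplotypes$target, sim$haplotypes$reference),
               "stage input-check")
})

test_that("scan results expose tidy, glance and autoplot interfaces", {
  sim <- simulate_panel(sim_config(n_snps = 300, n_target = 10, n_reference = 10,
                                   n_ancestral = 8, chrom_lengths = c("1" = 3e6),
                                   seed = 13))
  scan <- run_scan(sim$panels$target, sim$panels$reference, sim$panels$ancestral,
                   sim$haplotypes$target, sim$haplotypes$reference)
  td <- tidy(scan)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("css_raw", "css_smooth", "significant") %in% names(td)))
  gl <- glance(scan)
  expect_equal(gl$n_snps, 300)
  expect_equal(gl$n_significant, ceiling(0.005 * 300))
  p <- autoplot(scan)
  expect_s3_class(p, "ggplot")
  curve <- ehh_at(sim$haplotypes$target, 10, "right")
  expect_s3_class(autoplot(curve), "ggplot")
})
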