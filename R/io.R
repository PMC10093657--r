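#' Read a SNP panel from PLINK text files (.map / .ped)
#'
#' Alleles at each site are taken from the calls observed in the ped file and
#' assigned alphabetically (`allele1 < allele2`), which is deterministic and
#' independent of allele frequency. Genotype codes count copies of `allele2`.
#' A `0 0` (or half-missing) call becomes `NA`. At a monomorphic site the
#' observed allele is `allele2` and a placeholder base is used for `allele1`.
#'
#' @param map_path Path to the 4-column map file (chrom, snp_id, cM, bp).
#' @param ped_path Path to the ped file (6 leading columns, then two allele
#'   columns per SNP).
#' @return A [snp_panel()], SNPs re-sorted by `(chrom, bp)`.
#' @export
read_plink_text <- function(map_path, ped_path) {
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = c("character", "character",
                                              "numeric", "integer"))
  names(map_raw) <- c("chrom", "snp_id", "cm", "bp")
  m <- nrow(map_raw)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  lens <- lengths(fields)
  if (any(lens != want)) {
    stop("ragged ped line ", which(lens != want)[1], ": expected ", want,
         " fields, got ", lens[lens != want][1], call. = FALSE)
  }
  ped <- do.call(rbind, fields)
  sample_ids <- ped[, 2]
  n <- nrow(ped)

  a_first <- ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a_second <- ped[, 6L + 2L * seq_len(m), drop = FALSE]
  # half-missing calls are treated as fully missing, as PLINK does
  missing <- a_first == "0" | a_second == "0"

  allele1 <- character(m)
  allele2 <- character(m)
  geno <- matrix(NA_integer_, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    calls <- c(a_first[!missing[, j], j], a_second[!missing[, j], j])
    obs <- sort(unique(calls))
    if (length(obs) > 2) {
      stop("more than two alleles observed at SNP ", map_raw$snp_id[j], ": ",
           paste(obs, collapse = "/"), call. = FALSE)
    }
    if (length(obs) == 0) obs <- c("A", "C")  # fully missing column
    if (length(obs) == 1) {
      obs <- c(setdiff(c("A", "C", "G", "T"), obs)[1], obs)
    }
    allele1[j] <- obs[1]
    allele2[j] <- obs[2]
    g <- (a_first[, j] == obs[2]) + (a_second[, j] == obs[2])
    g[missing[, j]] <- NA_integer_
    geno[, j] <- as.integer(g)
  }
  map <- tibble::tibble(chrom = map_raw$chrom, bp = map_raw$bp,
                        snp_id = map_raw$snp_id,
                        allele1 = allele1, allele2 = allele2)
  snp_panel(map, geno, sample_ids)
}

#' Write a SNP panel as PLINK text files
#'
#' @param panel A [snp_panel()].
#' @param map_path,ped_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_plink_text <- function(panel, map_path, ped_path) {
  map <- panel$map
  writeLines(sprintf("%s\t%s\t0\t%d", map$chrom, map$snp_id, as.integer(map$bp)),
             map_path)
  g <- panel$genotypes
  n <- nrow(g)
  out <- character(n)
  for (i in seq_len(n)) {
    first <- ifelse(is.na(g[i, ]), "0", ifelse(g[i, ] >= 1, map$allele2, map$allele1))
    second <- ifelse(is.na(g[i, ]), "0", ifelse(g[i, ] == 2, map$allele2, map$allele1))
    out[i] <- paste(panel$sample_ids[i], panel$sample_ids[i], "0", "0", "0", "-9",
                    paste(rbind(first, second), collapse = " "))
  }
  writeLines(out, ped_path)
  invisible(c(map_path, ped_path))
}

#' Read phased haplotypes from a VCF file
#'
#' Accepts biallelic records with fully phased GT fields (`|` separator).
#' Unphased (`/`) or missing (`.`) genotypes are rejected: the scan's
#' haplotype statistics require complete phased input, so incompleteness is
#' an error rather than something to impute silently.
#'
#' @param vcf_path Path to a VCF (plain text or bgzipped).
#' @return A [haplotype_panel()]; `allele1` is REF, `allele2` is ALT, and the
#'   haplotype matrix stores ALT indicators.
#' @export
read_phased_vcf <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- v@fix
  if (any(grepl(",", fix[, "ALT"]))) {
    bad <- fix[grepl(",", fix[, "ALT"]), "ID"][1]
    stop("multiallelic record not supported: ", bad, call. = FALSE)
  }
  gt <- v@gt[, -1, drop = FALSE]
  sample_ids <- colnames(gt)
  # FORMAT may carry more than GT; keep the leading GT token
  gt[] <- sub(":.*$", "", gt)
  if (anyNA(gt)) {
    idx <- which(is.na(gt), arr.ind = TRUE)[1, ]
    stop("missing genotype at record ", fix[idx[1], "ID"],
         "; phased input must be complete", call. = FALSE)
  }
  unphased <- array(grepl("/", gt, fixed = TRUE), dim = dim(gt))
  if (any(unphased)) {
    idx <- which(unphased, arr.ind = TRUE)[1, ]
    stop("unphased genotype at record ", fix[idx[1], "ID"], " sample ",
         sample_ids[idx[2]], call. = FALSE)
  }
  absent <- array(grepl(".", gt, fixed = TRUE), dim = dim(gt))
  if (any(absent)) {
    idx <- which(absent, arr.ind = TRUE)[1, ]
    stop("missing genotype at record ", fix[idx[1], "ID"],
         "; phased input must be complete", call. = FALSE)
  }
  m <- nrow(fix)
  n <- length(sample_ids)
  h1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = m)
  h2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = m)
  if (anyNA(h1) || anyNA(h2) || any(h1 > 1) || any(h2 > 1)) {
    stop("GT fields must be phased biallelic 0|0, 0|1, 1|0 or 1|1", call. = FALSE)
  }
  haps <- matrix(0L, nrow = 2L * n, ncol = m)
  haps[seq(1, 2 * n, by = 2), ] <- t(h1)
  haps[seq(2, 2 * n, by = 2), ] <- t(h2)
  map <- tibble::tibble(chrom = fix[, "CHROM"], bp = as.integer(fix[, "POS"]),
                        snp_id = fix[, "ID"],
                        allele1 = fix[, "REF"], allele2 = fix[, "ALT"])
  ord <- order(map$chrom, map$bp)
  haplotype_panel(map[ord, ], haps[, ord, drop = FALSE], sample_ids)
}

#' Write a haplotype panel as a phased VCF 4.2 file
#'
#' @param haps A [haplotype_panel()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(haps, path) {
  map <- haps$map
  n <- length(haps$sample_ids)
  h1 <- haps$haplotypes[seq(1, 2 * n, by = 2), , drop = FALSE]
  h2 <- haps$haplotypes[seq(2, 2 * n, by = 2), , drop = FALSE]
  gt <- matrix(paste0(t(h1), "|", t(h2)), nrow = nrow(map))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", haps$sample_ids), collapse = "\t"))
  body <- paste(map$chrom, as.integer(map$bp), map$snp_id, map$allele1,
                map$allele2, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Quality-control filtering of a SNP panel
#'
#' Applies the standard array-QC rules in a fixed order: (1) keep only the
#' requested chromosomes, (2) drop samples whose missing fraction exceeds
#' `max_sample_missing`, (3) drop SNPs whose per-SNP missing fraction exceeds
#' `max_snp_missing`, (4) drop SNPs with minor allele frequency below
#' `min_maf` computed on the remaining samples. The order matters — sample
#' filtering changes per-SNP call rates and frequencies — and is fixed here
#' (samples before variants) so results are reproducible.
#'
#' @param panel A [snp_panel()].
#' @param max_sample_missing Maximum tolerated per-sample missing fraction
#'   (default 0.10).
#' @param min_maf Minimum minor allele frequency (default 0.01).
#' @param keep_chroms Character vector of chromosome ids to keep, or `NULL`
#'   to keep all. For a dog panel this is typically `as.character(1:38)`.
#' @param max_snp_missing Maximum tolerated per-SNP missing fraction
#'   (default 0.10).
#' @return A new, filtered [snp_panel()]; the input is never modified.
#' @export
filter_qc <- function(panel, max_sample_missing = 0.1, min_maf = 0.01,
                      keep_chroms = NULL, max_snp_missing = 0.1) {
  stopifnot(inherits(panel, "snp_panel"))
  g <- panel$genotypes
  map <- panel$map
  ids <- panel$sample_ids

  if (!is.null(keep_chroms)) {
    keep <- map$chrom %in% as.character(keep_chroms)
    map <- map[keep, ]
    g <- g[, keep, drop = FALSE]
  }
  if (ncol(g)) {
    keep_s <- rowMeans(is.na(g)) <= max_sample_missing
    g <- g[keep_s, , drop = FALSE]
    ids <- ids[keep_s]
  }
  if (nrow(g)) {
    keep_v <- colMeans(is.na(g)) <= max_snp_missing
    map <- map[keep_v, ]
    g <- g[, keep_v, drop = FALSE]
  }
  if (nrow(g) && ncol(g)) {
    called <- colSums(!is.na(g))
    freq2 <- colSums(g, na.rm = TRUE) / (2 * called)
    maf <- pmin(freq2, 1 - freq2)
    maf[called == 0] <- 0
    keep_v <- maf >= min_maf
    map <- map[keep_v, ]
    g <- g[, keep_v, drop = FALSE]
  }
  if (!nrow(g) || !ncol(g)) stop("no data after QC", call. = FALSE)
  snp_panel(map, g, ids)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Harmonize allele encodings between two SNP panels
#'
#' Restricts both panels to their shared SNP ids and reconciles panel B's
#' allele encoding with panel A's: strand flips (B's alleles are the
#' base-complement of A's) are complemented, allele swaps (allele1 and
#' allele2 interchanged) are recoded `g -> 2 - g`, and combinations of both
#' are handled. Strand-ambiguous sites (A/T or C/G pairs) are always dropped
#' — for these the flip and the swap are indistinguishable without array
#' manifest information, so keeping them risks silently inverting allele
#' frequencies. Sites whose alleles cannot be reconciled at all are dropped
#' as mismatches.
#'
#' @param panel_a,panel_b Two [snp_panel()] objects sharing SNP ids.
#' @return A list with the two harmonized panels (`panel_a`, `panel_b`,
#'   restricted to retained shared SNPs, B re-encoded to A's orientation) and
#'   `flip_report`, a tibble of `snp_id` and the `action` taken
#'   (kept / flipped / swapped / flipped_swapped / dropped_ambiguous /
#'   dropped_mismatch).
#' @export
harmonize_alleles <- function(panel_a, panel_b) {
  shared <- intersect(panel_a$map$snp_id, panel_b$map$snp_id)
  if (!length(shared)) stop("no shared SNP ids between panels", call. = FALSE)
  ia <- match(shared, panel_a$map$snp_id)
  ib <- match(shared, panel_b$map$snp_id)
  a1 <- panel_a$map$allele1[ia]; a2 <- panel_a$map$allele2[ia]
  b1 <- panel_b$map$allele1[ib]; b2 <- panel_b$map$allele2[ib]

  ambiguous <- a2 == unname(COMPLEMENT[a1])
  same <- b1 == a1 & b2 == a2
  flip <- b1 == unname(COMPLEMENT[a1]) & b2 == unname(COMPLEMENT[a2])
  swap <- b1 == a2 & b2 == a1
  flip_swap <- b1 == unname(COMPLEMENT[a2]) & b2 == unname(COMPLEMENT[a1])

  action <- rep("dropped_mismatch", length(shared))
  action[same] <- "kept"
  action[flip & !same] <- "flipped"
  action[swap & !same] <- "swapped"
  action[flip_swap & !same & !flip & !swap] <- "flipped_swapped"
  action[ambiguous] <- "dropped_ambiguous"

  report <- tibble::tibble(snp_id = shared, action = action)
  retained <- !(action %in% c("dropped_ambiguous", "dropped_mismatch"))
  if (!any(retained)) stop("no sites retained after harmonization", call. = FALSE)

  keep_ids <- shared[retained]
  act <- action[retained]
  ga <- panel_a$genotypes[, ia[retained], drop = FALSE]
  gb <- panel_b$genotypes[, ib[retained], drop = FALSE]
  recode <- act %in% c("swapped", "flipped_swapped")
  gb[, recode] <- 2L - gb[, recode, drop = FALSE]

  map_a <- panel_a$map[ia[retained], ]
  map_b <- map_a  # B adopts A's encoding wholesale
  out_a <- snp_panel(map_a, ga, panel_a$sample_ids)
  out_b <- snp_panel(map_b, gb, panel_b$sample_ids)
  list(panel_a = out_a, panel_b = out_b, flip_report = report)
}

#' Subset a panel to the samples of one population group
#'
#' @param panel A [snp_panel()] or [haplotype_panel()].
#' @param pop_spec Tibble mapping `sample_id` to `group` (and optionally
#'   `role`).
#' @param group Group label to keep.
#' @return A panel of the same class restricted to the group's samples, in
#'   their original order; SNP columns are untouched.
#' @export
subset_samples <- function(panel, pop_spec, group) {
  pop_spec <- tibble::as_tibble(pop_spec)
  if (!group %in% pop_spec$group) {
    stop("unknown group: ", group, call. = FALSE)
  }
  members <- pop_spec$sample_id[pop_spec$group == group]
  keep <- panel$sample_ids %in% members
  if (!any(keep)) stop("group ", group, " has no samples in the panel", call. = FALSE)
  if (inherits(panel, "snp_panel")) {
    snp_panel(panel$map, panel$genotypes[keep, , drop = FALSE],
              panel$sample_ids[keep])
  } else if (inherits(panel, "haplotype_panel")) {
    rows <- rep(which(keep), each = 2) * 2L - c(1L, 0L)
    haplotype_panel(panel$map, panel$haplotypes[rows, , drop = FALSE],
                    panel$sample_ids[keep])
  } else {
    stop("unsupported panel class", call. = FALSE)
  }
}

#' Read / write a sample-to-population table
#'
#' Tab-separated with columns `sample_id`, `group`, `role`; `role` marks each
#' group as `target`, `reference` or `ancestral`.
#'
#' @param path File path.
#' @return `read_pop_spec()` returns the tibble; the writer returns `path`
#'   invisibly.
#' @export
read_pop_spec <- function(path) {
  spec <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  stopifnot(all(c("sample_id", "group") %in% names(spec)))
  if (anyDuplicated(spec$sample_id)) {
    stop("each sample must belong to exactly one group", call. = FALSE)
  }
  spec
}

#' @rdname read_pop_spec
#' @param pop_spec Tibble to write.
#' @export
write_pop_spec <- function(pop_spec, path) {
  readr::write_tsv(tibble::as_tibble(pop_spec), path)
  invisible(path)
}
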