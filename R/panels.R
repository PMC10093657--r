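#' SNP panel: marker map plus diploid genotype matrix
#'
#' The central genotype container. `map` is one row per SNP, sorted by
#' `(chrom, bp)`; `genotypes` is a samples x SNPs integer matrix counting
#' copies of `allele2` (0, 1, 2), with `NA` for missing calls. The allele2
#' orientation is the single source of truth for every downstream frequency:
#' Fst, DAF and haplotype coding all count allele2, so results are
#' orientation-consistent across modules.
#'
#' @param map Data frame with columns `chrom`, `bp` (1-based position),
#'   `snp_id`, `allele1`, `allele2`. Alleles must be distinct single bases
#'   in A/C/G/T.
#' @param genotypes Integer matrix, samples in rows, SNPs in columns, values
#'   in `{0, 1, 2, NA}`.
#' @param sample_ids Character vector, one id per genotype row.
#' @return An object of class `snp_panel`.
#' @examples
#' map <- tibble::tibble(chrom = 1L, bp = c(100L, 200L),
#'                       snp_id = c("s1", "s2"),
#'                       allele1 = c("A", "C"), allele2 = c("G", "T"))
#' g <- matrix(c(0L, 1L, 2L, NA), nrow = 2)
#' snp_panel(map, g, c("dog1", "dog2"))
#' @export
snp_panel <- function(map, genotypes, sample_ids) {
  map <- tibble::as_tibble(map)
  stopifnot(all(c("chrom", "bp", "snp_id", "allele1", "allele2") %in% names(map)))
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(map) != ncol(genotypes)) {
    stop("map has ", nrow(map), " SNPs but genotype matrix has ",
         ncol(genotypes), " columns", call. = FALSE)
  }
  if (length(sample_ids) != nrow(genotypes)) {
    stop("sample_ids length does not match genotype rows", call. = FALSE)
  }
  ord <- order(map$chrom, map$bp)
  if (is.unsorted(ord) || any(ord != seq_along(ord))) {
    map <- map[ord, ]
    genotypes <- genotypes[, ord, drop = FALSE]
  }
  if (anyDuplicated(map[c("chrom", "bp")])) {
    stop("duplicate (chrom, bp) positions in map", call. = FALSE)
  }
  bad <- map$allele1 == map$allele2 |
    !(map$allele1 %in% c("A", "C", "G", "T")) |
    !(map$allele2 %in% c("A", "C", "G", "T"))
  if (any(bad)) {
    stop("invalid allele pair at SNP(s): ",
         paste(utils::head(map$snp_id[bad], 5), collapse = ", "), call. = FALSE)
  }
  ok <- genotypes %in% c(0L, 1L, 2L, NA_integer_)
  if (!all(ok)) stop("genotype values must be 0, 1, 2 or NA", call. = FALSE)
  structure(
    list(map = map, genotypes = genotypes, sample_ids = as.character(sample_ids)),
    class = "snp_panel"
  )
}

#' Phased haplotype panel aligned to a SNP map
#'
#' Holds phased haplotypes as a (2 x samples) x SNPs binary matrix of allele2
#' indicators. Rows `2i - 1` and `2i` are the two haplotypes of sample `i`,
#' in the same sample order as the genotype panel the haplotypes came from.
#' Haplotypes carry no missing values: phased input must be complete.
#'
#' @param map As in [snp_panel()].
#' @param haplotypes Integer 0/1 matrix with `2 * length(sample_ids)` rows.
#' @param sample_ids Character vector of diploid sample ids.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(map, haplotypes, sample_ids) {
  map <- tibble::as_tibble(map)
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (nrow(haplotypes) != 2L * length(sample_ids)) {
    stop("haplotype matrix must have two rows per sample", call. = FALSE)
  }
  if (nrow(map) != ncol(haplotypes)) {
    stop("map/haplotype dimension mismatch", call. = FALSE)
  }
  if (anyNA(haplotypes) || !all(haplotypes %in% c(0L, 1L))) {
    stop("haplotypes must be complete 0/1 indicators", call. = FALSE)
  }
  structure(
    list(map = map, haplotypes = haplotypes, sample_ids = as.character(sample_ids)),
    class = "haplotype_panel"
  )
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("<snp_panel> ", length(x$sample_ids), " samples x ", nrow(x$map),
      " SNPs on ", length(unique(x$map$chrom)), " chromosome(s)\n", sep = "")
  miss <- mean(is.na(x$genotypes))
  cat("  missing genotype fraction: ", format(round(miss, 4)), "\n", sep = "")
  invisible(x)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", nrow(x$haplotypes), " haplotypes (",
      length(x$sample_ids), " diploids) x ", nrow(x$map), " SNPs\n", sep = "")
  invisible(x)
}

#' Number of SNPs / samples in a panel
#' @param x A `snp_panel` or `haplotype_panel`.
#' @return Integer count.
#' @export
n_snps <- function(x) nrow(x$map)

#' @rdname n_snps
#' @export
n_samples <- function(x) length(x$sample_ids)

# consistency check used by tests and run_scan: both panels describe the same loci
assert_same_map <- function(a, b, what = "panels") {
  if (!identical(a$map[c("chrom", "bp", "snp_id")], b$map[c("chrom", "bp", "snp_id")])) {
    stop("SNP maps of the two ", what, " do not match", call. = FALSE)
  }
  invisible(TRUE)
}
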