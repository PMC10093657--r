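#' Run the full composite selection-signals scan
#'
#' End-to-end orchestration: allele counts for the three populations,
#' per-SNP Weir-Cockerham Fst (target vs reference), ancestral assignment
#' from the outgroup and deltaDAF with z-scoring, the XP-EHH haplotype scan,
#' the rank-based CSS combination with smoothing and significance calling,
#' region merging, and (optionally) gene annotation. Deterministic given its
#' inputs: no randomness is used anywhere in the scan itself.
#'
#' @param target,reference,ancestral [snp_panel()] objects over the same SNP
#'   map: the population under test, the comparison population, and the
#'   outgroup whose major allele polarizes derived alleles.
#' @param haps_target,haps_reference Phased [haplotype_panel()] objects over
#'   the same map.
#' @param genes Optional [read_gene_annotation()] tibble.
#' @param config A [css_config()].
#' @param cutoff,max_extend_bp,gap_cap_bp XP-EHH scan parameters, see
#'   [xpehh_scan()].
#' @param merge_gap_bp Region merge gap, see [call_regions()].
#' @param flank_bp Gene-attachment flank, see [overlap_genes()].
#' @param out_dir Optional directory; when given, the per-SNP track
#'   (`css_snps.tsv`), the region table (`css_regions.tsv`) and the run
#'   parameters (`params.tsv`) are written there.
#' @return A `css_scan` object: list with `snps` (the [css_track()] tibble
#'   joined with all component columns), `regions`, and `params`.
#' @examples
#' sim <- simulate_panel(sim_config(n_snps = 300, n_target = 15,
#'                                  n_reference = 15, n_ancestral = 10,
#'                                  chrom_lengths = c("1" = 5e6), seed = 7))
#' scan <- run_scan(sim$panels$target, sim$panels$reference,
#'                  sim$panels$ancestral, sim$haplotypes$target,
#'                  sim$haplotypes$reference)
#' glance(scan)
#' @export
run_scan <- function(target, reference, ancestral, haps_target, haps_reference,
                     genes = NULL, config = css_config(),
                     cutoff = 0.05, max_extend_bp = 1e6, gap_cap_bp = 2e5,
                     merge_gap_bp = 1e6, flank_bp = 0, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  stage("input-check", {
    assert_same_map(target, reference)
    assert_same_map(target, ancestral)
    assert_same_map(target, haps_target)
    assert_same_map(haps_target, haps_reference)
  })

  counts_t <- stage("allele_stats", count_alleles(target))
  counts_r <- stage("allele_stats", count_alleles(reference))
  counts_o <- stage("allele_stats", count_alleles(ancestral))

  fst <- stage("allele_stats", weir_cockerham_fst(counts_t, counts_r))
  anc <- stage("allele_stats", assign_ancestral(counts_o))
  ddaf <- stage("allele_stats", delta_daf(counts_t, counts_r, anc))
  ddaf$ddaf_z <- stage("allele_stats",
                       zscore_ddaf(ddaf$ddaf, ddaf$valid_ddaf))

  xp <- stage("haplotype_stats",
              xpehh_scan(haps_target, haps_reference, cutoff = cutoff,
                         max_extend_bp = max_extend_bp,
                         gap_cap_bp = gap_cap_bp))

  components <- fst |>
    dplyr::left_join(ddaf[c("snp_id", "ddaf", "ddaf_z", "valid_ddaf")],
                     by = "snp_id") |>
    dplyr::left_join(xp[c("snp_id", "ihh_target", "ihh_reference",
                          "xpehh_raw", "xpehh_norm", "valid_xpehh")],
                     by = "snp_id")

  track <- stage("css_core", css_track(components, config = config))
  regions <- stage("regions_report", call_regions(track, merge_gap_bp))
  if (!is.null(genes)) {
    regions <- stage("regions_report", overlap_genes(regions, genes, flank_bp))
  }

  params <- tibble::tibble(
    parameter = c("m", "smooth_flank_bp", "top_fraction", "secondary_fraction",
                  "invalid_policy", "xpehh_cutoff", "xpehh_max_extend_bp",
                  "xpehh_gap_cap_bp", "merge_gap_bp", "gene_flank_bp"),
    value = as.character(c(config$m, config$smooth_flank_bp,
                           config$top_fraction, config$secondary_fraction,
                           config$invalid_policy, cutoff, max_extend_bp,
                           gap_cap_bp, merge_gap_bp, flank_bp))
  )

  result <- structure(list(snps = track, regions = regions, params = params),
                      class = "css_scan")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(dplyr::select(tibble::as_tibble(track), -dplyr::any_of("genes")),
                     file.path(out_dir, "css_snps.tsv"))
    write_region_table(regions, file.path(out_dir, "css_regions.tsv"))
    readr::write_tsv(params, file.path(out_dir, "params.tsv"))
  }
  result
}

#' Compare called regions against a truth set of sweep intervals
#'
#' @param regions A [call_regions()] tibble.
#' @param truth Tibble with `chrom`, `start_bp`, `end_bp` (as produced by
#'   [simulate_panel()]).
#' @return `regions` with a logical `overlaps_truth` column.
#' @export
truth_overlap <- function(regions, truth) {
  truth <- tibble::as_tibble(truth)
  regions$overlaps_truth <- purrr::pmap_lgl(
    regions[c("chrom", "start_bp", "end_bp")],
    function(chrom, start_bp, end_bp) {
      any(truth$chrom == chrom & truth$end_bp >= start_bp &
            truth$start_bp <= end_bp)
    })
  regions
}

#' @export
print.css_scan <- function(x, ...) {
  cat("<css_scan> ", nrow(x$snps), " SNPs, ",
      sum(x$snps$significant), " significant, ",
      nrow(x$regions), " region(s)\n", sep = "")
  if (nrow(x$regions)) print(tibble::as_tibble(x$regions), n = 10)
  invisible(x)
}

#' Tidy the per-SNP track of a scan
#'
#' @param x A `css_scan`.
#' @param ... Unused.
#' @return The per-SNP tibble.
#' @importFrom generics tidy
#' @export
#' @method tidy css_scan
tidy.css_scan <- function(x, ...) tibble::as_tibble(x$snps)

#' One-row summary of a scan
#'
#' @param x A `css_scan`.
#' @param ... Unused.
#' @return Tibble with SNP/region counts and the significance threshold
#'   actually realised (the smallest smoothed CSS among flagged SNPs).
#' @importFrom generics glance
#' @export
#' @method glance css_scan
glance.css_scan <- function(x, ...) {
  tibble::tibble(
    n_snps = nrow(x$snps),
    n_significant = sum(x$snps$significant),
    n_regions = nrow(x$regions),
    css_threshold = if (any(x$snps$significant)) {
      min(x$snps$css_smooth[x$snps$significant])
    } else NA_real_,
    max_css_smooth = max(x$snps$css_smooth)
  )
}

#' @export
generics::tidy

#' @export
generics::glance
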