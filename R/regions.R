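#' Merge significant SNPs into candidate selection regions
#'
#' Significant SNPs on the same chromosome whose successive gaps are at most
#' `merge_gap_bp` apart are merged into one region. A region spans its first
#' to last significant SNP (1-based inclusive, SNP-delimited — not window
#' edges). `avg_css` is the mean smoothed CSS over the *significant* SNPs in
#' the region; `n_snps` counts every panel SNP inside the span and
#' `n_significant` the flagged ones. `merge_gap_bp` is the one knob that
#' changes region counts; its default of 1 Mb matches the effective scale of
#' the 0.5 Mb-flank smoothing window.
#'
#' @param track A [css_track()] tibble.
#' @param merge_gap_bp Maximum gap between successive significant SNPs
#'   merged into one region (default 1 Mb).
#' @return A `css_regions` tibble sorted by `(chrom, start_bp)` with columns
#'   `chrom`, `start_bp`, `end_bp`, `avg_css`, `n_significant`, `n_snps`.
#' @export
call_regions <- function(track, merge_gap_bp = 1e6) {
  track <- dplyr::arrange(tibble::as_tibble(track), .data$chrom, .data$bp)
  sig <- track[track$significant, ]
  if (!nrow(sig)) {
    out <- tibble::tibble(chrom = character(), start_bp = numeric(),
                          end_bp = numeric(), avg_css = numeric(),
                          n_significant = integer(), n_snps = integer())
    class(out) <- c("css_regions", class(out))
    return(out)
  }
  new_region <- c(TRUE, sig$chrom[-1] != sig$chrom[-nrow(sig)] |
                    diff(sig$bp) > merge_gap_bp)
  sig$region_id <- cumsum(new_region)
  out <- sig |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(chrom = dplyr::first(.data$chrom),
                     start_bp = min(.data$bp), end_bp = max(.data$bp),
                     avg_css = mean(.data$css_smooth),
                     n_significant = dplyr::n(), .groups = "drop") |>
    dplyr::select(-"region_id")
  out$n_snps <- purrr::pmap_int(out, function(chrom, start_bp, end_bp, ...) {
    sum(track$chrom == chrom & track$bp >= start_bp & track$bp <= end_bp)
  })
  out <- dplyr::arrange(out, .data$chrom, .data$start_bp)
  class(out) <- c("css_regions", class(out))
  out
}

#' Read gene annotation from a BED or GFF3 file
#'
#' Coordinates are normalized to 1-based inclusive internally: BED input
#' (0-based half-open) has 1 added to its starts, GFF3 is used as-is. Uses
#' rtracklayer when installed; otherwise falls back to a plain tabular read
#' of the two fixed formats.
#'
#' @param path Annotation file; format inferred from the extension unless
#'   given.
#' @param format `"bed"` or `"gff3"`.
#' @return A tibble with `gene_id`, `chrom`, `start_bp`, `end_bp`, `biotype`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
    md <- as.data.frame(gr)
    gene_id <- if (!is.null(md$Name)) md$Name
      else if (!is.null(md$name)) md$name
      else if (!is.null(md$gene_id)) md$gene_id
      else if (!is.null(md$ID)) md$ID
      else paste0("gene_", seq_len(nrow(md)))
    biotype <- if (!is.null(md$biotype)) md$biotype
      else if (!is.null(md$gene_biotype)) md$gene_biotype
      else NA_character_
    out <- tibble::tibble(gene_id = as.character(gene_id),
                          chrom = as.character(md$seqnames),
                          start_bp = md$start, end_bp = md$end,
                          biotype = as.character(biotype))
  } else if (format == "bed") {
    raw <- utils::read.table(path, header = FALSE, sep = "\t",
                             colClasses = "character")
    out <- tibble::tibble(
      gene_id = if (ncol(raw) >= 4) raw[[4]] else paste0("gene_", seq_len(nrow(raw))),
      chrom = raw[[1]],
      start_bp = as.numeric(raw[[2]]) + 1,  # BED is 0-based half-open
      end_bp = as.numeric(raw[[3]]),
      biotype = NA_character_
    )
  } else {
    raw <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                             colClasses = "character", quote = "")
    attr_field <- raw[[9]]
    grab <- function(key) {
      m <- regmatches(attr_field, regexpr(paste0(key, "=[^;]+"), attr_field))
      out <- rep(NA_character_, length(attr_field))
      hit <- grepl(paste0(key, "="), attr_field)
      out[hit] <- sub(paste0("^.*", key, "="), "",
                      regmatches(attr_field, regexpr(paste0(key, "=[^;]+"),
                                                     attr_field)))
      out
    }
    ids <- grab("ID")
    names_ <- grab("Name")
    out <- tibble::tibble(
      gene_id = ifelse(is.na(names_), ids, names_),
      chrom = raw[[1]],
      start_bp = as.numeric(raw[[4]]), end_bp = as.numeric(raw[[5]]),
      biotype = grab("biotype")
    )
  }
  bad <- !(out$start_bp < out$end_bp)
  if (any(bad)) {
    stop("malformed gene interval: ", out$gene_id[bad][1], call. = FALSE)
  }
  dplyr::arrange(out, .data$chrom, .data$start_bp)
}

#' Attach overlapping genes to called regions
#'
#' A gene is attached to a region when its interval intersects the region
#' span widened by `flank_bp` on each side (all coordinates 1-based
#' inclusive). `flank_bp = 0` restricts to genuine overlap; a positive flank
#' also captures genes immediately adjacent to a region. Per-region biotype
#' tallies are summarised in a display string.
#'
#' @param regions A [call_regions()] tibble.
#' @param genes A [read_gene_annotation()] tibble.
#' @param flank_bp Extension of each region on both sides (default 0).
#' @return `regions` with list-column `genes` (a tibble per region),
#'   `n_genes`, and `gene_summary`.
#' @export
overlap_genes <- function(regions, genes, flank_bp = 0) {
  genes <- tibble::as_tibble(genes)
  bad <- !(genes$start_bp <= genes$end_bp)
  if (any(bad)) stop("malformed gene interval: ", genes$gene_id[bad][1],
                     call. = FALSE)
  hits <- purrr::pmap(regions[c("chrom", "start_bp", "end_bp")],
                      function(chrom, start_bp, end_bp) {
    sel <- genes$chrom == chrom &
      genes$end_bp >= start_bp - flank_bp &
      genes$start_bp <= end_bp + flank_bp
    genes[sel, ]
  })
  regions$genes <- hits
  regions$n_genes <- purrr::map_int(hits, nrow)
  regions$gene_summary <- purrr::map_chr(hits, function(g) {
    if (!nrow(g)) return("0 genes")
    tal <- table(ifelse(is.na(g$biotype), "unannotated", g$biotype))
    paste0(nrow(g), " genes (",
           paste(sprintf("%d %s", as.integer(tal), names(tal)), collapse = ", "),
           ")")
  })
  regions
}

#' Write the region summary table
#'
#' One row per region with the display columns Chromosome, Region (Mb span
#' to two decimals), Average of CSS, Number of Significant SNPs and Number
#' of SNPs, plus exact machine columns (`start_bp`, `end_bp`) and the gene
#' summary when present.
#'
#' @param regions A [call_regions()] (optionally [overlap_genes()]) tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, path) {
  disp <- tibble::tibble(
    Chromosome = regions$chrom,
    Region = sprintf("%.2f-%.2f Mb", regions$start_bp / 1e6,
                     regions$end_bp / 1e6),
    `Average of CSS` = round(regions$avg_css, 2),
    `Number of Significant SNPs` = regions$n_significant,
    `Number of SNPs` = regions$n_snps,
    start_bp = regions$start_bp,
    end_bp = regions$end_bp
  )
  if ("gene_summary" %in% names(regions)) disp$Genes <- regions$gene_summary
  readr::write_tsv(disp, path)
  invisible(path)
}
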