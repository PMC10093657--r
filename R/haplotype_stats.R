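#' Extended haplotype homozygosity decay from a core SNP
#'
#' Pooled-sample EHH in one direction: at extension `x`, the probability that
#' two haplotypes drawn at random from the population are identical over
#' every SNP from the core to `x` inclusive, computed as
#' `sum_g C(n_g, 2) / C(n, 2)` over the groups `g` of identical haplotypes.
#' No partition by core allele is made — this is the pooled convention used
#' by the cross-population statistic. The curve starts at (0, 1) and is
#' non-increasing by construction (extending the window can only refine the
#' identity groups). The walk stops when EHH drops below `cutoff`, at the
#' chromosome edge, or `max_extend_bp` from the core; in the latter two cases
#' the curve is flagged truncated.
#'
#' @param haps A [haplotype_panel()].
#' @param core Column index of the core SNP.
#' @param direction `"left"` or `"right"`.
#' @param cutoff EHH level below which extension stops (default 0.05).
#' @param max_extend_bp Maximum extension distance from the core in bp
#'   (default 1 Mb).
#' @return An `ehh_curve`: list with `core`, `direction`, `points` (tibble of
#'   `distance_bp`, `ehh`), `truncated`.
#' @export
ehh_at <- function(haps, core, direction = c("right", "left"),
                   cutoff = 0.05, max_extend_bp = 1e6) {
  direction <- match.arg(direction)
  h <- haps$haplotypes
  if (nrow(h) < 2) stop("need at least two haplotypes", call. = FALSE)
  map <- haps$map
  chrom <- map$chrom[core]
  on_chrom <- which(map$chrom == chrom)
  step <- if (direction == "right") 1L else -1L

  n <- nrow(h)
  # identity is over [core..x] inclusive, so groups start split by the core
  # allele; the distance-0 curve point is 1 by convention
  g <- h[, core] + 1L
  dist <- 0
  ehh <- 1
  truncated <- FALSE
  j <- core + step
  repeat {
    if (j < min(on_chrom) || j > max(on_chrom)) {
      truncated <- TRUE  # chromosome edge before the cutoff was reached
      break
    }
    d <- abs(map$bp[j] - map$bp[core])
    if (d > max_extend_bp) {
      truncated <- TRUE
      break
    }
    key <- g * 2L + h[, j]
    g <- match(key, unique(key))
    tab <- tabulate(g)
    e <- sum(tab * (tab - 1)) / (n * (n - 1))
    dist <- c(dist, d)
    ehh <- c(ehh, e)
    if (e < cutoff) break
    j <- j + step
  }
  structure(list(core = core, direction = direction,
                 points = tibble::tibble(distance_bp = dist, ehh = ehh),
                 truncated = truncated),
            class = "ehh_curve")
}

#' Integrated haplotype homozygosity from a pair of decay curves
#'
#' Trapezoidal integral of EHH over physical distance, left side plus right
#' side. Truncated curves are integrated as-is over the points they contain —
#' a core near a chromosome edge contributes its partial area, it is not
#' discarded. Steps wider than `gap_cap_bp` contribute at most `gap_cap_bp`
#' of width, so a single large inter-SNP gap cannot dominate the integral.
#'
#' @param curve_left,curve_right [ehh_at()] curves sharing the same core.
#' @param gap_cap_bp Per-step width cap in bp (default `Inf`: no cap).
#' @return Non-negative scalar iHH in bp.
#' @export
ihh <- function(curve_left, curve_right, gap_cap_bp = Inf) {
  if (curve_left$core != curve_right$core) {
    stop("curves have different cores", call. = FALSE)
  }
  side <- function(curve) {
    p <- curve$points
    if (!nrow(p)) stop("empty EHH curve", call. = FALSE)
    if (nrow(p) == 1) return(0)
    w <- pmin(diff(p$distance_bp), gap_cap_bp)
    sum(w * (p$ehh[-nrow(p)] + p$ehh[-1]) / 2)
  }
  side(curve_left) + side(curve_right)
}

#' Cross-population XP-EHH scan over a shared SNP map
#'
#' For every SNP as core, integrates the pooled-sample EHH decay of the
#' target and the reference population with *shared stopping*: both
#' integrals end at the extension where the EHH of the combined
#' two-population sample first falls below `cutoff` (or at the chromosome
#' edge / `max_extend_bp`, whichever comes first). The raw statistic is
#' `ln(iHH_target / iHH_reference)`; positive values mean longer haplotype
#' homozygosity in the target, the hallmark of a recent sweep there. Raw
#' scores are normalized genome-wide to mean 0, sd 1 over valid SNPs. A core
#' is invalid (rather than infinite) when either integral is zero.
#'
#' @param haps_target,haps_reference [haplotype_panel()] objects with
#'   identical SNP maps.
#' @param cutoff Pooled-EHH stopping threshold (default 0.05).
#' @param max_extend_bp Maximum extension from the core (default 1 Mb).
#' @param gap_cap_bp Maximum width a single inter-SNP gap may contribute to
#'   the integral (default 200 kb).
#' @return A tibble with `chrom`, `bp`, `snp_id`, `ihh_target`,
#'   `ihh_reference`, `xpehh_raw`, `xpehh_norm`, `valid_xpehh`.
#' @export
xpehh_scan <- function(haps_target, haps_reference, cutoff = 0.05,
                       max_extend_bp = 1e6, gap_cap_bp = 2e5) {
  assert_same_map(haps_target, haps_reference, "haplotype panels")
  map <- haps_target$map
  ihh_t <- numeric(nrow(map))
  ihh_r <- numeric(nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    res <- xpehh_chrom_cpp(haps_target$haplotypes[, idx, drop = FALSE],
                           haps_reference$haplotypes[, idx, drop = FALSE],
                           as.numeric(map$bp[idx]),
                           cutoff, max_extend_bp, gap_cap_bp)
    ihh_t[idx] <- res$ihh_t
    ihh_r[idx] <- res$ihh_r
  }
  valid <- ihh_t > 0 & ihh_r > 0
  raw <- ifelse(valid, log(ihh_t / ihh_r), NA_real_)
  norm <- rep(NA_real_, length(raw))
  if (sum(valid) >= 2 && stats::sd(raw[valid]) > 0) {
    norm[valid] <- (raw[valid] - mean(raw[valid])) / stats::sd(raw[valid])
  }
  tibble::tibble(chrom = map$chrom, bp = map$bp, snp_id = map$snp_id,
                 ihh_target = ihh_t, ihh_reference = ihh_r,
                 xpehh_raw = raw, xpehh_norm = norm, valid_xpehh = valid)
}
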