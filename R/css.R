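#' Configuration of the composite selection signals index
#'
#' @param m Number of component statistics combined (3 for Fst + deltaDAF +
#'   XP-EHH).
#' @param smooth_flank_bp One-sided smoothing window in bp; each SNP's score
#'   is averaged with every SNP within this distance on either side
#'   (default 500 kb, i.e. a 1 Mb total window).
#' @param top_fraction Fraction of SNPs, by smoothed score, declared
#'   significant (default 0.005).
#' @param secondary_fraction Stricter fraction reported alongside for
#'   reference only (default 0.001); it plays no role in region calling.
#' @param invalid_policy How a SNP with an invalid component value enters the
#'   ranking: `"zero"` (default) treats the value as 0 — null-neutral, so all
#'   components stay aligned on one SNP vector — while `"drop"` removes SNPs
#'   with any invalid component from the track entirely.
#' @return A `css_config` list.
#' @export
css_config <- function(m = 3, smooth_flank_bp = 5e5, top_fraction = 0.005,
                       secondary_fraction = 0.001,
                       invalid_policy = c("zero", "drop")) {
  stopifnot(m >= 1, top_fraction > 0, top_fraction < 1, smooth_flank_bp > 0)
  structure(list(m = as.integer(m), smooth_flank_bp = smooth_flank_bp,
                 top_fraction = top_fraction,
                 secondary_fraction = secondary_fraction,
                 invalid_policy = match.arg(invalid_policy)),
            class = "css_config")
}

#' Fractional ranks of a component statistic
#'
#' Ascending ranks (largest statistic gets the largest rank) over the valid
#' entries, average ranks for ties, scaled by `1 / (n_valid + 1)` so every
#' rank lies strictly inside (0, 1) and the inverse-normal transform stays
#' finite. An invalid entry receives the rank the value 0 would take against
#' the valid pool (its midrank), scaled the same way: invalid components are
#' null-neutral rather than dropping the whole SNP.
#'
#' @param values Numeric vector.
#' @param valid Logical vector; defaults to non-NA entries.
#' @return Numeric vector of ranks in (0, 1).
#' @export
fractional_rank <- function(values, valid = !is.na(values)) {
  x <- values[valid]
  n_valid <- length(x)
  if (n_valid == 0) stop("no valid values to rank", call. = FALSE)
  out <- numeric(length(values))
  out[valid] <- rank(x, ties.method = "average") / (n_valid + 1)
  if (any(!valid)) {
    # midrank of 0 inserted against the valid pool
    r0 <- sum(x < 0) + (sum(x == 0) + 1) / 2
    out[!valid] <- r0 / (n_valid + 1)
  }
  out
}

#' Inverse-normal transform of a fractional rank
#'
#' @param rank Numeric vector of ranks strictly in (0, 1).
#' @return Standard-normal quantiles.
#' @export
z_from_rank <- function(rank) {
  if (any(rank <= 0 | rank >= 1)) {
    stop("ranks must lie strictly inside (0, 1)", call. = FALSE)
  }
  stats::qnorm(rank)
}

#' Raw CSS score from per-SNP component z-scores
#'
#' The mean of the `m` rank-derived z-scores follows Normal(0, 1/m) under
#' the null of no selection. The CSS value is `-log10` of the upper-tail
#' probability of the observed mean — one-sided, because each component is
#' oriented so that selection in the target population pushes its rank, and
#' hence its z-score, upward. Computed on the log scale so extreme scores do
#' not underflow to `p = 0`.
#'
#' @param z_matrix Numeric matrix, SNPs in rows, one column per component
#'   z-score (or a vector of pre-averaged means with `m` supplied).
#' @param m Number of components; defaults to `ncol(z_matrix)`.
#' @return A tibble with `mean_z` and `css_raw`.
#' @export
css_score <- function(z_matrix, m = NULL) {
  if (is.matrix(z_matrix)) {
    if (is.null(m)) m <- ncol(z_matrix)
    mean_z <- rowMeans(z_matrix)
  } else {
    if (is.null(m)) stop("supply m when passing pre-averaged mean z", call. = FALSE)
    mean_z <- z_matrix
  }
  log_p <- stats::pnorm(mean_z * sqrt(m), lower.tail = FALSE, log.p = TRUE)
  tibble::tibble(mean_z = mean_z, css_raw = -log_p / log(10))
}

#' Smooth a per-SNP score with a symmetric physical window
#'
#' Each SNP's smoothed value is the mean of the raw scores of every SNP on
#' the same chromosome within `smooth_flank_bp` of it (inclusive on both
#' sides; the SNP itself always contributes). Windows never cross chromosome
#' boundaries. Positions must be sorted within chromosome.
#'
#' @param values Numeric vector of raw scores.
#' @param chrom,bp Chromosome ids and positions, sorted by `(chrom, bp)`.
#' @param smooth_flank_bp One-sided window half-width in bp.
#' @return Numeric vector of smoothed scores.
#' @export
smooth_scores <- function(values, chrom, bp, smooth_flank_bp = 5e5) {
  out <- numeric(length(values))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos <- bp[idx]
    if (is.unsorted(pos)) stop("positions must be sorted within chromosome",
                               call. = FALSE)
    v <- values[idx]
    cs <- c(0, cumsum(v))
    hi <- findInterval(pos + smooth_flank_bp, pos)
    lo <- findInterval(pos - smooth_flank_bp - 0.5, pos) + 1L
    out[idx] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

#' Flag the top fraction of smoothed scores as significant
#'
#' Exactly `ceiling(top_fraction * n)` SNPs are flagged — the ones with the
#' highest smoothed scores, ties at the threshold broken by genome order
#' (lowest `(chrom, bp)` first) so the count is exact and deterministic.
#'
#' @param css_smooth Numeric vector of smoothed scores.
#' @param chrom,bp Genome order keys for tie-breaking.
#' @param top_fraction Fraction to flag.
#' @return Logical mask.
#' @export
call_significant <- function(css_smooth, chrom, bp, top_fraction = 0.005) {
  n <- length(css_smooth)
  stopifnot(n >= 1)
  k <- ceiling(top_fraction * n)
  ord <- order(-css_smooth, chrom, bp)
  mask <- logical(n)
  mask[ord[seq_len(k)]] <- TRUE
  mask
}

#' Build the full composite selection signals track
#'
#' Runs the whole per-SNP construction: fractional ranking of each component
#' (Fst, deltaDAF z, normalized XP-EHH), inverse-normal z-scores, their mean,
#' the upper-tail `-log10 p` under Normal(0, 1/m), windowed smoothing, and
#' top-fraction significance calling. Because every component enters only
#' through its ranks, the track is invariant to any strictly increasing
#' transform of a component — which is why the deltaDAF z-scoring and the
#' XP-EHH normalization never change the result.
#'
#' @param components Tibble with `chrom`, `bp`, `snp_id` and one column per
#'   component statistic, e.g. `fst`, `ddaf_z`, `xpehh_norm`, plus matching
#'   `valid_*` columns (optional; `NA` means invalid).
#' @param component_cols Character vector naming the component columns.
#' @param config A [css_config()]; `m` defaults to the number of components.
#' @return A `css_track` tibble: the input keys plus `rank_*` and `z_*`
#'   per component, `mean_z`, `css_raw`, `css_smooth`, `significant`, and
#'   `significant_secondary` (the stricter report-only threshold).
#' @export
css_track <- function(components,
                      component_cols = c("fst", "ddaf_z", "xpehh_norm"),
                      config = css_config(m = length(component_cols))) {
  components <- tibble::as_tibble(components)
  stopifnot(all(c("chrom", "bp") %in% names(components)),
            all(component_cols %in% names(components)))
  components <- dplyr::arrange(components, .data$chrom, .data$bp)
  m <- length(component_cols)

  validity <- purrr::map(component_cols, function(col) {
    vcol <- paste0("valid_", sub("_z$|_norm$", "", col))
    v <- if (vcol %in% names(components)) components[[vcol]] else TRUE
    v & !is.na(components[[col]])
  })

  if (config$invalid_policy == "drop") {
    keep <- Reduce(`&`, validity)
    components <- components[keep, ]
    validity <- purrr::map(validity, `[`, keep)
  }

  ranks <- purrr::map2(component_cols, validity, function(col, v) {
    fractional_rank(components[[col]], v)
  })
  z <- purrr::map(ranks, z_from_rank)
  zmat <- do.call(cbind, z)
  scored <- css_score(zmat, m = m)

  out <- components[c("chrom", "bp",
                      intersect("snp_id", names(components)), component_cols)]
  for (i in seq_len(m)) {
    out[[paste0("rank_", component_cols[i])]] <- ranks[[i]]
    out[[paste0("z_", component_cols[i])]] <- z[[i]]
  }
  out$mean_z <- scored$mean_z
  out$css_raw <- scored$css_raw
  out$css_smooth <- smooth_scores(out$css_raw, out$chrom, out$bp,
                                  config$smooth_flank_bp)
  out$significant <- call_significant(out$css_smooth, out$chrom, out$bp,
                                      config$top_fraction)
  out$significant_secondary <- call_significant(out$css_smooth, out$chrom,
                                                out$bp,
                                                config$secondary_fraction)
  class(out) <- c("css_track", class(out))
  attr(out, "css_config") <- config
  out
}
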