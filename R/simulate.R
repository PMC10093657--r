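#' Specify a selective sweep to inject into a simulated panel
#'
#' A sweep is modelled by copying the segment of one randomly chosen target
#' haplotype over a fraction of all target haplotypes inside the interval,
#' which creates exactly the joint signal the scan looks for: a long shared
#' haplotype (XP-EHH), shifted allele frequencies relative to the reference
#' (Fst) and an excess of one allele relative to the outgroup-polarized
#' ancestral state (deltaDAF). The copied haplotype is an existing one, not a
#' novel allele, so ancestral polarization by the outgroup stays meaningful.
#'
#' @param chrom Chromosome id the sweep lies on.
#' @param start_bp,end_bp Sweep interval in base pairs, `start_bp < end_bp`.
#' @param carrier_fraction Fraction in (0, 1] of target haplotypes that carry
#'   the sweep haplotype after the overwrite.
#' @return A one-row tibble describing the sweep.
#' @export
sweep_spec <- function(chrom, start_bp, end_bp, carrier_fraction = 0.9) {
  if (!(start_bp < end_bp)) stop("start_bp must be < end_bp", call. = FALSE)
  if (!(carrier_fraction > 0 && carrier_fraction <= 1)) {
    stop("carrier_fraction must be in (0, 1]", call. = FALSE)
  }
  tibble::tibble(chrom = chrom, start_bp = as.numeric(start_bp),
                 end_bp = as.numeric(end_bp),
                 carrier_fraction = carrier_fraction)
}

#' Configuration for the synthetic diverged-population generator
#'
#' The generator draws, per SNP, a pool allele frequency `p ~ Uniform(0.05,
#' 0.95)` (avoiding rare-allele degeneracy; low-MAF behaviour is exercised by
#' deliberately injected sites in the QC tests, not here). The ancestral
#' (outgroup) population samples haplotypes at the pool frequency; target and
#' reference frequencies are drawn around it under a Balding-Nichols model,
#' `p_pop ~ Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` with drift parameter
#' `F = divergence_f`, so a larger `divergence_f` yields larger expected
#' between-population frequency variance and hence larger Weir-Cockerham Fst.
#' Sites are independent outside sweep intervals (no background LD): the
#' sweep-copying mechanism alone creates the extended shared haplotypes the
#' haplotype statistic responds to, and the exchangeable null makes the CSS
#' calibration exactly testable.
#'
#' @param n_snps Total SNP count, allocated to chromosomes proportionally to
#'   their lengths.
#' @param n_target,n_reference,n_ancestral Diploid sample counts.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp;
#'   names are chromosome ids.
#' @param divergence_f Drift parameter strictly in (0, 1).
#' @param sweeps Tibble of [sweep_spec()] rows (zero rows for a null panel).
#'   Sweep intervals must lie within their chromosome and not overlap.
#' @param missing_rate Fraction in \[0, 1) of genotype entries set to missing.
#'   Haplotypes are never masked.
#' @param seed Integer seed; identical configurations with the same seed
#'   produce byte-identical panels.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_snps = 5000, n_target = 50, n_reference = 50,
                       n_ancestral = 30, chrom_lengths = c("1" = 5e7),
                       divergence_f = 0.05, sweeps = NULL,
                       missing_rate = 0, seed = 1L) {
  counts <- c(n_snps, n_target, n_reference, n_ancestral)
  if (any(counts < 1)) stop("all counts must be positive", call. = FALSE)
  if (!(divergence_f > 0 && divergence_f < 1)) {
    stop("divergence_f must be strictly inside (0, 1)", call. = FALSE)
  }
  if (!(missing_rate >= 0 && missing_rate < 1)) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- as.character(seq_along(chrom_lengths))
  }
  if (is.null(sweeps)) {
    sweeps <- sweep_spec(1, 1, 2, 1)[0, ]
  }
  sweeps <- tibble::as_tibble(sweeps)
  if (nrow(sweeps)) {
    if (any(sweeps$carrier_fraction <= 0)) {
      stop("carrier_fraction must be > 0", call. = FALSE)
    }
    sweeps$chrom <- as.character(sweeps$chrom)
    unknown <- setdiff(sweeps$chrom, names(chrom_lengths))
    if (length(unknown)) {
      stop("sweep on unknown chromosome: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (any(sweeps$end_bp > chrom_lengths[sweeps$chrom]) || any(sweeps$start_bp < 1)) {
      stop("sweep interval outside its chromosome", call. = FALSE)
    }
    by_chr <- split(sweeps, sweeps$chrom)
    for (s in by_chr) {
      s <- s[order(s$start_bp), ]
      if (nrow(s) > 1 && any(s$start_bp[-1] <= s$end_bp[-nrow(s)])) {
        stop("sweep intervals overlap", call. = FALSE)
      }
    }
  }
  structure(list(n_snps = as.integer(n_snps), n_target = as.integer(n_target),
                 n_reference = as.integer(n_reference),
                 n_ancestral = as.integer(n_ancestral),
                 chrom_lengths = chrom_lengths,
                 divergence_f = divergence_f, sweeps = sweeps,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# positions drawn uniformly without replacement then sorted; duplicates
# impossible because sample() is without replacement over 1..L
draw_positions <- function(n, len) sort(sample.int(len, n, replace = FALSE))

sample_haps <- function(freqs, n_hap) {
  # one Bernoulli(freq) draw per haplotype and site, sites independent
  matrix(stats::rbinom(n_hap * length(freqs), 1L, rep(freqs, each = n_hap)),
         nrow = n_hap)
}

#' Simulate diverged SNP panels with known selective sweeps
#'
#' Generates phased haplotype and genotype panels for a target, a reference
#' and an ancestral (outgroup) population under the divergence model described
#' in [sim_config()], injects the configured sweeps into the target
#' population, and records their positions as a truth set for benchmarking.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{panels}{named list of [snp_panel()] objects (`target`,
#'       `reference`, `ancestral`), genotypes masked at `missing_rate`}
#'     \item{haplotypes}{named list of [haplotype_panel()] objects, unmasked}
#'     \item{truth}{tibble of sweep intervals (`chrom`, `start_bp`, `end_bp`),
#'       mirrored verbatim into BED records by [write_truth_bed()]}
#'     \item{pop_spec}{sample-to-population tibble with `sample_id`, `group`,
#'       `role` columns, for use with [subset_samples()]}
#'     \item{pool_freq}{the latent per-SNP pool allele2 frequency the
#'       populations were drawn around, kept for validation of the outgroup
#'       polarization}
#'   }
#' @examples
#' sim <- simulate_panel(sim_config(n_snps = 200, n_target = 10,
#'                                  n_reference = 10, n_ancestral = 10,
#'                                  chrom_lengths = c("1" = 1e6), seed = 42))
#' sim$panels$target
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- names(config$chrom_lengths)
  lens <- as.numeric(config$chrom_lengths)
  # proportional allocation, largest-remainder so the total is exact
  raw <- config$n_snps * lens / sum(lens)
  alloc <- floor(raw)
  rem <- config$n_snps - sum(alloc)
  if (rem > 0) {
    alloc[order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]] <-
      alloc[order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]] + 1
  }
  map <- purrr::map2_dfr(chroms, seq_along(chroms), function(ch, k) {
    tibble::tibble(chrom = ch, bp = draw_positions(alloc[k], lens[k]))
  })
  m <- nrow(map)
  map$snp_id <- paste0("snp_", map$chrom, "_", map$bp)
  # random distinct allele pairs; haplotype/genotype values count allele2
  pairs <- t(vapply(seq_len(m), function(i) sample(c("A", "C", "G", "T"), 2),
                    character(2)))
  map$allele1 <- pairs[, 1]
  map$allele2 <- pairs[, 2]

  p_pool <- stats::runif(m, 0.05, 0.95)
  f <- config$divergence_f
  shape_mult <- (1 - f) / f
  p_t <- stats::rbeta(m, p_pool * shape_mult, (1 - p_pool) * shape_mult)
  p_r <- stats::rbeta(m, p_pool * shape_mult, (1 - p_pool) * shape_mult)

  haps <- list(
    target = sample_haps(p_t, 2L * config$n_target),
    reference = sample_haps(p_r, 2L * config$n_reference),
    ancestral = sample_haps(p_pool, 2L * config$n_ancestral)
  )

  if (nrow(config$sweeps)) {
    n_hap_t <- 2L * config$n_target
    for (i in seq_len(nrow(config$sweeps))) {
      sw <- config$sweeps[i, ]
      in_sweep <- which(map$chrom == sw$chrom &
                          map$bp >= sw$start_bp & map$bp <= sw$end_bp)
      if (!length(in_sweep)) next
      donor <- sample.int(n_hap_t, 1)
      n_carrier <- min(n_hap_t, ceiling(sw$carrier_fraction * n_hap_t))
      carriers <- sample.int(n_hap_t, n_carrier)
      haps$target[carriers, in_sweep] <-
        matrix(haps$target[donor, in_sweep], nrow = n_carrier,
               ncol = length(in_sweep), byrow = TRUE)
    }
  }

  ids <- list(
    target = sprintf("tgt_%03d", seq_len(config$n_target)),
    reference = sprintf("ref_%03d", seq_len(config$n_reference)),
    ancestral = sprintf("anc_%03d", seq_len(config$n_ancestral))
  )

  genos <- purrr::map(haps, function(h) {
    h[seq(1, nrow(h), by = 2), , drop = FALSE] +
      h[seq(2, nrow(h), by = 2), , drop = FALSE]
  })
  if (config$missing_rate > 0) {
    genos <- purrr::map(genos, function(g) {
      mask <- matrix(stats::runif(length(g)) < config$missing_rate, nrow = nrow(g))
      g[mask] <- NA_integer_
      g
    })
  }

  panels <- purrr::map2(genos, ids, function(g, id) snp_panel(map, g, id))
  hpanels <- purrr::map2(haps, ids, function(h, id) haplotype_panel(map, h, id))

  truth <- tibble::tibble(chrom = as.character(config$sweeps$chrom),
                          start_bp = config$sweeps$start_bp,
                          end_bp = config$sweeps$end_bp)
  pop_spec <- tibble::tibble(
    sample_id = unlist(ids, use.names = FALSE),
    group = rep(names(ids), lengths(ids)),
    role = rep(c("target", "reference", "ancestral"), lengths(ids))
  )
  list(panels = panels, haplotypes = hpanels, truth = truth,
       pop_spec = pop_spec, pool_freq = p_pool)
}

#' Write sweep truth intervals as a BED file
#'
#' Coordinates are written exactly as recorded in the truth set, one line per
#' sweep, sorted by chromosome then start, in three-column BED layout
#' (0-based, half-open).
#'
#' @param truth Tibble with `chrom`, `start_bp`, `end_bp`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  truth <- tibble::as_tibble(truth)
  truth <- truth[order(truth$chrom, truth$start_bp), ]
  lines <- sprintf("%s\t%d\t%d", truth$chrom,
                   as.integer(truth$start_bp), as.integer(truth$end_bp))
  writeLines(lines, path)
  invisible(path)
}
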