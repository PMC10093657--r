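#' Manhattan-style plot of a CSS track
#'
#' Smoothed CSS against genome position, chromosomes in alternating shades,
#' significant SNPs highlighted and the realised significance threshold drawn
#' as a horizontal line.
#'
#' @param object A `css_track` tibble or a `css_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
#' @method autoplot css_track
autoplot.css_track <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- dplyr::arrange(d, .data$chrom, .data$bp)
  offsets <- d |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$bp), .groups = "drop") |>
    dplyr::mutate(offset = dplyr::lag(cumsum(.data$len), default = 0))
  d <- dplyr::left_join(d, offsets[c("chrom", "offset")], by = "chrom")
  d$gpos <- d$bp + d$offset
  d$shade <- factor(as.integer(factor(d$chrom)) %% 2)
  thr <- if (any(d$significant)) min(d$css_smooth[d$significant]) else NA_real_
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$gpos, y = .data$css_smooth)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$shade), size = 0.4,
                        show.legend = FALSE) +
    ggplot2::geom_point(data = d[d$significant, ], colour = "firebrick",
                        size = 0.7) +
    ggplot2::scale_colour_manual(values = c("grey55", "grey30")) +
    ggplot2::labs(x = "genome position (bp, chromosomes concatenated)",
                  y = "smoothed CSS") +
    ggplot2::theme_minimal()
  if (!is.na(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' @rdname autoplot.css_track
#' @export
#' @method autoplot css_scan
autoplot.css_scan <- function(object, ...) autoplot.css_track(object$snps, ...)

#' Plot an EHH decay curve
#'
#' @param object An [ehh_at()] curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot ehh_curve
autoplot.ehh_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$distance_bp, y = .data$ehh)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = paste0("distance from core (bp, ", object$direction, ")"),
                  y = "EHH") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
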