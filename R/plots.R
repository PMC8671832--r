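# Plotting helpers for interpretation results.

#' Plot the resolved regions of an SV along the chromosome
#'
#' Draws the brTAD, flanking TADs and remaining/explicit regions as
#' segments, with breakpoints as vertical lines, one facet per
#' chromosome.
#'
#' @param regions Region tibble from [regions_for_sv()].
#' @return A ggplot object.
#' @export
plot_regions <- function(regions) {
  bp <- regions[!is.na(regions$bp_pos) & !duplicated(regions$bp_pos), ]
  ggplot2::ggplot(regions) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$kind, yend = .data$kind,
                                       colour = factor(.data$offset)),
                          linewidth = 4) +
    ggplot2::geom_vline(data = bp, ggplot2::aes(xintercept = .data$bp_pos),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~chrom, scales = "free_x", ncol = 1) +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = "TAD offset") +
    ggplot2::theme_minimal()
}

#' @describeIn acmg_score Bar chart of the evidence points.
#' @param object A `tad_acmg` object.
#' @export
autoplot.tad_acmg <- function(object, ...) {
  ggplot2::ggplot(object$evidence,
                  ggplot2::aes(x = .data$criterion_id, y = .data$points)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "criterion",
                  y = "points",
                  title = sprintf("ACMG score %.2f (%s)", object$final_score,
                                  object$acmg_class)) +
    ggplot2::theme_minimal()
}

#' Plot phenotype-similarity results
#'
#' PhenSSc per disorder against the MaxSSc ceiling, shaded by
#' permutation p-value.
#'
#' @param object A `tad_phenosim` tibble from [phenosim()].
#' @param ... Unused.
#' @export
autoplot.tad_phenosim <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = stats::reorder(.data$disease_id,
                                                          .data$phenssc),
                                       y = .data$phenssc,
                                       fill = .data$p_value)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$maxssc),
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "PhenSSc (dashed: MaxSSc)", fill = "p") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
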