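# ggplot2 views of the stage outputs: z-score heatmaps, overlap-share pies,
# and dose-response curves. Numbers come from the stage functions; these
# only draw them.

#' Heatmap of per-stage z-scores
#'
#' Tile plot of subgroup z-scores per gene for one or all stages, the view
#' behind the expression-stage heatmaps.
#'
#' @param screen An [expression_screen()] result.
#' @param stage Optional stage subset.
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(screen, stage = NULL) {
  dat <- if (is.null(stage)) screen else dplyr::filter(screen, .data$stage %in% !!stage)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$subgroup, y = .data$gene,
                                    fill = .data$z_subgroup)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  name = "z") +
    ggplot2::facet_wrap(~stage) +
    ggplot2::labs(x = "subgroup", y = NULL) +
    ggplot2::theme_minimal()
}

#' Pie chart of DMR-by-mark overlap shares
#'
#' @param shares An [overlap_fraction_distribution()] result (optionally
#'   with a `cell_line` column for faceting).
#' @return A ggplot object.
#' @export
plot_overlap_shares <- function(shares) {
  p <- ggplot2::ggplot(shares, ggplot2::aes(x = "", y = .data$share_pct,
                                            fill = .data$mark)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::labs(x = NULL, y = "share of overlapping (DMR, mark) pairs [%]") +
    ggplot2::theme_minimal()
  if ("cell_line" %in% names(shares)) p <- p + ggplot2::facet_wrap(~cell_line)
  p
}

#' @describeIn fit_ic50 Dose-response curve with the fitted 4PL overlaid.
#' @param object A `ren_ic50_fit` object.
#' @export
autoplot.ren_ic50_fit <- function(object, ...) {
  grid <- tibble::tibble(conc = exp(seq(log(min(object$data$conc)),
                                        log(max(object$data$conc)),
                                        length.out = 200)))
  grid$viability <- object$bottom + (object$top - object$bottom) /
    (1 + (grid$conc / object$ic50)^object$hill)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc, y = .data$viability)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "concentration [uM]", y = "viability (fraction of untreated)",
      title = sprintf("IC50 = %.3g uM", object$ic50)
    ) +
    ggplot2::theme_minimal()
}
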