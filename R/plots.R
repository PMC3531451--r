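# ggplot2 views of the result types. Every plot draws only numbers that
# are present in the plotted object.

#' Bar chart of functional-class proportions
#'
#' @param props A [class_proportions()] tibble.
#' @return A ggplot object.
#' @export
plot_class_proportions <- function(props) {
  stopifnot(all(c("functional_class", "pct") %in% names(props)))
  ggplot2::ggplot(props, ggplot2::aes(
    x = stats::reorder(.data$functional_class, -.data$pct),
    y = .data$pct
  )) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$pct_display, "%")),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "% of identified spots",
                  title = "Functional classes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Fold-change plot of a differential classification
#'
#' Mean ppm against case/control ratio on log scales, with the fold
#' thresholds drawn and passing spots highlighted. Presence/absence calls
#' (infinite or zero ratio) are omitted from the panel.
#'
#' @param object A `gelprot_diff` from [classify_twofold()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.gelprot_diff <- function(object, ...) {
  fold <- attr(object, "fold") %||% 2
  dat <- object %>%
    filter(is.finite(.data$ratio) & .data$ratio > 0) %>%
    mutate(mean_ppm = (.data$case_ppm + .data$control_ppm) / 2)
  ggplot2::ggplot(dat, ggplot2::aes(.data$mean_ppm, .data$ratio,
                                    colour = .data$passes_twofold)) +
    ggplot2::geom_hline(yintercept = c(fold, 1 / fold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
      name = paste0(">= ", fold, "-fold")
    ) +
    ggplot2::labs(x = "mean abundance (ppm)",
                  y = "case / control ratio") +
    ggplot2::theme_minimal()
}

#' Spot map of a simulated scene
#'
#' Truth spot positions in (pI, MW) space, sized by baseline volume,
#' differential spots highlighted. The MW axis is reversed and
#' log-scaled, matching gel orientation.
#'
#' @param object A `gelprot_scene` from [simulate_gel_scene()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.gelprot_scene <- function(object, ...) {
  ggplot2::ggplot(object$truth, ggplot2::aes(
    .data$pi, .data$mw_kda, size = .data$base_volume,
    colour = .data$differential
  )) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_y_continuous(trans = c("log10", "reverse")) +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey40"),
      name = "differential"
    ) +
    ggplot2::labs(x = "pI", y = "MW (kDa)") +
    ggplot2::theme_minimal()
}

#' Raster view of a gel image
#'
#' @param image A gel-image matrix.
#' @param downsample Keep every n-th pixel (default 2) to bound plot size.
#' @return A ggplot object.
#' @export
plot_gel_image <- function(image, downsample = 2) {
  px <- unclass(image)
  rows <- seq(1, nrow(px), by = downsample)
  cols <- seq(1, ncol(px), by = downsample)
  dat <- tidyr::expand_grid(row = rows, col = cols)
  dat$value <- px[cbind(dat$row, dat$col)]
  ggplot2::ggplot(dat, ggplot2::aes(.data$col, .data$row,
                                    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 name = "OD") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "pI axis (px)", y = "MW axis (px)") +
    ggplot2::theme_minimal()
}
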