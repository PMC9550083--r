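#' Plot InDel density along chromosomes
#'
#' One panel per chromosome; bars give the InDel count per window.
#'
#' @param object An `indel_density` from [density_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.indel_density <- function(object, ...) {
  w <- object$windows
  ggplot2::ggplot(w, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                  y = .data$n)) +
    ggplot2::geom_col(width = object$window / 1e6, fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), ncol = 1,
                        strip.position = "right") +
    ggplot2::labs(x = "Position (Mb)",
                  y = sprintf("InDels per %g kb window", object$window / 1e3)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.indel_density
#' @export
plot_density <- function(object, ...) autoplot.indel_density(object, ...)

#' Plot the physical map of markers
#'
#' Chromosomes as bars with marker positions as ticks and labels.
#'
#' @param object A `physical_map` from [physical_map()].
#' @param label Draw marker names next to their positions.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.physical_map <- function(object, label = TRUE, ...) {
  chroms <- object$counts
  m <- object$markers
  chroms$x <- seq_len(nrow(chroms))
  m$x <- chroms$x[match(m$chrom, chroms$chrom)]
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = chroms,
      ggplot2::aes(x = .data$x, xend = .data$x, y = 0, yend = .data$length / 1e6),
      linewidth = 4, colour = "grey80", lineend = "round"
    ) +
    ggplot2::geom_segment(
      data = m,
      ggplot2::aes(x = .data$x - 0.12, xend = .data$x + 0.12,
                   y = .data$pos / 1e6, yend = .data$pos / 1e6),
      colour = "firebrick"
    ) +
    ggplot2::scale_x_continuous(breaks = chroms$x, labels = chroms$chrom) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "Position (Mb)") +
    ggplot2::theme_minimal()
  if (label && nrow(m)) {
    p <- p + ggplot2::geom_text(
      data = m,
      ggplot2::aes(x = .data$x + 0.15, y = .data$pos / 1e6,
                   label = .data$marker_name),
      hjust = 0, size = 2.5
    )
  }
  p
}

#' @rdname autoplot.physical_map
#' @export
plot_physical_map <- function(object, label = TRUE, ...) {
  autoplot.physical_map(object, label = label, ...)
}

#' Heatmap of a band matrix
#'
#' Varieties (grouped) by markers, scored band presence as fill; missing
#' entries are grey.
#'
#' @param object A `band_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.band_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(object, cols = dplyr::all_of(marker_cols(object)),
                              names_to = "marker", values_to = "band")
  long$variety <- factor(long$variety,
                         levels = object$variety[order(object$group)])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$marker, y = .data$variety,
                                     fill = factor(.data$band))) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(
      values = c(`0` = "wheat", `1` = "darkgreen"),
      na.value = "grey70", name = "band"
    ) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$group), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' @rdname autoplot.band_matrix
#' @export
plot_band_matrix <- function(object, ...) autoplot.band_matrix(object, ...)
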