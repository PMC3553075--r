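#' Plot the quadripartite layout of a genome
#'
#' Linearized region map (LSC, IRa, SSC, IRb) as stacked segments, the usual
#' quick look at relative region sizes across taxa.
#'
#' @param object a `quadripartite_partition`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.quadripartite_partition <- function(object, ...) {
  d <- tidy(object)
  d$length_plot <- d$length
  d$region <- factor(d$region, levels = c("LSC", "IRa", "SSC", "IRb"))
  d <- arrange(d, .data$region)
  d$xmin <- cumsum(c(0, head(d$length_plot, -1)))
  d$xmax <- d$xmin + d$length_plot
  ggplot2::ggplot(d) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = 0, ymax = 1, fill = .data$region)) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL) +
    ggplot2::labs(x = "position (bp, linearized)", fill = "region") +
    ggplot2::theme_minimal()
}

#' Plot per-placement Dollo loss totals from a placement scan
#'
#' @param object a `placement_scan`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.placement_scan <- function(object, ...) {
  d <- as_tibble(object)
  d$edge_short <- ifelse(d$original, "original",
                         stringr::str_trunc(d$edge, 40))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$edge_short, .data$total),
                                  y = .data$total,
                                  fill = .data$original)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "attachment edge", y = "total Dollo losses",
                  fill = "original") +
    ggplot2::theme_minimal()
}

#' Heatmap view of a character matrix
#'
#' @param m a character-matrix tibble.
#' @param characters optional subset of character columns.
#' @return a ggplot object.
#' @export
plot_matrix <- function(m, characters = NULL) {
  chars <- characters %||% setdiff(names(m), "taxon")
  long <- tidyr::pivot_longer(m[, c("taxon", chars)], -"taxon",
                              names_to = "character", values_to = "state")
  long$taxon <- factor(long$taxon, levels = rev(m$taxon))
  long$character <- factor(long$character, levels = chars)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$character, y = .data$taxon,
                                     fill = .data$state)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_manual(values = c(`1` = "#2c7fb8", `0` = "grey95",
                                          P = "#fec44f", T = "#41ab5d",
                                          `?` = "grey60")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "state") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
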