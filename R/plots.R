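#' Commonality across the threshold sweep
#'
#' Line plot of the directed commonality A against the clustering
#' threshold, one line per ordered region pair (diagonal threshold pairs
#' only).
#'
#' @param commonality The `commonality` tibble of a report (see
#'   [run_insilico_comparison()]) or any [region_commonality()] output
#'   with a threshold sweep.
#' @return A ggplot object.
#' @export
plot_commonality <- function(commonality) {
  d <- dplyr::filter(commonality, .data$t1 == .data$t2) |>
    dplyr::mutate(pair = paste(.data$db1, "→", .data$db2))
  ggplot2::ggplot(d, ggplot2::aes(.data$t1, .data$A,
                                  colour = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "clustering identity threshold",
                  y = "commonality A = Σm / N", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Species per OTU across the threshold sweep
#'
#' @param species_per_otu The `species_per_otu` tibble of a
#'   [run_insilico_comparison()] report (`region`, `threshold`,
#'   `mean_species`).
#' @return A ggplot object.
#' @export
plot_species_per_otu <- function(species_per_otu) {
  ggplot2::ggplot(species_per_otu,
                  ggplot2::aes(.data$threshold, .data$mean_species,
                               colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "clustering identity threshold",
                  y = "mean species per OTU", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Region length distributions
#'
#' @param regions A `regions` tibble (`region`, `sequence`), e.g. from a
#'   report.
#' @return A ggplot object (box plots of sequence length per region).
#' @export
plot_region_lengths <- function(regions) {
  d <- dplyr::mutate(regions, length = nchar(.data$sequence))
  ggplot2::ggplot(d, ggplot2::aes(.data$region, .data$length)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "length (bp)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.otu_clustering <- function(object, ...) {
  d <- tidy(object) |> dplyr::arrange(dplyr::desc(.data$size)) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(.data$rank, .data$size)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "OTU rank", y = "OTU size",
                  title = sprintf("%d OTUs at %s%% identity",
                                  nrow(d), format(100 * object$threshold))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.marker_report <- function(object, ...) {
  plot_commonality(object$commonality)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
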