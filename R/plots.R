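#' Volcano plot of a differential table
#'
#' @param object A `photomics_differential` tibble.
#' @param q_threshold Significance threshold used for coloring.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot photomics_differential
#' @export
autoplot.photomics_differential <- function(object, q_threshold = 0.05, ...) {
  df <- as_tibble(object) |>
    mutate(significant = .data$q_value < q_threshold,
           direction = dplyr::case_when(
             !.data$q_value < q_threshold ~ "ns",
             .data$effect < 0 ~ "down",
             TRUE ~ "up"
           ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect,
                                   y = -log10(pmax(.data$p_value, 1e-300)),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(down = "#2166AC", ns = "grey70",
                                            up = "#E08214")) +
    ggplot2::labs(x = "effect (log2 fold-change / ΔM)",
                  y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the hypomethylation fraction by island relation
#'
#' @param summary_tbl Output of [hypomethylation_summary()].
#' @return A ggplot object.
#' @export
plot_hypomethylation_gradient <- function(summary_tbl) {
  df <- summary_tbl |>
    filter(.data$island_relation != "overall") |>
    mutate(island_relation = factor(.data$island_relation,
                                    levels = c("OpenSea", "Shelf", "Shore",
                                               "Island")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$island_relation,
                                   y = .data$fraction_hypo)) +
    ggplot2::geom_col(fill = "#2166AC") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = NULL, y = "fraction hypomethylated\n(significant CpGs)") +
    ggplot2::theme_minimal()
}
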