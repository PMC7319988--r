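#' Bar plot of consensus-cluster feature classes
#'
#' @param annotated Annotated consensus tibble (or `epicat_result$annotated`).
#' @return A ggplot object.
#' @export
plot_feature_classes <- function(annotated) {
  df <- annotated %>%
    mutate(feature_class = factor(.data$feature_class,
                                  levels = feature_classes()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature_class)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "consensus clusters",
                  title = "Genomic distribution of TSSs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Heatmap of the mutant-convergence matrix
#'
#' @param m Matrix from [convergence_matrix()].
#' @return A ggplot object.
#' @export
plot_convergence <- function(m) {
  df <- as_tibble(as.data.frame.table(m, responseName = "n")) %>%
    rename(row = "Var1", col = "Var2")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "EPICATs shared between mutants") +
    ggplot2::theme_minimal()
}

#' Positional motif profile plot
#'
#' @param object A `motif_profile` from [motif_positional_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.motif_profile <- function(object, ...) {
  peak <- attr(object, "peak_offset")
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$offset, y = .data$smoothed)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "offset from dominant CTSS (nt, upstream < 0)",
                  y = "motif instances (smoothed)",
                  title = "Positional motif profile") +
    ggplot2::theme_minimal()
  if (!is.na(peak)) {
    p <- p + ggplot2::geom_vline(xintercept = peak, color = "firebrick",
                                 linetype = "dashed")
  }
  p
}

#' @rdname autoplot.motif_profile
#' @param x A `motif_profile`.
#' @param y Unused.
#' @export
plot.motif_profile <- function(x, y, ...) print(autoplot.motif_profile(x))
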