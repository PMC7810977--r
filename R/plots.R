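# ggplot2 visualisations of result objects.

#' Plot methods for hemiphase results
#'
#' `autoplot()` gives the standard view of each result type: a two-point
#' recombination-fraction heatmap (`rf_matrix`), cluster sizes
#' (`mlg_clustering`), or a per-cross progeny composition bar chart
#' (`family_summary`).
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A `ggplot`.
#' @name hemiphase-autoplot
NULL

#' @rdname hemiphase-autoplot
#' @method autoplot rf_matrix
#' @export
autoplot.rf_matrix <- function(object, ...) {
  df <- tidy(object)
  df <- bind_rows(df, dplyr::rename(df, locus_a = "locus_b", locus_b = "locus_a"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$locus_a, levels = object$loci),
    y = factor(.data$locus_b, levels = rev(object$loci)),
    fill = .data$r_hat)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#2c7bb6", high = "#d7191c",
                                 limits = c(0, 0.5), name = expression(hat(r))) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Two-point recombination fractions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname hemiphase-autoplot
#' @method autoplot mlg_clustering
#' @export
autoplot.mlg_clustering <- function(object, ...) {
  df <- tidy(object) |> count(.data$cluster_id)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cluster_id), y = .data$n)) +
    ggplot2::geom_col(fill = "#2c7bb6") +
    ggplot2::labs(x = "MLG cluster", y = "haplotypes",
                  title = "Multilocus-genotype clusters") +
    ggplot2::theme_minimal()
}

#' @rdname hemiphase-autoplot
#' @method autoplot family_summary
#' @export
autoplot.family_summary <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(dplyr::matches("^(rr|rl)_"), names_to = "cell",
                        values_to = "n") |>
    filter(.data$n > 0) |>
    tidyr::separate_wider_delim("cell", "_", names = c("taxon", "sex")) |>
    mutate(taxon = toupper(.data$taxon))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cross_id, y = .data$n,
                                   fill = paste(.data$taxon, .data$sex))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "offspring", fill = "taxon / sex",
                  title = "Progeny composition per cross") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
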