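#' Heatmap of atom tract loadings
#'
#' @param decomposition An `atom_decomposition`.
#' @param ... Unused.
#' @return A ggplot: tracts on the x axis, atoms on the y axis, fill by
#'   loading weight.
#' @export
autoplot.atom_decomposition <- function(decomposition, ...) {
  df <- tibble::as_tibble(decomposition$W, rownames = "tract") |>
    tidyr::pivot_longer(-"tract", names_to = "atom", values_to = "weight")
  df$tract <- factor(df$tract, levels = rownames(decomposition$W))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tract, y = .data$atom,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "loading") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Lesion atom tract loadings") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5))
}

#' Bar chart of atom lateralization indices
#'
#' @param atoms Tibble from [atom_summary()].
#' @return A ggplot; positive LI = left-dominant (red), negative =
#'   right-dominant (blue).
#' @export
plot_lateralization <- function(atoms) {
  ggplot2::ggplot(atoms, ggplot2::aes(x = factor(.data$atom), y = .data$li,
                                      fill = .data$li > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b",
                                          `FALSE` = "#2980b9")) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "lesion atom", y = "lateralization index (L - R)/(L + R)",
                  title = "Hemispheric lateralization per atom") +
    ggplot2::theme_minimal()
}

#' Forest plot of a posterior summary
#'
#' Posterior means with HDI bars for the sex-stratified atom slopes;
#' relevant atoms (HDI excluding zero) are drawn solid.
#'
#' @param summary_tbl A `posterior_summary` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.posterior_summary <- function(summary_tbl, ...) {
  df <- dplyr::filter(summary_tbl, !is.na(.data$atom))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pm,
                                   y = factor(.data$atom),
                                   colour = .data$stratum,
                                   alpha = .data$relevant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$hdi_lower,
                                          xmax = .data$hdi_upper),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::scale_colour_manual(values = c(female = "#1e8449",
                                            male = "#21618c")) +
    ggplot2::labs(x = "posterior mean (HDI)", y = "lesion atom",
                  colour = "stratum",
                  title = "Sex-stratified atom effects") +
    ggplot2::theme_minimal()
}

#' Relevance-ranking bar chart
#'
#' @param ranking Tibble from [rank_atoms()].
#' @return A ggplot of summed absolute correlation scores by atom.
#' @export
plot_ranking <- function(ranking) {
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = stats::reorder(factor(.data$atom),
                                                  .data$score),
                               y = .data$score)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "lesion atom", y = "summed |r| across outcomes",
                  title = "Clinical relevance ranking") +
    ggplot2::theme_minimal()
}
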