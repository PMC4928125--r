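# ggplot2 displays for the main result types.

#' Bar chart of clade omega comparisons
#'
#' Mirrors the usual paired-bars display of mean pairwise omega per
#' subfamily and clade, with significance stars from the paired t-test.
#'
#' @param comparison Tibble from [compare_subfamily_omegas()].
#' @return A ggplot object.
#' @export
plot_omega_comparison <- function(comparison) {
  long <- comparison |>
    dplyr::mutate(pair = paste(
      .data$grass_subfamily, .data$eudicot_subfamily,
      sep = " / "
    )) |>
    tidyr::pivot_longer(c("mean_grass", "mean_eudicot"),
      names_to = "clade", values_to = "mean_omega"
    ) |>
    dplyr::mutate(clade = sub("mean_", "", .data$clade))
  stars <- comparison |>
    dplyr::mutate(
      pair = paste(.data$grass_subfamily, .data$eudicot_subfamily,
        sep = " / "
      ),
      label = dplyr::case_when(
        .data$p_value < 0.01 ~ "**",
        .data$p_value < 0.05 ~ "*",
        TRUE ~ ""
      ),
      y = pmax(.data$mean_grass, .data$mean_eudicot)
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$pair, y = .data$mean_omega, fill = .data$clade
  )) +
    ggplot2::geom_col(position = "dodge", colour = "black") +
    ggplot2::geom_text(
      data = stars,
      ggplot2::aes(x = .data$pair, y = .data$y, label = .data$label),
      inherit.aes = FALSE, vjust = -0.5, size = 6
    ) +
    ggplot2::scale_fill_manual(values = c(grass = "white", eudicot = "black")) +
    ggplot2::labs(
      x = "orthologous subfamily pair", y = "mean pairwise ω",
      fill = NULL
    ) +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-site posterior probability of positive selection
#'
#' @param object A `site_selection` from [neb_sites()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot site_selection
#' @export
autoplot.site_selection <- function(object, ...) {
  ggplot2::ggplot(object$sites, ggplot2::aes(
    x = .data$site, y = .data$posterior_positive
  )) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::geom_hline(
      yintercept = object$threshold,
      linetype = "dashed", colour = "red"
    ) +
    ggplot2::labs(
      x = "codon site",
      y = "posterior P(ω > 1 class)"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
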