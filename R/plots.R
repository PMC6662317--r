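#' SES bar figure for a pipeline report
#'
#' Mean SES per habitat, subgroup and index, faceted by landscape and
#' index, with error bars (sd across sites) and significance marks:
#' habitat-contrast stars above the panel, assembly-test plus signs under
#' the bars (one mark p < 0.10, two p < 0.05, three p < 0.01).
#'
#' @param object an `fda_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot fda_report
#' @export
autoplot.fda_report <- function(object, ...) {
  ses_con <- object$contrasts |>
    dplyr::filter(startsWith(.data$metric, "ses"))
  bars <- ses_con |>
    tidyr::pivot_longer(
      cols = c("mean_forest", "mean_agroforestry"),
      names_to = "habitat", names_prefix = "mean_", values_to = "mean_ses"
    ) |>
    dplyr::mutate(
      sd_ses = dplyr::if_else(.data$habitat == "forest",
                              .data$sd_forest, .data$sd_agroforestry),
      p_assembly = dplyr::if_else(.data$habitat == "forest",
                                  .data$p_forest, .data$p_agroforestry),
      assembly_mark = stars(.data$p_assembly, "+"),
      contrast_mark = stars(.data$p_value, "*")
    )
  ggplot2::ggplot(bars, ggplot2::aes(x = .data$subgroup, y = .data$mean_ses,
                                     fill = .data$habitat)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_ses - .data$sd_ses,
                   ymax = .data$mean_ses + .data$sd_ses),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$assembly_mark,
                   y = pmin(.data$mean_ses - .data$sd_ses, 0)),
      position = ggplot2::position_dodge(width = 0.8), vjust = 1.6, size = 3
    ) +
    ggplot2::geom_text(
      data = dplyr::distinct(bars, .data$landscape, .data$metric,
                             .data$subgroup, .data$contrast_mark),
      ggplot2::aes(label = .data$contrast_mark, y = Inf, fill = NULL),
      vjust = 1.2, size = 3
    ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_grid(metric ~ landscape) +
    ggplot2::labs(x = "Ecological subgroup", y = "Standardized effect size",
                  fill = "Habitat") +
    ggplot2::theme_minimal()
}

stars <- function(p, symbol) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.01 ~ strrep(symbol, 3),
    p < 0.05 ~ strrep(symbol, 2),
    p < 0.10 ~ symbol,
    TRUE ~ ""
  )
}

#' Plot species in functional trait space
#'
#' First two Cailliez-corrected principal-coordinate axes, optionally sized
#' by a community's relative abundances.
#'
#' @param space an `fda_trait_space`.
#' @param p optional named relative-abundance vector; species absent from
#'   `p` are drawn hollow.
#' @return A ggplot object.
#' @export
plot_trait_space <- function(space, p = NULL) {
  df <- tibble::tibble(
    species_id = rownames(space$coordinates),
    A1 = space$coordinates[, 1],
    A2 = if (ncol(space$coordinates) >= 2) space$coordinates[, 2] else 0
  )
  df$abundance <- if (is.null(p)) 1 else unname(p[df$species_id])
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$A1, y = .data$A2))
  if (is.null(p)) {
    gg <- gg + ggplot2::geom_point()
  } else {
    gg <- gg +
      ggplot2::geom_point(data = df[is.na(df$abundance), ], shape = 1,
                          colour = "grey60") +
      ggplot2::geom_point(data = df[!is.na(df$abundance), ],
                          ggplot2::aes(size = .data$abundance))
  }
  rel <- space$eigenvalues / sum(space$eigenvalues)
  gg + ggplot2::labs(
    x = sprintf("PCoA 1 (%.1f%%)", 100 * rel[1]),
    y = if (length(rel) >= 2) sprintf("PCoA 2 (%.1f%%)", 100 * rel[2]) else "",
    size = "Relative abundance"
  ) + ggplot2::theme_minimal()
}

#' Per-site SES dot plot
#'
#' One point per site, grouped by habitat, faceted by index and landscape;
#' the zero line is the random-assembly expectation.
#'
#' @param ses_tbl output of [ses_indices()].
#' @return A ggplot object.
#' @export
plot_ses_sites <- function(ses_tbl) {
  ggplot2::ggplot(ses_tbl, ggplot2::aes(x = .data$habitat, y = .data$ses,
                                        colour = .data$habitat)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.7) +
    ggplot2::facet_grid(index ~ landscape + subgroup) +
    ggplot2::labs(x = NULL, y = "Standardized effect size") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
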