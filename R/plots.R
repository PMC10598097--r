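#' Kendrick mass-defect plot
#'
#' KM versus KMD scatter of a transformed spectrum, the plot on which
#' peak groups are gated. Gate polygons, when given, are drawn on top.
#'
#' @param points Kendrick-point tibble from [kendrick_transform()].
#' @param polygons Optional list of gate polygons to overlay.
#' @param color Column mapped to point colour (default
#'   `"rel_intensity"` if present, otherwise `"intensity"`).
#' @return A ggplot object.
#' @export
plot_kendrick <- function(points, polygons = NULL, color = NULL) {
  color <- color %||%
    if ("rel_intensity" %in% names(points) &&
        !all(is.na(points$rel_intensity))) "rel_intensity" else "intensity"
  p <- ggplot2::ggplot(points,
                       ggplot2::aes(x = .data$km, y = .data$kmd)) +
    ggplot2::geom_point(ggplot2::aes(color = .data[[color]]),
                        size = 0.8, alpha = 0.8) +
    ggplot2::labs(x = "Kendrick mass (u)", y = "Kendrick mass defect",
                  color = color) +
    ggplot2::theme_minimal()
  if (!is.null(polygons)) {
    for (i in seq_along(polygons)) {
      poly <- polygons[[i]]
      poly <- rbind(poly, poly[1L, ])
      p <- p + ggplot2::geom_path(data = poly,
                                  ggplot2::aes(x = .data$km, y = .data$kmd),
                                  color = "red", linewidth = 0.4)
    }
  }
  p
}

#' van Krevelen diagram of formula assignments
#'
#' H/C against O/C elemental ratios of assigned formulas; lignin-like
#' material falls around O/C 0.2-0.6, H/C 0.7-1.5.
#'
#' @param assignments Assignment tibble from [assign_formulas()].
#' @param color Column mapped to colour (default `"dbe"`).
#' @return A ggplot object.
#' @export
plot_van_krevelen <- function(assignments, color = "dbe") {
  asg <- assignments[assignments$assigned, , drop = FALSE]
  ggplot2::ggplot(asg, ggplot2::aes(x = .data$o_c, y = .data$h_c)) +
    ggplot2::geom_point(ggplot2::aes(color = .data[[color]]),
                        size = 1, alpha = 0.8) +
    ggplot2::labs(x = "O/C", y = "H/C", color = color) +
    ggplot2::theme_minimal()
}

#' Bar chart of a solvent ranking
#'
#' @param ranking A [rank_solvents()] tibble.
#' @return A ggplot object; bars ordered by rank, filled by
#'   organic/aqueous ratio.
#' @export
plot_solvent_ranking <- function(ranking) {
  ranking$solvent_label <- stats::reorder(ranking$solvent_label,
                                          -ranking$rank)
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = .data$score, y = .data$solvent_label,
                               fill = .data$organic_aqueous_ratio)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "recovered peaks", y = NULL,
                  fill = "organic/aqueous") +
    ggplot2::theme_minimal()
}
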