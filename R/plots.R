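#' Plot boundary-distance distributions
#'
#' Histogram of 5'-3' boundary distances, optionally split by a grouping
#' column (e.g. activity status or condition), with the interaction
#' threshold marked.
#'
#' @param alleles allele tibble with a distance column.
#' @param value distance column name.
#' @param group optional grouping column name.
#' @param threshold_um threshold to mark (um); NULL to omit.
#' @param binwidth_um histogram bin width (um).
#' @return A ggplot object.
#' @export
plot_distance_distribution <- function(alleles, value = "distance_2d_um",
                                       group = NULL, threshold_um = 0.250,
                                       binwidth_um = 0.05) {
  p <- ggplot2::ggplot(alleles, ggplot2::aes(x = .data[[value]]))
  if (is.null(group)) {
    p <- p + ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$density)),
      binwidth = binwidth_um, fill = "grey35", colour = "white"
    )
  } else {
    p <- p + ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$density),
                   fill = factor(.data[[group]])),
      binwidth = binwidth_um, position = "identity", alpha = 0.55
    ) + ggplot2::labs(fill = group)
  }
  if (!is.null(threshold_um)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold_um, linetype = "dashed")
  }
  p + ggplot2::labs(x = "5'-3' boundary distance (µm)", y = "Density") +
    ggplot2::theme_classic()
}

#' Plot allelic expression-state fractions
#'
#' Bar chart of the fraction of cells with 0, 1, 2 or >=3 active
#' transcription sites, as produced by [expression_state_fractions()].
#'
#' @param fractions tibble from [expression_state_fractions()], optionally
#'   with an extra `condition` column for dodged bars.
#' @return A ggplot object.
#' @export
plot_expression_states <- function(fractions) {
  fractions$state <- factor(fractions$state, levels = c("0", "1", "2", ">=3"))
  p <- ggplot2::ggplot(fractions,
                       ggplot2::aes(x = .data$state, y = .data$fraction))
  if ("condition" %in% names(fractions)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$condition),
                               position = "dodge")
  } else {
    p <- p + ggplot2::geom_col(fill = "grey35")
  }
  p + ggplot2::labs(x = "Active transcription sites per cell",
                    y = "Fraction of cells") +
    ggplot2::theme_classic()
}

#' Field map of a simulated scene
#'
#' Scatter of nuclei outlines and true spot positions for a
#' [simulate_ground_truth()] scene, useful for eyeballing a configuration.
#'
#' @param object a `scene_truth`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.scene_truth <- function(object, ...) {
  al <- object$alleles
  spots <- dplyr::bind_rows(
    dplyr::transmute(al, x = .data$x5_um, y = .data$y5_um, channel = "dna5"),
    dplyr::transmute(al, x = .data$x3_um, y = .data$y3_um, channel = "dna3"),
    al |> dplyr::filter(.data$active) |>
      dplyr::transmute(x = .data$rna_x_um, y = .data$rna_y_um, channel = "rna")
  )
  circ <- purrr::map(seq_len(nrow(object$cells)), function(i) {
    th <- seq(0, 2 * pi, length.out = 90)
    tibble(cell_id = object$cells$cell_id[i],
           x = object$cells$cx_um[i] + object$cells$radius_um[i] * cos(th),
           y = object$cells$cy_um[i] + object$cells$radius_um[i] * sin(th))
  }) |> dplyr::bind_rows()
  ggplot2::ggplot() +
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(.data$x, .data$y, group = .data$cell_id),
                       colour = "grey70") +
    ggplot2::geom_point(data = spots,
                        ggplot2::aes(.data$x, .data$y, colour = .data$channel),
                        size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = NULL) +
    ggplot2::theme_classic()
}
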