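#' Plot real versus permuted correlation distributions
#'
#' Overlays the real per-protein correlation values for one comparison on the
#' within-FOV permutation null, with the candidate threshold marked -- the
#' display used to pick a threshold with a low false discovery rate.
#'
#' @param object A [screen_motility()] result.
#' @param comparison Which of the six comparisons to show.
#' @param statistic `"pearson"` or `"spearman"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motility_screen <- function(object, comparison = "level~velocity",
                                     statistic = c("pearson", "spearman"),
                                     ...) {
  statistic <- match.arg(statistic)
  col <- paste0(statistic, "_r")
  real <- dplyr::filter(object$correlations, .data$comparison == !!comparison)
  null <- dplyr::filter(object$null$values, .data$comparison == !!comparison)
  thr <- object$params$threshold
  ggplot2::ggplot(mapping = ggplot2::aes(x = .data[[col]])) +
    ggplot2::geom_histogram(
      data = null,
      ggplot2::aes(y = ggplot2::after_stat(.data$density), fill = "permuted"),
      bins = 40, alpha = 0.6
    ) +
    ggplot2::geom_histogram(
      data = real,
      ggplot2::aes(y = ggplot2::after_stat(.data$density), fill = "real"),
      bins = 40, alpha = 0.6
    ) +
    ggplot2::geom_vline(xintercept = c(-thr, thr), linetype = "dashed") +
    ggplot2::scale_fill_manual(NULL, values = c(permuted = "grey60",
                                                real = "black")) +
    ggplot2::labs(x = sprintf("%s R (%s)", statistic, comparison),
                  y = "density",
                  title = "Real vs within-FOV permuted correlations") +
    ggplot2::theme_minimal()
}

#' Plot single-cell trajectories
#'
#' Paths of tracked cells (origin-anchored per cell), one panel per cell.
#'
#' @param tracks Track tibble.
#' @param n_cells Number of cells to show (sampled deterministically: the
#'   first `n_cells` in table order).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(tracks, n_cells = 12) {
  keys <- dplyr::distinct(tracks, .data$protein_id, .data$fov_id, .data$cell_id)
  keys <- utils::head(keys, n_cells)
  d <- dplyr::semi_join(tracks, keys,
                        by = c("protein_id", "fov_id", "cell_id")) |>
    dplyr::group_by(.data$protein_id, .data$fov_id, .data$cell_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(x = .data$x - .data$x[1], y = .data$y - .data$y[1]) |>
    dplyr::ungroup() |>
    dplyr::mutate(cell = paste(.data$fov_id, .data$cell_id))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::facet_wrap(~cell) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Scatter plot of one protein/motility feature pair
#'
#' Pooled (cell, frame) scatter of a protein feature against a motility
#' feature with the linear fit, for one protein.
#'
#' @param table Feature table.
#' @param protein_id Protein to show.
#' @param protein_feature,motility_feature Which pair to plot.
#' @return A ggplot object.
#' @export
plot_feature_pair <- function(table, protein_id,
                              protein_feature = "level",
                              motility_feature = "velocity") {
  d <- table[table$protein_id == protein_id, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(.data[[protein_feature]],
                                  .data[[motility_feature]])) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(title = protein_id) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
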