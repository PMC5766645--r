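# ggplot2 views of the result types: per-position interaction map,
# region-score heatmap, entropy-rank tiles and the
# interaction-vs-conservation scatter.

#' Interaction map of one complex
#'
#' Bars of the minimum set distance per universal tRNA position, shaded by
#' the number of amino acids within the threshold; the dashed line marks
#' the threshold and undetermined positions are flagged along the axis.
#'
#' @param object a `trna_distance_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot trna_distance_profile
#' @export
autoplot.trna_distance_profile <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 3.3
  df <- tibble::as_tibble(object)
  df$label <- factor(df$label, levels = df$label[order(sprinzl_order(df$label))])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$min_distance,
                                   fill = .data$n_interacting_aa)) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "blue") +
    ggplot2::geom_point(
      data = df[!df$determined, ], y = 0, shape = 4, colour = "blue") +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 na.value = "grey85") +
    ggplot2::labs(x = "universal tRNA position",
                  y = "minimum set distance (Å)",
                  fill = "interacting\namino acids",
                  title = attr(object, "entry_id")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, vjust = 0.5, size = 6))
}

#' Region-score heatmap across complexes
#'
#' @param object a `trna_region_matrix`.
#' @param ... unused.
#' @return a ggplot (complexes x regions; undetermined regions dark).
#' @method autoplot trna_region_matrix
#' @export
autoplot.trna_region_matrix <- function(object, ...) {
  cols <- intersect(paste0("S", 1:15), names(object))
  long <- tidyr::pivot_longer(tibble::as_tibble(object), dplyr::all_of(cols),
                              names_to = "region", values_to = "score")
  long$region <- factor(long$region, levels = paste0("S", 1:15))
  ggplot2::ggplot(long, ggplot2::aes(.data$region, .data$complex_id,
                                     fill = .data$score)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient(low = "white", high = "red",
                                 na.value = "black") +
    ggplot2::labs(x = "tRNA sequence region", y = NULL,
                  fill = "interacting\nscore") +
    ggplot2::theme_minimal()
}

#' Entropy-rank tile map of an isoacceptor group
#'
#' @param object a `trna_entropy_profile`.
#' @param ... unused.
#' @return a ggplot (positions coloured from variable, rank 1, to
#'   conserved, rank 9).
#' @method autoplot trna_entropy_profile
#' @export
autoplot.trna_entropy_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- factor(df$label,
                     levels = df$label[order(sprinzl_order(df$label))])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = 1,
                                   fill = .data$rank)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "cyan", high = "magenta",
                                 limits = c(1, 9)) +
    ggplot2::labs(x = "universal tRNA position", y = NULL,
                  fill = "conservation\nrank") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(
                     angle = 90, vjust = 0.5, size = 6))
}

#' Interaction versus conservation per region
#'
#' Scatter of the mean interacting-amino-acid score against the mean
#' conservation rank for the cloverleaf regions, with standard-error bars.
#'
#' @param data tibble from [interaction_vs_conservation()].
#' @return a ggplot.
#' @export
plot_interaction_vs_conservation <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(.data$mean_score, .data$mean_rank)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_rank - .data$se,
      ymax = .data$mean_rank + .data$se), width = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$region),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "mean interacting amino acids per position",
                  y = "mean conservation rank") +
    ggplot2::theme_minimal()
}

#' Threshold-sweep curve
#'
#' @param sweep tibble from [threshold_sweep()].
#' @return a ggplot of interacting counts against the threshold.
#' @export
plot_threshold_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep, c("n_rib_interacting",
                                       "n_aa_interacting"),
                              names_to = "side", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(.data$threshold, .data$n,
                                     colour = .data$side)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = 3.3, linetype = "dashed") +
    ggplot2::labs(x = "distance threshold (Å)",
                  y = "interacting residues", colour = NULL) +
    ggplot2::theme_minimal()
}
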