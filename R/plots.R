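#' Plot a synapse distance profile
#'
#' Histogram of geodesic distances to the dendritic root with the median
#' marked; overlay several profiles by row-binding them first.
#'
#' @param object A `distance_profile` (stacked profiles allowed).
#' @param binwidth_nm Histogram bin width (nm).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot distance_profile
#' @export
autoplot.distance_profile <- function(object, binwidth_nm = 500, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance_nm,
                                       fill = .data$synapse_class)) +
    ggplot2::geom_histogram(binwidth = binwidth_nm, position = "identity",
                            alpha = 0.6, boundary = 0) +
    ggplot2::facet_wrap(ggplot2::vars(.data$neuron)) +
    ggplot2::labs(x = "geodesic distance to dendritic root (nm)",
                  y = "synapses", fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot a dendrogram layout
#'
#' Draws the flattened arbor (depth = topological distance from the root,
#' neurite length not preserved) with synapse marks coloured by class.
#'
#' @param object A `dendrogram_layout` from [layout_dendrogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dendrogram_layout
#' @export
autoplot.dendrogram_layout <- function(object, ...) {
  seg <- dplyr::inner_join(
    object[!duplicated(object$node_id), c("node_id", "parent_id", "x", "y")],
    object[!duplicated(object$node_id), c("node_id", "x", "y")],
    by = c("parent_id" = "node_id"), suffix = c("", "_parent"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$x_parent, yend = .data$y_parent),
                          linewidth = 0.2, colour = "grey40")
  marked <- object[!is.na(object$mark), ]
  if (nrow(marked) > 0) {
    p <- p + ggplot2::geom_point(data = marked,
                                 ggplot2::aes(x = .data$x, y = .data$y,
                                              colour = .data$mark), size = 1)
  }
  p + ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "topological depth", colour = "synapse class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Boxplot of a paired imaging cohort
#'
#' The paper-style summary: 25th-75th percentile box, median line, whiskers
#' to the minimum and maximum, one point per fly.
#'
#' @param object A `paired_cohort` from [paired_group_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot paired_cohort
#' @export
autoplot.paired_cohort <- function(object, ...) {
  long <- tidyr::pivot_longer(object$pairs, c("cs_plus", "cs_minus"),
                              names_to = "condition", values_to = "value")
  long$condition <- ifelse(long$condition == "cs_plus", "CS+", "CS-")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_boxplot(coef = Inf, width = 0.5, outlier.shape = NA) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.08),
                        alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "normalized response") +
    ggplot2::theme_minimal()
}

#' Plot a circuit trajectory
#'
#' Per-phase CS+ and CS- responses of each model readout across the
#' protocol.
#'
#' @param object A `circuit_trajectory` from [run_protocol()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot circuit_trajectory
#' @export
autoplot.circuit_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$responses,
    c("mvp2", "m6_dendrite", "m6_axon", "m4_dendrite", "m4_axon",
      "approach_other", "valence"),
    names_to = "readout", values_to = "rate")
  long$phase <- factor(long$phase, levels = unique(object$responses$phase))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$phase, y = .data$rate,
                                     colour = .data$odor, group = .data$odor)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$readout), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "model rate (a.u.)", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a protocol timeline
#'
#' @param object A `protocol_timeline` from [build_protocol()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot protocol_timeline
#' @export
autoplot.protocol_timeline <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$end_s <- df$onset_s + pmax(df$duration_s, 1)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$onset_s / 60,
                                    xmax = .data$end_s / 60,
                                    ymin = 0, ymax = 1, fill = .data$label)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (min)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
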