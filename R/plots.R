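# ggplot2 graphics for the main result types.

#' Plot an annual concentration field
#'
#' One line per spatial unit over the observed years, on a log scale so
#' multiplicative trends appear linear. A reconstructed pre-period (from
#' [backcast()]) can be overlaid and is drawn dashed.
#'
#' @param field Annual field tibble (`unit_id`, `year`, `value`).
#' @param reconstructed Optional `"reconstructed_field"` to overlay.
#' @return A ggplot object.
#' @export
plot_annual_field <- function(field, reconstructed = NULL) {
  p <- ggplot2::ggplot(field,
                       ggplot2::aes(.data$year, .data$value,
                                    group = .data$unit_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "year", y = expression(NO[2] ~ (mu * g / m^3)),
                  title = "Annual mean concentrations by spatial unit")
  if (!is.null(reconstructed)) {
    p <- p + ggplot2::geom_line(data = reconstructed, linetype = "dashed",
                                alpha = 0.4, colour = "firebrick")
  }
  p
}

#' @describeIn plot_annual_field autoplot method for reconstructed fields.
#' @param object A `"reconstructed_field"` tibble.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.reconstructed_field <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$year, .data$value,
                                       group = .data$unit_id)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value * exp(-.data$sd_log),
                                      ymax = .data$value * exp(.data$sd_log)),
                         alpha = 0.15) +
    ggplot2::geom_line(alpha = 0.5, colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "year", y = expression(NO[2] ~ (mu * g / m^3)),
                  title = "Reconstructed pre-period concentrations",
                  subtitle = "band: multiplicative one-sigma calibration uncertainty")
}

#' Dendrogram of the unit/station clustering
#'
#' Draws the merge tree of [cluster_profiles()] with leaves coloured by
#' entity kind, mirroring the usual presentation of monitor-assignment
#' dendrograms.
#'
#' @param object A `"station_clustering"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.station_clustering <- function(object, ...) {
  tree <- object$hclust
  n <- length(tree$labels)
  leaf_x <- setNames(match(seq_len(n), tree$order), seq_len(n))
  node_x <- numeric(nrow(tree$merge))
  node_h <- tree$height
  seg <- vector("list", nrow(tree$merge))
  pos <- function(id) {
    if (id < 0) c(leaf_x[[-id]], 0) else c(node_x[id], node_h[id])
  }
  for (s in seq_len(nrow(tree$merge))) {
    a <- pos(tree$merge[s, 1]); b <- pos(tree$merge[s, 2])
    node_x[s] <- mean(c(a[1], b[1]))
    seg[[s]] <- tibble::tibble(
      x = c(a[1], a[1], b[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], node_h[s], node_h[s]), yend = c(node_h[s], node_h[s], b[2]))
  }
  leaves <- tibble::tibble(
    x = unname(leaf_x[as.character(seq_len(n))]),
    label = tree$labels,
    kind = object$labels$kind[match(tree$labels, object$labels$entity_id)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = dplyr::bind_rows(seg),
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(.data$x, -0.02 * max(node_h),
                                    label = .data$label,
                                    colour = .data$kind),
                       angle = 90, hjust = 1, size = 2.5) +
    ggplot2::scale_y_continuous("correlation distance (average linkage)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.title.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank()) +
    ggplot2::labs(title = sprintf("Units and monitors, cut at k = %d", object$k))
}

#' Mobility-contrast plot for cumulative-exposure results
#'
#' Shows the exposure difference attributable to residential mobility
#' (sedentary minus mobility-aware estimate) against each unit's degree of
#' mobility — the package's headline contrast.
#'
#' @param object A `"cumulative_exposure"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cumulative_exposure <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$degree_of_mobility,
                                       .data$relative_difference)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(
      x = "degree of mobility (%)",
      y = expression(Delta ~ exposure ~ (mu * g / m^3)),
      title = "Exposure overestimation when residential mobility is ignored")
}
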