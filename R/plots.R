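# ggplot2 displays for the result types.

#' Plot an enrichment result
#'
#' Horizontal bars of the objective value (OR ratio or Additional Sites)
#' per matrix, the usual display for a motif over-representation screen.
#' Bars are coloured by location group when a `group_id` column is present.
#'
#' @param object A `flex_enrichment` tibble.
#' @param top_n Show at most this many rows (by objective value).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.flex_enrichment <- function(object, top_n = 20, ...) {
  df <- tidy(object)
  if (nrow(df) == 0) abort("empty enrichment result")
  df$.obj <- objective_value(object)
  df <- dplyr::slice_max(df, .data$.obj, n = top_n, with_ties = FALSE)
  lab <- if (identical(attr(object, "objective"), "or")) {
    "OR ratio"
  } else {
    "Additional Sites"
  }
  df$setting <- sprintf("%s (w=%s, n=%d)", df$motif_id,
                        ifelse(is.na(df$window), "frag", df$window),
                        df$n_required)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$.obj, y = stats::reorder(.data$setting, .data$.obj)))
  if ("group_id" %in% names(df)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = factor(.data$group_id)),
                               show.legend = FALSE)
  } else {
    p <- p + ggplot2::geom_col()
  }
  p + ggplot2::labs(x = lab, y = NULL) + ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a threshold scan
#'
#' Objective value against candidate threshold with the admissible band
#' highlighted; the flexible-threshold optimum is the admissible maximum.
#'
#' @param points A [scan_thresholds()] tibble.
#' @param objective `"as"` or `"or"`.
#' @return A ggplot.
#' @export
plot_threshold_scan <- function(points, objective = c("as", "or")) {
  objective <- match.arg(objective)
  points$.obj <- if (objective == "or") points$or_ratio else points$additional_sites
  ggplot2::ggplot(points, ggplot2::aes(x = .data$threshold, y = .data$.obj)) +
    ggplot2::geom_step(colour = "grey50") +
    ggplot2::geom_point(data = points[points$admissible, ],
                        colour = "firebrick", size = 1) +
    ggplot2::labs(
      x = "score threshold",
      y = if (objective == "or") "OR ratio" else "Additional Sites",
      subtitle = "red: thresholds admissible under the control-frequency band"
    ) +
    ggplot2::theme_minimal()
}

#' Plot regulatory-class counts per timepoint
#'
#' @param classified Output of [classify_genes()].
#' @return A ggplot.
#' @export
plot_class_counts <- function(classified) {
  df <- classified |>
    dplyr::filter(.data$class != "none") |>
    dplyr::count(.data$timepoint, .data$class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$n,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "genes", fill = "class") +
    ggplot2::theme_minimal()
}
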