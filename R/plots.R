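#' Plot per-cell score distributions
#'
#' Density strips of the senescence score per stratum, with the mu + 3 sigma
#' outlier threshold drawn when outlier calls are present.
#'
#' @param object A `senesig_scores` tibble (optionally after
#'   [call_outliers()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.senesig_scores <- function(object, ...) {
  if (!"stratum" %in% names(object)) object$stratum <- "all"
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey35") +
    ggplot2::facet_wrap(~stratum, scales = "free_y") +
    ggplot2::labs(
      x = "senescence score (signature mean - background mean)",
      y = "cells"
    ) +
    ggplot2::theme_minimal()
  if ("threshold" %in% names(object)) {
    thr <- unique(object[, c("stratum", "threshold")])
    p <- p + ggplot2::geom_vline(
      data = thr, ggplot2::aes(xintercept = .data$threshold),
      linetype = "dashed", colour = "firebrick"
    )
  }
  p
}

#' Plot membership counts of a universal signature
#'
#' @param object A `senesig_universal` tibble from [universal_signature()].
#' @param top_n Number of most common genes to show (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.senesig_universal <- function(object, top_n = 30, ...) {
  top <- head(object[object$m > 0, ], top_n)
  ggplot2::ggplot(
    top,
    ggplot2::aes(
      x = stats::reorder(.data$gene, .data$m), y = .data$m,
      fill = .data$member
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "signatures containing the gene", fill = "universal"
    ) +
    ggplot2::theme_minimal()
}

#' Map outlier spots on the spatial grid
#'
#' @param merged The `merged` tibble returned by [score_spots()] (per-spot
#'   coordinates and outlier flags).
#' @return A ggplot object.
#' @export
plot_spot_outliers <- function(merged) {
  ggplot2::ggplot(
    merged,
    ggplot2::aes(x = .data$x, y = .data$y, colour = .data$outlier)
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c("grey80", "firebrick")) +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "senescent-like") +
    ggplot2::theme_minimal()
}
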