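# ggplot2 views of the result objects. Bins are drawn oldest-first (age
# decreasing rightward), the convention for geological time series.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a phylogenetic diversity curve
#' @param object a `diversity_curve`
#' @param ... ignored
#' @return a ggplot
#' @export
autoplot.diversity_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("observed", "total"),
                              names_to = "count_type", values_to = "lineages")
  long$bin <- factor(long$bin, levels = object$bin)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$lineages,
                                     group = .data$count_type,
                                     linetype = .data$count_type)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "lineages (observed + ghost)",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-interval disparity with rarefaction CIs
#' @param object a `disparity_result`
#' @param metric `"mpd"` or `"sov"`
#' @param ... ignored
#' @return a ggplot
#' @export
autoplot.disparity_result <- function(object, metric = c("mpd", "sov"), ...) {
  metric <- match.arg(metric)
  df <- tibble::tibble(bin = factor(object$bin, levels = object$bin),
                       y = object[[metric]],
                       lo = object[[paste0(metric, "_lower")]],
                       hi = object[[paste0(metric, "_upper")]])
  ylab <- if (metric == "mpd") "mean pairwise dissimilarity"
          else "sum of variances (PCo scores)"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$y)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot an ordination (morphospace)
#' @param object an `ordination`
#' @param axes which two axes to draw
#' @param groups optional named vector mapping taxa to groups (colour)
#' @param ... ignored
#' @return a ggplot
#' @export
autoplot.ordination <- function(object, axes = c(1, 2), groups = NULL, ...) {
  df <- tibble::tibble(taxon = object$taxa,
                       x = object$scores[, axes[1]],
                       y = object$scores[, axes[2]])
  df$group <- if (is.null(groups)) "all" else unname(groups[df$taxon])
  pct <- object$percent_per_axis
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PCo%d (%.1f%%)", axes[1], pct[axes[1]]),
      y = sprintf("PCo%d (%.1f%%)", axes[2], pct[axes[2]])) +
    ggplot2::theme_minimal()
  if (is.null(groups)) p <- p + ggplot2::guides(colour = "none")
  p
}

#' Plot Akaike weights of a trait-model comparison
#' @param object a `trait_model_set`
#' @param ... ignored
#' @return a ggplot
#' @export
autoplot.trait_model_set <- function(object, ...) {
  df <- glance(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Akaike weight") +
    ggplot2::theme_minimal()
}
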