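# ggplot2 views of the main result types.

#' E-score distribution per allele
#'
#' Histogram of scores faceted by allele; bimodality with a dominant
#' negative peak is the expected shape for a screened pool.
#'
#' @param escores Score table; the score column is auto-detected as in
#'   [call_binders()].
#' @param bins Histogram bins.
#' @param threshold Optional cutoff drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_escore_distribution <- function(escores, bins = 40, threshold = NULL) {
  col <- intersect(c("mean_escore", "aligned_escore", "raw_escore"),
                   names(escores))[1]
  p <- ggplot2::ggplot(escores,
                       ggplot2::aes(x = .data[[col]])) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::facet_wrap(ggplot2::vars(.data$allele), scales = "free_y") +
    ggplot2::labs(x = "E-score", y = "trimers") +
    ggplot2::theme_bw()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = 2,
                                 colour = "firebrick")
  }
  p
}

#' @rdname escape_benchmark
#' @param object An `escape_benchmark` object.
#' @param which `"roc"` or `"pr"`.
#' @export
autoplot.escape_benchmark <- function(object, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  curves <- filter(object$curves, .data$curve == which)
  labs <- if (which == "roc") {
    ggplot2::labs(x = "false positive rate", y = "true positive rate")
  } else {
    ggplot2::labs(x = "recall", y = "precision")
  }
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$allele)) +
    ggplot2::geom_step() + labs + ggplot2::theme_bw()
  if (which == "roc") {
    p <- p + ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3)
  }
  p
}

#' Mutant versus wild-type quadrant scatter
#'
#' @param quadrants Output of [quadrant_classify()].
#' @param threshold The threshold to draw (dashed lines).
#' @return A ggplot object.
#' @export
plot_quadrants <- function(quadrants,
                           threshold = default_threshold("combinatorial")) {
  ggplot2::ggplot(quadrants,
                  ggplot2::aes(x = .data$mut_escore, y = .data$wt_escore,
                               colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "mutant E-score", y = "wild-type E-score") +
    ggplot2::theme_bw()
}

#' @rdname build_motif
#' @param object A `pfm` matrix.
#' @param ... Unused.
#' @export
autoplot.pfm <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("residue", "position", "frequency")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$residue,
                                   fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue") +
    ggplot2::labs(x = "position", y = NULL) +
    ggplot2::theme_minimal()
}

#' Allele map from a 2-D embedding
#'
#' @param embedding Tibble from [embed_2d()].
#' @return A ggplot object.
#' @export
plot_allele_embedding <- function(embedding) {
  ggplot2::ggplot(embedding, ggplot2::aes(x = .data$x, y = .data$y,
                                          label = .data$allele)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = "dim 1", y = "dim 2") +
    ggplot2::theme_bw()
}

#' Per-mutation population-coverage histogram
#'
#' @param coverage A `coverage_distribution` or its `per_mutation` tibble.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage, bins = 20) {
  if (inherits(coverage, "coverage_distribution")) {
    coverage <- coverage$per_mutation
  }
  ggplot2::ggplot(coverage, ggplot2::aes(x = .data$coverage)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::labs(x = "population coverage", y = "mutations") +
    ggplot2::theme_bw()
}
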