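# ggplot2 visualisations for the main result types.

#' Plot a fingerprint curve
#'
#' @param fingerprint Tibble of `x`, `y` points from [fingerprint_curve()].
#' @return A ggplot object.
#' @export
plot_fingerprint <- function(fingerprint) {
  ggplot2::ggplot(fingerprint, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "Fraction of bins (ranked by coverage)",
                  y = "Cumulative fraction of signal",
                  title = "KAS-seq fingerprint") +
    ggplot2::theme_minimal()
}

#' Plot a saturation curve
#'
#' @param saturation Tibble of `fraction`, `frip` from [saturation_curve()].
#' @return A ggplot object.
#' @export
plot_saturation <- function(saturation) {
  ggplot2::ggplot(saturation, ggplot2::aes(x = .data$fraction, y = .data$frip)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Subsampled fraction of tags", y = "FRiP",
                  title = "Sequencing saturation") +
    ggplot2::theme_minimal()
}

#' Metagene profile plot
#'
#' Plots the column-mean metagene curve of a profile matrix, optionally
#' split by gene groups (e.g. pausing-index tertiles).
#'
#' @param object A `kas_profile` from [metagene_profile()].
#' @param groups Optional tibble `name`, `group` (as from
#'   [tertile_groups()]) to draw one curve per group.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kas_profile <- function(object, groups = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(groups)) {
    df <- dplyr::inner_join(df, dplyr::rename(groups, gene = "name"), by = "gene")
    df <- dplyr::summarise(dplyr::group_by(df, .data$group, .data$bin),
                           value = mean(.data$value), .groups = "drop")
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$value,
                                          colour = .data$group))
  } else {
    df <- dplyr::summarise(dplyr::group_by(df, .data$bin),
                           value = mean(.data$value), .groups = "drop")
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$value))
  }
  n_flank <- attr(object, "n_flank")
  body_bins <- attr(object, "body_bins")
  p <- p + ggplot2::geom_line(linewidth = 0.8)
  if (identical(attr(object, "mode"), "scale-regions")) {
    p <- p + ggplot2::geom_vline(xintercept = c(n_flank + 0.5, n_flank + body_bins + 0.5),
                                 linetype = "dotted", colour = "grey50")
  } else {
    p <- p + ggplot2::geom_vline(xintercept = n_flank + 0.5,
                                 linetype = "dotted", colour = "grey50")
  }
  p + ggplot2::labs(x = "Profile bin (5' to 3')", y = "Mean density",
                    title = "Metagene profile") +
    ggplot2::theme_minimal()
}

#' Volcano plot of strand-imbalance results
#'
#' @param object A `kas_imbalance` from [nb_imbalance_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kas_imbalance <- function(object, ...) {
  df <- as_tibble(object)
  df$status <- ifelse(!df$significant, "n.s.",
                      ifelse(df$dominant_strand == "+", "plus", "minus"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$padj, 1e-300)),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(plus = "#d7301f", minus = "#2b8cbe",
                                            n.s. = "grey70")) +
    ggplot2::labs(x = "log2(plus / minus)", y = "-log10 adjusted p",
                  title = "Strand imbalance", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Fitted trajectory plot for one feature
#'
#' Draws the normalized counts and the fitted constant, sigmoid, and
#' impulse curves.
#'
#' @param object A converged `kas_impulse_fit`.
#' @param y Counts used in the fit.
#' @param timepoints Timepoint per sample.
#' @param sf Size factor per sample.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kas_impulse_fit <- function(object, y, timepoints, sf = rep(1, length(y)), ...) {
  stopifnot(isTRUE(object$converged))
  grid <- seq(min(timepoints), max(timepoints), length.out = 200)
  curves <- dplyr::bind_rows(
    tibble(t = grid, value = rep(object$h_const, length(grid)), model = "constant"),
    tibble(t = grid, value = sigmoid_value(grid, object$sigmoid_params), model = "sigmoid"),
    tibble(t = grid, value = impulse_value(grid, object$params), model = "impulse")
  )
  pts <- tibble(t = timepoints, value = y / sf)
  ggplot2::ggplot() +
    ggplot2::geom_point(data = pts, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$t, y = .data$value,
                                    colour = .data$model, linetype = .data$model)) +
    ggplot2::labs(x = "Time (h)", y = "Normalized count",
                  title = "Trajectory model fits") +
    ggplot2::theme_minimal()
}

#' Feature-distribution bar chart
#'
#' @param distribution Tibble from [annotate_peaks()].
#' @return A ggplot object.
#' @export
plot_feature_distribution <- function(distribution) {
  distribution$feature <- factor(distribution$feature,
                                 levels = c("promoter", "gene_body", "terminator", "intergenic"))
  ggplot2::ggplot(distribution,
                  ggplot2::aes(x = .data$feature, y = .data$percent, fill = .data$feature)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "% of peaks", title = "Peak genomic distribution") +
    ggplot2::theme_minimal()
}
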