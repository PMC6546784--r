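#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an interaction-call locus
#'
#' Significance track of one element's candidate bins: -log10(p) against
#' candidate-bin position, with the FDR cut shown as the largest p still
#' called significant.
#'
#' @param calls Corrected call tibble from [correct_and_call()].
#' @param element Element id to plot.
#' @return A ggplot object.
#' @export
plot_locus <- function(calls, element) {
  sub <- calls[calls$element == element, ]
  if (nrow(sub) == 0) stop("no calls for element ", element)
  p <- ggplot2::ggplot(sub, ggplot2::aes(x = .data$candidate,
                                         y = -log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                        show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = sub$anchor[1], linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "candidate bin", y = expression(-log[10](italic(p))),
                  title = element, subtitle = unique(sub$chrom)[1]) +
    ggplot2::theme_minimal()
  if (any(sub$significant)) {
    cut <- max(sub$p[sub$significant])
    p <- p + ggplot2::geom_hline(yintercept = -log10(cut),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' @method autoplot or_distribution
#' @export
autoplot.or_distribution <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_or)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed$odds_ratio,
                        colour = "firebrick") +
    ggplot2::labs(x = "null odds ratio", y = "matched sets",
                  subtitle = sprintf("observed OR = %.2f, empirical p = %.3g",
                                     object$observed$odds_ratio,
                                     object$p_empirical)) +
    ggplot2::theme_minimal()
}

#' @method autoplot trajectory_result
#' @export
autoplot.trajectory_result <- function(object, ...) {
  tr <- object$trajectory
  x <- if ("age" %in% names(tr)) "age" else "sample"
  ggplot2::ggplot(tr, ggplot2::aes(x = .data[[x]], y = .data$mean_expr,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(y = "mean centered expression") +
    ggplot2::theme_minimal()
}

#' @method autoplot contact_null
#' @export
autoplot.contact_null <- function(object, ...) {
  df <- tidy(object)
  df$mean_contact <- df$scale * gamma(1 + 1 / df$shape)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance,
                                   y = .data$mean_contact,
                                   colour = .data$chrom)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "genomic distance (bp)", y = "fitted mean contact") +
    ggplot2::theme_minimal()
}
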