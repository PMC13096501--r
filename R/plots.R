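# ggplot2 views of the main result types.

#' Rank-ordered erosion plot with null SD bands
#'
#' Reproduces the standard view of per-RDC mean log2 ratios: regions ordered
#' by decreasing mean, a solid line at the shuffled-null mean and dotted
#' bands at +/- 1-3 null SDs, flagged regions highlighted.
#'
#' @param x An [erosion_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_erosion <- function(x, ...) {
  mu0 <- attr(x, "mu0"); sigma0 <- attr(x, "sigma0")
  bands <- tibble(level = rep(1:3, 2),
                  y = mu0 + c(1:3, -(1:3)) * sigma0)
  ggplot2::ggplot(x, ggplot2::aes(x = .data$rank, y = .data$mean_log2)) +
    ggplot2::geom_hline(yintercept = mu0, colour = "grey40") +
    ggplot2::geom_hline(data = bands,
                        ggplot2::aes(yintercept = .data$y),
                        linetype = "dotted", colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flag_3sd)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "firebrick"),
                                 name = "≤ -3 SD") +
    ggplot2::labs(x = "rank (by mean log2 ratio)",
                  y = "mean log2 (treated / control)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_erosion
#' @method autoplot erosion_table
#' @export
autoplot.erosion_table <- function(x, ...) plot_erosion(x, ...)

#' Permutation-null histogram for an enrichment result
#'
#' @param x An `enrichment_result` from [clustered_permutation_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(x, ...) {
  ggplot2::ggplot(tibble(null = x$null), ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = x$observed, colour = "firebrick") +
    ggplot2::labs(x = "null window hits per permutation",
                  y = "permutations",
                  title = sprintf("observed = %d, p = %.3g, z = %.2f",
                                  x$observed, x$p_value, x$z_score)) +
    ggplot2::theme_minimal()
}

#' Microhomology spectrum plot (mean +/- SEM across libraries)
#'
#' @param spectrum Output of [mh_spectrum()]; one or more conditions can be
#'   compared by passing a list named by condition.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_mh_spectrum <- function(spectrum, ...) {
  if (!is.data.frame(spectrum) && is.list(spectrum)) {
    spectrum <- dplyr::bind_rows(purrr::map(spectrum, mh_spectrum_summary),
                                 .id = "condition")
  } else {
    spectrum <- mh_spectrum_summary(spectrum)
    spectrum$condition <- "all"
  }
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(x = .data$mh, y = .data$mean_freq,
                               fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_freq - .data$sem,
                                        ymax = .data$mean_freq + .data$sem),
                           position = ggplot2::position_dodge(width = 0.9),
                           width = 0.3) +
    ggplot2::labs(x = "microhomology length (bp)",
                  y = "junction frequency") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
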