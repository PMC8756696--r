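# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of differential abundance
#'
#' @param object A `dap_tbl`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dap_tbl <- function(object, ...) {
  df <- dplyr::filter(object, .data$status != "untestable")
  thr <- attr(object, "lfc_threshold")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p_value),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-thr, thr), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(
      up = "#d73027", down = "#4575b4", not_significant = "grey70"
    )) +
    ggplot2::labs(
      x = sprintf("log2(%s / %s)", attr(object, "tissue_a"),
                  attr(object, "tissue_b")),
      y = "-log10 p", colour = NULL,
      title = "Differential protein abundance"
    ) +
    ggplot2::theme_minimal()
}

#' Homeolog bias plot (log2 A/B against significance)
#'
#' @param object A `bias_tbl`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bias_tbl <- function(object, ...) {
  df <- dplyr::filter(object, .data$class != "untestable")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_ratio_AB,
                                   y = -log10(.data$p_value),
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::geom_vline(xintercept = c(-2, 2), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(
      A_biased = "#d73027", B_biased = "#4575b4", unbiased = "grey70"
    )) +
    ggplot2::labs(x = "log2(sub-genome A / sub-genome B)", y = "-log10 p",
                  colour = NULL, title = "Homeolog abundance bias") +
    ggplot2::theme_minimal()
}

#' Ka/Ks distribution by relation class
#'
#' @param object A `kaks_tbl`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kaks_tbl <- function(object, ...) {
  df <- dplyr::filter(object, !.data$excluded)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$relation, y = .data$ratio)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = NULL, y = "Ka / Ks",
                  title = "Selective pressure by homolog class") +
    ggplot2::theme_minimal()
}
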