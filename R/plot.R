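#' Plot potential DEGs on their OR / FP / dFP indexes
#'
#' Scatter of the potential DEGs with OR on the vertical axis, mean FP on
#' the horizontal axis, marker area inversely proportional to mean dFP,
#' colour by cluster, and relaxed-selected genes drawn as triangles. Genes
#' in the top-left (high OR, low FP, large symbol) are the clearest DEGs.
#'
#' @param object A `degor_fit` from [find_degs()].
#' @param eps Floor added to dFP before inversion (default 1e-10).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.degor_fit <- function(object, eps = 1e-10, ...) {
  genes <- object$genes
  if (nrow(genes) == 0L) stop("no potential DEGs to plot")
  genes <- dplyr::mutate(
    genes,
    inv_dfp = 1 / (.data$dfp + eps),
    selection = factor(ifelse(.data$relaxed, "relaxed DEG", "not selected"),
                       levels = c("relaxed DEG", "not selected")),
    cluster = factor(.data$cluster)
  )
  ggplot2::ggplot(genes, ggplot2::aes(x = .data$fp, y = .data$or)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$inv_dfp,
                                     colour = .data$cluster,
                                     shape = .data$selection),
                        alpha = 0.8) +
    ggplot2::scale_shape_manual(values = c("relaxed DEG" = 17,
                                           "not selected" = 16),
                                drop = FALSE) +
    ggplot2::scale_size_area(max_size = 6, guide = "none") +
    ggplot2::labs(x = "mean FP neighbours", y = "OR",
                  colour = "cluster", shape = NULL,
                  title = "Potential DEGs: outlier ratio vs false-positive neighbourhood") +
    ggplot2::theme_minimal()
}

#' @export
plot.degor_fit <- function(x, ...) {
  print(autoplot.degor_fit(x, ...))
  invisible(x)
}

#' Save the index plot of a fitted result
#'
#' @param fit A `degor_fit`.
#' @param path Output image path (extension selects the device, e.g.
#'   `.png` or `.svg`).
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#' @return `path`, invisibly.
#' @export
save_score_plot <- function(fit, path, width = 7, height = 5, dpi = 150) {
  p <- autoplot.degor_fit(fit)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  invisible(path)
}
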