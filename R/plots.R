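#' Morphospace plot of the descriptor table
#'
#' Solidity against aspect ratio for every cell, coloured by the quartile
#' class of one metric - the undulation/base-shape morphospace view.
#'
#' @param metrics Cell metrics table (from [measure_outlines()]).
#' @param colour_by `"solidity"` or `"aspect_ratio"` quartiles.
#' @return A ggplot object.
#' @export
plot_morphospace <- function(metrics, colour_by = c("solidity", "aspect_ratio")) {
  colour_by <- match.arg(colour_by)
  metrics$quartile <- factor(quartile_classify(metrics[[colour_by]]))
  ggplot2::ggplot(metrics, ggplot2::aes(
    x = .data$aspect_ratio, y = .data$solidity, colour = .data$quartile)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_viridis_d(name = paste(colour_by, "quartile")) +
    ggplot2::labs(x = "aspect ratio (width / length)",
                  y = "solidity (area / hull area)") +
    ggplot2::theme_minimal()
}

#' Plot an outline (or several)
#'
#' @param object An [outline()].
#' @param ... Further outlines to overlay.
#' @return A ggplot object with fixed aspect.
#' @export
autoplot.outline <- function(object, ...) {
  olist <- c(list(object), list(...))
  df <- purrr::imap(olist, function(o, i) {
    v <- as_tibble.outline(o)
    v$outline <- paste0(i, ": ", attr(o, "label"))
    rbind(v, v[1, ])    # close the ring
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   group = .data$outline,
                                   colour = .data$outline)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' PCA biplot of the descriptor morphospace
#'
#' Scores on the first two components with the descriptor loading vectors
#' overlaid, optionally coloured by a grouping column carried through the
#' scores (e.g. `clade`).
#'
#' @param object A `pavecell_pca` from [pca_descriptors()].
#' @param colour Optional name of a score column to colour points by.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pavecell_pca <- function(object, colour = NULL, ...) {
  sc <- object$scores
  ve <- object$variance_explained
  arrow_scale <- 0.8 * min(
    diff(range(sc$PC1)) / max(abs(object$loadings$PC1)),
    diff(range(sc$PC2)) / max(abs(object$loadings$PC2))) / 2
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2))
  p <- if (!is.null(colour) && colour %in% names(sc)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                            alpha = 0.5, size = 1)
  } else {
    p + ggplot2::geom_point(alpha = 0.5, size = 1)
  }
  p +
    ggplot2::geom_segment(
      data = object$loadings,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * arrow_scale,
                   yend = .data$PC2 * arrow_scale),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "black") +
    ggplot2::geom_text(
      data = object$loadings,
      ggplot2::aes(x = .data$PC1 * arrow_scale * 1.1,
                   y = .data$PC2 * arrow_scale * 1.1,
                   label = .data$descriptor), size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ve[2])) +
    ggplot2::theme_minimal()
}

#' Local Moran's I per tip
#'
#' Lollipop view of the per-tip statistic with hotspot tips highlighted.
#'
#' @param object A `pavecell_moran` from [local_moran()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pavecell_moran <- function(object, ...) {
  df <- tidy(object)
  df$tip <- factor(df$tip, levels = df$tip)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tip, y = .data$local_i,
                                   colour = .data$hotspot)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$tip, yend = 0)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "local Moran's I") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 5,
                                                       vjust = 0.5))
}
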