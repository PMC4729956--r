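#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's objects: images as
#' rasters (nm axes), peptides and assemblies as bead maps coloured by
#' polarity, pore graphs as segment plots.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name pepnet-plots
NULL

#' @rdname pepnet-plots
#' @export
autoplot.stm_image <- function(object, ...) {
  df <- expand.grid(ix = seq_len(nrow(object$pixels)),
                    iy = seq_len(ncol(object$pixels)))
  df$x <- object$origin[1] + (df$ix - 1) * object$pixel_size
  df$y <- object$origin[2] + (df$iy - 1) * object$pixel_size
  df$value <- as.vector(object$pixels)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "orange",
                                 name = if (object$mode == "constant_height_ldos")
                                   "density" else "height (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

bead_plot <- function(beads) {
  ggplot2::ggplot(dplyr::filter(beads, .data$kind != "backbone"),
                  ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(data = dplyr::filter(beads, .data$kind == "backbone"),
                       ggplot2::aes(group = .data$grp),
                       colour = "grey40", linewidth = 0.7) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$polarity,
                                     shape = .data$kind), size = 2) +
    ggplot2::scale_colour_manual(values = c(polar = "darkorange",
                                            nonpolar = "forestgreen")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' @rdname pepnet-plots
#' @export
autoplot.peptide2d <- function(object, ...) {
  bead_plot(dplyr::mutate(object$beads, grp = 1L))
}

#' @rdname pepnet-plots
#' @export
autoplot.dimer <- function(object, ...) {
  bead_plot(dplyr::mutate(assembly_beads(object), grp = .data$peptide))
}

#' @rdname pepnet-plots
#' @export
autoplot.assembly_model <- function(object, ...) {
  b <- object$beads
  b$grp <- if ("dimer" %in% names(b)) paste(b$dimer, b$peptide) else b$peptide
  bead_plot(b)
}

#' @rdname pepnet-plots
#' @export
autoplot.honeycomb_network <- function(object, ...) {
  b <- object$beads
  b$grp <- paste(b$edge, b$peptide)
  bead_plot(b)
}

#' @rdname pepnet-plots
#' @export
autoplot.pore_graph <- function(object, ...) {
  seg <- tibble::tibble(
    x = object$vertices$x[object$edges$v1],
    y = object$vertices$y[object$edges$v1],
    xend = object$vertices$x[object$edges$v2],
    yend = object$vertices$y[object$edges$v2])
  ggplot2::ggplot(seg, ggplot2::aes(.data$x, .data$y,
                                    xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_segment(colour = "grey30") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}
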