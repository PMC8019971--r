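# ggplot2 visualisation of fitted spectra, ROI distributions and maps.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a fitted T2 spectrum
#'
#' Spectrum amplitude over the log T2 axis with the compartment boundaries
#' marked.
#'
#' @param object A `t2_spectrum`.
#' @param bounds A [compartment_bounds()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot t2_spectrum
#' @export
autoplot.t2_spectrum <- function(object, bounds = compartment_bounds(), ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t2, y = .data$amplitude)) +
    ggplot2::geom_area(ggplot2::aes(fill = .data$compartment), alpha = 0.4) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(bounds$myelin_max, bounds$iew_max),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "T2 (ms)", y = "amplitude", fill = "pool",
      title = sprintf("T2 spectrum (flip %.1f deg, mu %.3g)",
                      object$flip_angle, object$mu)
    ) +
    ggplot2::theme_minimal()
}

#' Plot one or two ROI T2 distributions
#'
#' @param object A `t2_distribution`.
#' @param ... Further `t2_distribution` objects to overlay.
#' @return A ggplot.
#' @method autoplot t2_distribution
#' @export
autoplot.t2_distribution <- function(object, ...) {
  dists <- c(list(object), list(...))
  df <- dplyr::bind_rows(lapply(dists, function(d) {
    tibble::tibble(support = d$support, density = d$density,
                   roi = attr(d, "source"))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$support, y = .data$density,
                                   colour = .data$roi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "IEw T2 (ms)", y = "density (1/ms)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of one quantitative map
#'
#' @param mapset A `t2_map_set`.
#' @param map Map name (e.g. `"iew_t2"`, `"myelin_fraction"`).
#' @param slice Axial (k) slice index; defaults to the middle slice.
#' @return A ggplot raster.
#' @export
plot_map <- function(mapset, map = "iew_t2", slice = NULL) {
  stopifnot(inherits(mapset, "t2_map_set"), map %in% names(mapset$maps))
  if (is.null(slice)) slice <- ceiling(mapset$dim[3] / 2)
  m <- mapset$maps[[map]][, , slice]
  df <- tibble::tibble(
    i = as.vector(row(m)), j = as.vector(col(m)), value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s, slice %d", map, slice),
                  x = NULL, y = NULL, fill = map) +
    ggplot2::theme_minimal()
}
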