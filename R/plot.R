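#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a categorical raster
#'
#' @param object A `cat_raster`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cat_raster
#' @export
autoplot.cat_raster <- function(object, ...) {
  d <- as_tibble.pw_raster(object)
  d$label <- object$legend[as.character(d$value)]
  d$label[is.na(d$label)] <- "nodata"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = NULL, x = NULL, y = NULL)
}

#' Plot a population or error raster
#'
#' Population surfaces are drawn on a sequential fill; signed error rasters
#' look best with `diverging = TRUE`, colouring underestimation blue and
#' overestimation red around zero.
#'
#' @param object A `value_raster`.
#' @param diverging Use a diverging palette centred at zero.
#' @param trans Scale transformation for the fill (e.g. `"sqrt"`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot value_raster
#' @export
autoplot.value_raster <- function(object, diverging = FALSE, trans = "identity", ...) {
  d <- as_tibble.pw_raster(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "persons/cell", x = NULL, y = NULL)
  if (diverging) {
    p + ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                      midpoint = 0, na.value = "grey90")
  } else {
    p + ggplot2::scale_fill_viridis_c(trans = trans, na.value = "grey90")
  }
}

#' Observed-versus-estimated scatter per method
#'
#' One panel per redistribution method, each fine admin unit a point, with
#' the 1:1 line; the closer the cloud hugs the line, the better the method
#' reproduces the held-out fine-level counts.
#'
#' @param pairs Stacked [evaluate()] pairs (columns `observed`, `estimated`,
#'   `method`).
#' @param log10 Plot both axes on log10 (zeros dropped).
#' @return A ggplot.
#' @export
plot_obs_vs_est <- function(pairs, log10 = FALSE) {
  d <- tibble::as_tibble(pairs)
  if (log10) d <- d[d$observed > 0 & d$estimated > 0, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$observed, y = .data$estimated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "observed (persons)", y = "estimated (persons)")
  if (log10) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}
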