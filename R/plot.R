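#' @export
tidy.gel_profile <- function(x, baseline = NULL, ...) {
  out <- tibble::tibble(row = x$row, intensity = x$intensity)
  if (!is.null(baseline)) out$baseline <- baseline_at(baseline, x$row)
  out
}

#' @export
glance.gel_profile <- function(x, ...) {
  tibble::tibble(rows = nrow(x), y_start = x$row[1],
                 total = sum(x$intensity), peak = max(x$intensity))
}

#' Plot a lane intensity profile
#'
#' Intensity as a function of the vertical migration coordinate, optionally
#' with the per-lane baseline overlaid, the way the profile is inspected
#' when choosing integration bounds.
#'
#' @param object a `gel_profile` from [lane_profile()].
#' @param baseline optional [gel_baseline()] to overlay.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.gel_profile <- function(object, baseline = NULL, ...) {
  d <- tidy.gel_profile(object, baseline = baseline)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$row, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "image row (migration direction)",
                  y = "lane intensity (intensity · px)")
  if (!is.null(baseline)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$baseline),
                                linetype = "dashed", colour = "red")
  }
  p
}

#' Plot a raster as an intensity image
#'
#' @param object a [gel_raster()].
#' @param ... unused.
#' @return A ggplot with reversed y so migration runs downwards.
#' @export
autoplot.gel_raster <- function(object, ...) {
  m <- as_pixel_matrix(object)
  d <- tidyr::expand_grid(row = 0:(nrow(m) - 1L), col = 0:(ncol(m) - 1L))
  d$intensity <- as.vector(t(m))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (px)", y = "row (px)")
}

#' @export
plot.gel_profile <- function(x, y, ...) print(autoplot.gel_profile(x, ...))

#' @export
plot.gel_raster <- function(x, y, ...) print(autoplot.gel_raster(x, ...))
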