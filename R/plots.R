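#' Plot a cross-section: lumen contour, rays and calcification intervals
#'
#' @param object one element of `cross_sections$sections` (a valid slice).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cross_section <- function(object, ...) plot_cross_section(object)

#' @rdname autoplot.cross_section
#' @param cs a valid slice from `cross_sections$sections`.
#' @export
plot_cross_section <- function(cs) {
  stopifnot(isTRUE(cs$valid))
  contour <- tibble::tibble(x = cs$contour[, 1], y = cs$contour[, 2])
  p <- ggplot2::ggplot(contour, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_polygon(fill = "steelblue", alpha = 0.3,
                          colour = "steelblue") +
    ggplot2::annotate("point", x = cs$centroid[1], y = cs$centroid[2],
                      shape = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u (mm)", y = "v (mm)",
                  title = sprintf("s = %.1f mm, lumen %.2f mm^2",
                                  cs$s_mm, cs$area_mm2)) +
    ggplot2::theme_minimal()
  if (!is.null(cs$calc_intervals)) {
    has <- which(!vapply(cs$calc_intervals, is.null, logical(1)))
    if (length(has)) {
      segs <- dplyr::bind_rows(lapply(has, function(j) {
        iv <- cs$calc_intervals[[j]]
        th <- cs$theta_deg[j] * pi / 180
        tibble::tibble(x = cs$centroid[1] + iv[, 1] * cos(th),
                       y = cs$centroid[2] + iv[, 1] * sin(th),
                       xend = cs$centroid[1] + iv[, 2] * cos(th),
                       yend = cs$centroid[2] + iv[, 2] * sin(th))
      }))
      p <- p + ggplot2::geom_segment(
        data = segs, ggplot2::aes(x = .data$x, y = .data$y,
                                  xend = .data$xend, yend = .data$yend),
        colour = "goldenrod3", linewidth = 0.8)
    }
  }
  p
}

#' Plot the lumen area and stenosis profile along the artery
#'
#' @param analysis an `artery_analysis` (with calcification present for the
#'   stenosis panel).
#' @return a ggplot.
#' @export
plot_stenosis_profile <- function(analysis) {
  tab <- analysis$slices[analysis$slices$valid, ]
  p <- ggplot2::ggplot(tab, ggplot2::aes(.data$s_mm, .data$lumen_area_mm2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "arclength s (mm)", y = "lumen area (mm^2)") +
    ggplot2::theme_minimal()
  if (!is.null(analysis$stenosis)) {
    ps <- analysis$stenosis$per_slice
    p <- p + ggplot2::geom_point(
      data = ps, ggplot2::aes(.data$s_mm, .data$a_mm2),
      colour = "goldenrod3", size = 0.6) +
      ggplot2::geom_hline(
        yintercept = analysis$stenosis$regions$a_ref_mm2,
        linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot the curvature profile with Bouthillier boundaries
#'
#' @param cl a `centerline`.
#' @param labels optional `segment_labels` to mark boundaries.
#' @return a ggplot.
#' @export
plot_curvature <- function(cl, labels = NULL) {
  df <- tidy.centerline(cl)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$s_mm, .data$curvature)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "arclength s (mm)", y = "curvature (1/mm)") +
    ggplot2::theme_minimal()
  if (!is.null(labels))
    p <- p + ggplot2::geom_vline(xintercept = labels$boundaries_mm,
                                 linetype = "dotted", colour = "firebrick")
  p
}
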