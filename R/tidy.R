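#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an artery analysis into a long metric table
#'
#' @param x an `artery_analysis`.
#' @param ... unused.
#' @return tibble with `metric`, `value` (numeric metrics only) columns.
#' @export
tidy.artery_analysis <- function(x, ...) {
  num <- dplyr::select(x$record, dplyr::where(is.numeric))
  tidyr::pivot_longer(num, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.artery_analysis
#' @export
glance.artery_analysis <- function(x, ...) x$record

#' Tidy a stenosis result
#'
#' @param x a `stenosis_result`.
#' @param ... unused.
#' @return the per-slice stenosis tibble (`index`, `s_mm`, `region`,
#'   `a_mm2`, `s_i_percent`).
#' @export
tidy.stenosis_result <- function(x, ...) x$per_slice

#' @rdname tidy.stenosis_result
#' @export
glance.stenosis_result <- function(x, ...) {
  dplyr::mutate(
    dplyr::summarise(x$regions,
                     n_regions = dplyr::n(),
                     max_cumulative_percent = max(.data$s_c_percent)),
    max_local_percent = x$max_local_percent,
    severity = x$severity)
}

#' Tidy a centerline into a point table
#'
#' @param x a `centerline`.
#' @param ... unused.
#' @return tibble: `x`, `y`, `z`, `s_mm`, `curvature`.
#' @export
tidy.centerline <- function(x, ...) {
  pts <- x$points
  s <- x$arclength
  k <- x$curvature
  tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 s_mm = s, curvature = k)
}
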