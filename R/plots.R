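# ggplot2 views of the diagnostic and result objects

#' Plot a shape trajectory
#'
#' Two stacked panels over the effective sample size `k`: the ML shape
#' estimate with its Gaussian confidence band, and the implied right
#' endpoint where the shape is negative. The stability region -- the
#' stretch where the shape curve flattens -- is what guides the choice of
#' `k`.
#'
#' @param object A [shape_trajectory()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shape_trajectory
#' @export
autoplot.shape_trajectory <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(object, k = .data$k, panel = "shape estimate",
                     value = .data$gamma, lo = .data$ci_lower,
                     hi = .data$ci_upper),
    dplyr::transmute(object, k = .data$k, panel = "right endpoint (t/ha)",
                     value = .data$endpoint, lo = NA_real_, hi = NA_real_)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      fill = "grey70", alpha = 0.5, na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "effective sample size k", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an analysis report
#'
#' Right-endpoint estimates with their truncated confidence intervals,
#' one row per analysis block. Truncated lower bounds (raised to the
#' sample maximum) are drawn with a flat cap.
#'
#' @param object A `"yield_report"` from [run_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot yield_report
#' @export
autoplot.yield_report <- function(object, ...) {
  tbl <- dplyr::filter(object$table, !is.na(.data$endpoint))
  if (nrow(tbl) == 0L) abort("No finite endpoint estimates to plot.")
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$endpoint, y = .data$stratum)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$endpoint_lower, xmax = .data$endpoint_upper),
      height = 0.2, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(
      data = dplyr::filter(tbl, .data$truncated),
      ggplot2::aes(x = .data$endpoint_lower), shape = "|", size = 4) +
    ggplot2::labs(x = "maximum attainable yield (t/ha)", y = NULL,
                  caption = "bars: truncated 95% intervals; tick: lower bound at the sample maximum") +
    ggplot2::theme_minimal()
}
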