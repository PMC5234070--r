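#' Plot methods
#'
#' `autoplot()` methods give quick-look ggplot figures for the tabular
#' result types: the min-singular-value scan (log scale, protected window
#' visible as a collapse to numerical zero), localization profiles
#' (log-mass against column, exponential flanks are straight lines),
#' adaptation sweeps (activity pinning and methylation tracking), and
#' empirical occupancies.
#'
#' @param object A stochtopo result tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @name stochtopo-plots
NULL

#' @rdname stochtopo-plots
#' @export
autoplot.smin_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = lam, y = smin2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(lambda),
                  y = expression(s[min]^2 ~ of ~ W(lambda)),
                  title = "Smallest singular value of the tilted generator")
}

#' @rdname stochtopo-plots
#' @export
autoplot.localization_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = x, y = mass)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "column", y = "probability mass",
                  title = "Column marginal of the steady state")
}

#' @rdname stochtopo-plots
#' @export
autoplot.adaptation_sweep <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(S = object$S, value = object$mean_activity,
                   quantity = "mean activity"),
    tibble::tibble(S = object$S, value = object$mean_methylation,
                   quantity = "mean methylation"))
  ggplot2::ggplot(long, ggplot2::aes(x = S, y = value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "S (log chemoattractant concentration)", y = NULL,
                  title = "Adaptation sweep")
}

#' @rdname stochtopo-plots
#' @export
autoplot.occupancy_estimate <- function(object, ...) {
  prof <- dplyr::summarise(dplyr::group_by(object, x),
                           occupancy = sum(occupancy), .groups = "drop")
  ggplot2::ggplot(prof, ggplot2::aes(x = x, y = occupancy)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "column", y = "time-weighted occupancy",
                  title = "Empirical column occupancy")
}

#' Winding number as a function of the tilt field
#'
#' Convenience scan of `winding_number()` over a grid (skipping `lam = 0`),
#' useful to visualize the piecewise-constant winding and its transitions.
#'
#' @param cell A [bulk_cell()].
#' @param lam_values Grid of tilt values.
#' @param n_k Grid size passed to [winding_number()].
#' @return Tibble with `lam`, `w` (NA where the evaluation failed).
#' @export
winding_profile <- function(cell, lam_values, n_k = 512L) {
  lam_values <- lam_values[lam_values != 0]
  w <- vapply(lam_values, function(l) {
    tryCatch(as.double(winding_number(cell, l, n_k)$w),
             error = function(e) NA_real_)
  }, numeric(1))
  tibble::tibble(lam = lam_values, w = w)
}
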