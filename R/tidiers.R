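#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy methods for stochtopo results
#'
#' broom-style accessors: `tidy()` returns per-component rows, `glance()` a
#' one-row summary.
#'
#' @param x A stochtopo result object.
#' @param ... Unused.
#' @return A tibble.
#' @name stochtopo-tidiers
NULL

#' @rdname stochtopo-tidiers
#' @export
tidy.spectral_result <- function(x, ...) {
  tibble::tibble(id = names(x$leading_right),
                 leading_right = unname(x$leading_right),
                 leading_left = unname(x$leading_left))
}

#' @rdname stochtopo-tidiers
#' @export
glance.spectral_result <- function(x, ...) {
  tibble::tibble(lam = x$lam, e_lam = x$e_lam, gap = x$gap,
                 n_states = x$n_states, open_flag = x$open_flag)
}

#' @rdname stochtopo-tidiers
#' @export
tidy.winding_result <- function(x, ...) {
  tibble::tibble(lam = x$lam, w = x$w, min_abs_det = x$min_abs_det)
}

#' @rdname stochtopo-tidiers
#' @export
tidy.topo_window <- function(x, ...) {
  tibble::tibble(lam_minus = x$lam_minus, lam_plus = x$lam_plus, dw = x$dw,
                 eta_left = x$eta_left, eta_right = x$eta_right,
                 empty = x$empty)
}

#' @rdname stochtopo-tidiers
#' @export
glance.topo_window <- tidy.topo_window

#' @rdname stochtopo-tidiers
#' @export
tidy.zero_mode_set <- function(x, ...) {
  one_side <- function(modes, side) {
    if (!ncol(modes)) return(NULL)
    purrr::map_dfr(seq_len(ncol(modes)), function(j) {
      tibble::tibble(side = side, mode = j,
                     id = rownames(modes), weight = modes[, j])
    })
  }
  dplyr::bind_rows(one_side(x$right_modes, "right"),
                   one_side(x$left_modes, "left"))
}

#' @rdname stochtopo-tidiers
#' @export
glance.zero_mode_set <- function(x, ...) {
  tibble::tibble(lam = x$lam, n_right = ncol(x$right_modes),
                 n_left = ncol(x$left_modes), tol = x$tol,
                 smallest_singular = min(x$singular_values))
}

#' @rdname stochtopo-tidiers
#' @export
glance.occupancy_estimate <- function(x, ...) {
  tibble::tibble(current = attr(x, "current"),
                 current_se = attr(x, "current_se"),
                 t_total = attr(x, "t_total"))
}
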