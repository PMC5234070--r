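#' Zero modes of the tilted generator
#'
#' Finds right null vectors (`W(lam) v = 0`) and left null vectors
#' (`W(lam)^T u = 0`) through the singular value decomposition: a mode is
#' counted for every singular value below `tol` times the largest. The
#' tolerance is relative because on a finite network the topological zero
#' mode is split by an amount exponentially small in the bulk width (the
#' default presumes at least ~30 columns per bulk at decay rate ~log 2).
#' At `lam = 0` there is always exactly one right mode (the steady state)
#' and one left mode (the uniform vector).
#'
#' @param net A `stoch_network`.
#' @param lam Tilt field.
#' @param tol Relative singular-value threshold.
#' @return A `zero_mode_set`: list with matrices `right_modes` and
#'   `left_modes` (columns are unit-1-norm modes, rows named by node id),
#'   the singular values, and `tol`.
#' @export
zero_modes <- function(net, lam, tol = 1e-6) {
  W <- tilt_generator(build_generator(net), net, lam)
  sv <- svd(W)
  small <- which(sv$d <= tol * sv$d[1])
  norm1 <- function(m) {
    if (!ncol(m)) return(m)
    apply(m, 2, function(v) {
      v <- v / sum(abs(v))
      if (v[which.max(abs(v))] < 0) v <- -v
      v
    })
  }
  right <- norm1(sv$v[, small, drop = FALSE])
  left <- norm1(sv$u[, small, drop = FALSE])
  if (length(small)) rownames(right) <- rownames(left) <- net$nodes$id
  structure(list(right_modes = right, left_modes = left,
                 singular_values = sv$d, tol = tol, lam = lam),
            class = "zero_mode_set")
}

#' @export
print.zero_mode_set <- function(x, ...) {
  cat(sprintf("<zero_mode_set> lam = %g: %d right / %d left modes (tol %g rel)\n",
              x$lam, ncol(x$right_modes), ncol(x$left_modes), x$tol))
  invisible(x)
}

#' Fraction of a mode's mass inside a region
#'
#' `sum(|v_i|, i in region) / sum(|v_i|)`; operationalizes "zero mode
#' contained in the interfacial region".
#'
#' @param v Named vector (names are node ids).
#' @param region Character vector of node ids (see [region_columns()]).
#' @return Number in `[0, 1]`.
#' @export
localization_fraction <- function(v, region) {
  tot <- sum(abs(v))
  if (tot == 0) stop("cannot localize the zero vector")
  if (is.null(names(v))) stop("v must be named by node id")
  sum(abs(v[intersect(names(v), region)])) / tot
}

#' Local index of the tilted generator at an interface
#'
#' Counts right zero modes minus left zero modes whose 1-norm mass is
#' majority-localized in the given region. By the bulk-boundary
#' correspondence this equals the winding mismatch `dw = w_L - w_R` of the
#' bulks flanking the region. Ties at exactly `frac` are broken toward "not
#' in region" so the index errs conservative.
#'
#' @inheritParams zero_modes
#' @param region Character vector of node ids defining the interface region.
#' @param frac Mass fraction required to assign a mode to the region.
#' @return Integer.
#' @export
local_index <- function(net, lam, region, tol = 1e-6, frac = 0.5) {
  region <- intersect(region, net$nodes$id)
  if (!length(region)) stop("region contains no nodes of the network")
  zm <- zero_modes(net, lam, tol)
  count_in <- function(modes) {
    if (!ncol(modes)) return(0L)
    sum(apply(modes, 2, function(v) localization_fraction(v, region) > frac))
  }
  as.integer(count_in(zm$right_modes) - count_in(zm$left_modes))
}

#' Dimension of the kernel of the composed matrix rho W(lam)
#'
#' Diagnostic companion to [local_index()]: the literal reading of the local
#' index through `dim ker(rho W(lam))`, with `rho` the 0/1 diagonal projector
#' on the region. Exposed for comparison; the localized-mode counting of
#' [local_index()] is the operative definition here.
#'
#' @inheritParams local_index
#' @return Integer kernel dimension (relative tolerance `tol`).
#' @export
local_kernel_dim <- function(net, lam, region, tol = 1e-6) {
  W <- tilt_generator(build_generator(net), net, lam)
  rho <- as.numeric(net$nodes$id %in% region)
  M <- rho * W
  d <- svd(M, nu = 0, nv = 0)$d
  as.integer(sum(d <= tol * max(d)))
}

#' Per-column marginals of a probability vector
#'
#' Sums a probability (or mode magnitude) vector over the rows of each
#' column, yielding the horizontal profile whose exponential decay the
#' topological analysis predicts.
#'
#' @param net A `stoch_network`.
#' @param p Named vector over the nodes.
#' @return A `localization_profile` tibble with columns `x`, `mass`.
#' @export
column_marginals <- function(net, p) {
  df <- tibble::tibble(x = net$nodes$x, mass = abs(as.numeric(p[net$nodes$id])))
  out <- dplyr::summarise(dplyr::group_by(df, x), mass = sum(mass), .groups = "drop")
  out <- dplyr::arrange(out, x)
  class(out) <- c("localization_profile", class(out))
  out
}

#' Fit an exponential decay rate to a column profile
#'
#' Least-squares slope of `log(mass)` against column index over a contiguous
#' column range; `kappa` is reported positive (decay away from the
#' interface) with the fit quality `r2`. Compare against
#' [bulk_decay_rates()] of the flanking bulk.
#'
#' @param profile A `localization_profile` (or any tibble with `x`, `mass`).
#' @param columns Contiguous integer range of columns to fit (at least 4).
#' @return List with `kappa`, `r2` and the signed `slope`.
#' @export
fit_decay <- function(profile, columns) {
  sub <- profile[profile$x %in% as.integer(columns), ]
  if (nrow(sub) < 4) stop("need at least 4 columns to fit a decay rate")
  if (any(sub$mass <= 0)) {
    stop("non-positive column marginal in the fit range (column ",
         sub$x[which(sub$mass <= 0)[1]], ")")
  }
  fit <- stats::lm(log(mass) ~ x, data = sub)
  slope <- unname(stats::coef(fit)[2])
  # summary.lm warns on an exactly exponential profile ("perfect fit")
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (is.nan(r2)) r2 <- 1 # zero-variance (flat) profile fits exactly
  list(kappa = abs(slope), r2 = r2, slope = slope)
}

#' Scan the smallest singular value of W(lam) over a tilt grid
#'
#' For each grid value the smallest eigenvalue of `W(lam) W(lam)^T`, i.e. the
#' squared smallest singular value of the tilted generator. Within the
#' protected window this quantity collapses to zero (a zero mode exists);
#' outside it is bounded away from zero. The numerical window read off this
#' scan converges to the bulk prediction (`lambda_window()`) as the bulks
#' grow.
#'
#' @param net A `stoch_network`.
#' @param lam_grid Numeric vector of tilt values (0 is allowed here).
#' @return A `smin_scan` tibble with columns `lam`, `smin2`.
#' @export
min_singular_scan <- function(net, lam_grid) {
  gen <- build_generator(net)
  smin2 <- vapply(lam_grid, function(l) {
    d <- tryCatch(svd(tilt_generator(gen, net, l), nu = 0, nv = 0)$d,
                  error = function(e) NA_real_)
    min(d)^2
  }, numeric(1))
  out <- tibble::tibble(lam = as.numeric(lam_grid), smin2 = smin2)
  class(out) <- c("smin_scan", class(out))
  out
}
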