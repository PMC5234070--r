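#' Translationally invariant bulk unit cells
#'
#' A `bulk_cell` describes one repeating column of a translationally
#' invariant bulk: `intra` holds within-column rates (entry `(i, j)` is the
#' rate `j -> i`, zero diagonal), `hop_plus` rates into the next column to
#' the right, `hop_minus` into the previous column. The induced single-cell
#' generator (intra + both hops with an outflow diagonal) has zero column
#' sums by construction.
#'
#' @param intra B x B non-negative matrix of within-column rates.
#' @param hop_plus,hop_minus B x B non-negative matrices of rates to the
#'   column to the right / left.
#' @return An object of class `bulk_cell` with fields `n_internal`, `intra`,
#'   `hop_plus`, `hop_minus`.
#' @export
#' @examples
#' bulk_cell_1d(2, 1)              # biased single-row bulk
#' topological_charge(bulk_cell_1d(2, 1))
bulk_cell <- function(intra, hop_plus, hop_minus) {
  intra <- as.matrix(intra); hop_plus <- as.matrix(hop_plus); hop_minus <- as.matrix(hop_minus)
  B <- nrow(intra)
  stopifnot(ncol(intra) == B, all(dim(hop_plus) == B), all(dim(hop_minus) == B))
  if (any(intra < 0) || any(hop_plus < 0) || any(hop_minus < 0)) {
    stop("all cell rates must be non-negative")
  }
  if (any(diag(intra) != 0)) stop("intra must have a zero diagonal (no self-rates)")
  if (all(hop_plus == 0) || all(hop_minus == 0)) {
    stop("cell must have at least one positive rate in each hop direction")
  }
  structure(list(n_internal = B, intra = intra,
                 hop_plus = hop_plus, hop_minus = hop_minus),
            class = "bulk_cell")
}

#' @param p,q Rightward and leftward hop rates of a single-row bulk.
#' @rdname bulk_cell
#' @export
bulk_cell_1d <- function(p, q) {
  bulk_cell(matrix(0, 1, 1), matrix(p, 1, 1), matrix(q, 1, 1))
}

#' @export
print.bulk_cell <- function(x, ...) {
  cat(sprintf("<bulk_cell> B = %d states per column\n", x$n_internal))
  invisible(x)
}

# total untilted outflow diagonal of the cell generator
cell_outflow_diag <- function(cell) {
  -(colSums(cell$intra) + colSums(cell$hop_plus) + colSums(cell$hop_minus))
}

#' Bloch matrix of a bulk unit cell
#'
#' Fourier transform of the tilted translationally invariant bulk generator:
#' `W(k, lam) = intra + hop_plus e^{ik + lam} + hop_minus e^{-ik - lam} + D`
#' with `D` the diagonal of total untilted outflow. Periodic in `k` with
#' period `2*pi`; at `k = 0, lam = 0` probability conservation forces
#' `det W = 0`.
#'
#' @param cell A [bulk_cell()].
#' @param k Wave vector.
#' @param lam Tilt field.
#' @return B x B complex matrix.
#' @export
bloch_matrix <- function(cell, k, lam) {
  cell$intra + cell$hop_plus * exp(1i * k + lam) +
    cell$hop_minus * exp(-1i * k - lam) +
    diag(cell_outflow_diag(cell), cell$n_internal)
}

# base det() has no complex method; closed forms for the small cells used
# here, eigenvalue product as the general fallback
complex_det <- function(M) {
  n <- nrow(M)
  if (n == 1L) return(M[1, 1])
  if (n == 2L) return(M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1])
  if (n == 3L) {
    return(M[1, 1] * (M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2]) -
             M[1, 2] * (M[2, 1] * M[3, 3] - M[2, 3] * M[3, 1]) +
             M[1, 3] * (M[2, 1] * M[3, 2] - M[2, 2] * M[3, 1]))
  }
  prod(eigen(M, only.values = TRUE)$values)
}

bloch_dets <- function(cell, ks, lam) {
  if (cell$n_internal == 1L) {
    as.complex(cell$intra[1, 1] + cell$hop_plus[1, 1] * exp(1i * ks + lam) +
                 cell$hop_minus[1, 1] * exp(-1i * ks - lam) +
                 cell_outflow_diag(cell))
  } else {
    vapply(ks, function(k) complex_det(bloch_matrix(cell, k, lam)), complex(1))
  }
}

#' Winding number of the Bloch-determinant phase
#'
#' Writes the Bloch determinant as `D(k, lam) = |D| e^{i theta}` and counts
#' the net number of turns of the phase `theta` as `k` runs through one
#' Brillouin zone. The sign convention is fixed so that a rightward-biased
#' single-row bulk at `lam > 0` has `w = +1`. The winding is undefined at
#' `lam = 0`, where the determinant vanishes at `k = 0`.
#'
#' @param cell A [bulk_cell()].
#' @param lam Nonzero tilt field.
#' @param n_k Number of grid intervals over `[0, 2*pi]`.
#' @return A `winding_result`: list with integer `w`, `lam`, `min_abs_det`
#'   and the sampled unwrapped phase `theta_trajectory`.
#' @export
winding_number <- function(cell, lam, n_k = 512L) {
  if (lam == 0) {
    stop("winding number is undefined at lam = 0 (det vanishes at k = 0); ",
         "evaluate at small +/- offsets instead")
  }
  ks <- seq(0, 2 * pi, length.out = n_k + 1L)
  dets <- bloch_dets(cell, ks, lam)
  ab <- Mod(dets)
  if (min(ab) < 1e-10 * max(ab)) {
    stop(sprintf(
      "band touching: |det W(k, lam)| ~ 0 at k = %.6f (lam = %g); winding undefined",
      ks[which.min(ab)], lam))
  }
  dtheta <- diff(Arg(dets))
  dtheta <- dtheta - 2 * pi * round(dtheta / (2 * pi))
  if (any(abs(dtheta) > 0.9 * pi)) {
    stop("phase step close to pi between adjacent k points; increase n_k")
  }
  w_raw <- sum(dtheta) / (2 * pi)
  w <- as.integer(round(w_raw))
  if (abs(w - w_raw) > 1e-6) {
    stop(sprintf("phase winding %.8f is not an integer; increase n_k", w_raw))
  }
  structure(list(w = w, lam = lam, min_abs_det = min(ab),
                 theta_trajectory = cumsum(c(Arg(dets[1]), dtheta))),
            class = "winding_result")
}

#' @export
print.winding_result <- function(x, ...) {
  cat(sprintf("<winding_result> w = %d at lam = %g (min|det| = %.3g)\n",
              x$w, x$lam, x$min_abs_det))
  invisible(x)
}

# --- argument-principle oracle ------------------------------------------

poly_mul <- function(a, b) {
  res <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) res[i:(i + length(b) - 1L)] <- res[i:(i + length(b) - 1L)] + a[i] * b
  res
}

# det of a matrix of polynomials (lists of coefficient vectors), by cofactor
# expansion along the first column; fine for the B <= 3 cells used here.
poly_det <- function(P) {
  n <- nrow(P)
  if (n == 1L) return(P[[1, 1]])
  acc <- 0
  for (i in seq_len(n)) {
    minor <- P[-i, -1, drop = FALSE]
    term <- poly_mul(P[[i, 1]], poly_det(minor))
    if (i %% 2 == 0) term <- -term
    la <- max(length(acc), length(term))
    acc <- c(acc, numeric(la - length(acc))) + c(term, numeric(la - length(term)))
  }
  acc
}

cell_det_poly <- function(cell, lam) {
  # coefficients (z^0, z^1, z^2) of z * A_ij(z), A the Bloch matrix in z = e^{ik}
  B <- cell$n_internal
  Dg <- diag(cell_outflow_diag(cell), B)
  P <- matrix(vector("list", B * B), B, B)
  for (i in seq_len(B)) for (j in seq_len(B)) {
    P[[i, j]] <- c(cell$hop_minus[i, j] * exp(-lam),
                   cell$intra[i, j] + Dg[i, j],
                   cell$hop_plus[i, j] * exp(lam))
  }
  poly_det(P) # coefficients of Q(z) = z^B det A(z), ascending powers
}

#' Winding number by the argument principle (root-counting oracle)
#'
#' Independent route to [winding_number()]: substitute `z = e^{ik}` so the
#' Bloch determinant becomes a Laurent polynomial, clear the pole of order B
#' at the origin, and count polynomial roots inside the unit circle. The
#' winding equals (roots inside) - B. Used as a cross-check of the
#' phase-integral winding on every valid input.
#'
#' @inheritParams winding_number
#' @return List with integer `charge` and the complex `roots` of the cleared
#'   polynomial.
#' @export
winding_oracle_roots <- function(cell, lam) {
  if (lam == 0) stop("winding number is undefined at lam = 0")
  q <- cell_det_poly(cell, lam)
  while (length(q) > 1 && q[length(q)] == 0) q <- q[-length(q)]
  roots <- polyroot(q)
  on_circle <- abs(Mod(roots) - 1) < 1e-8
  if (any(on_circle)) {
    stop(sprintf("band touching: determinant root on the unit circle (|z| = %.10f)",
                 Mod(roots[on_circle][1])))
  }
  list(charge = as.integer(sum(Mod(roots) < 1) - cell$n_internal),
       roots = roots)
}

#' Topological charge of a bulk against the vacuum
#'
#' For a bulk that terminates at open ends (bulk-vs-vacuum geometry, as in
#' proofreading chains), the conventional single winding label is the sum of
#' the winding numbers evaluated just above and just below `lam = 0`.
#' A rightward-biased single-row bulk gives +1 (probability pushed to the
#' right end), a leftward-biased one -1, and a detailed-balance bulk 0.
#'
#' @param cell A [bulk_cell()].
#' @param eps Evaluation offset on each side of zero.
#' @param n_k Grid size passed to [winding_number()].
#' @return Integer.
#' @export
topological_charge <- function(cell, eps = 0.05, n_k = 512L) {
  stopifnot(eps > 0)
  winding_number(cell, eps, n_k)$w + winding_number(cell, -eps, n_k)$w
}

#' Bulk localization rates from determinant roots
#'
#' Roots `z*` of the untilted Bloch determinant `det W(z, lam = 0) = 0`
#' control the spatial profiles a bulk can sustain: a root with `|z*| < 1`
#' gives a decay rate `kappa = -log|z*|` (localization length `1/kappa`),
#' one with `|z*| > 1` a growth rate. The steady-state exponential profile in
#' a bulk decays at one of these rates. Roots on the unit circle (always
#' including `z = 1`, by conservation) are reported separately; if all roots
#' are on the circle the bulk is marginal/diffusive and a warning is issued.
#'
#' @param cell A [bulk_cell()].
#' @param tol Distance from the unit circle below which a root counts as
#'   marginal.
#' @return List with sorted numeric `decay` (kappa values), `growth`, and all
#'   complex `roots`.
#' @export
bulk_decay_rates <- function(cell, tol = 1e-8) {
  q <- cell_det_poly(cell, 0)
  while (length(q) > 1 && abs(q[length(q)]) == 0) q <- q[-length(q)]
  roots <- polyroot(q)
  m <- Mod(roots)
  inside <- m < 1 - tol & m > tol
  outside <- m > 1 + tol
  if (!any(inside) && !any(outside)) {
    warning("all determinant roots lie on the unit circle: marginal (diffusive) bulk",
            call. = FALSE)
  }
  list(decay = sort(-log(m[inside])),
       growth = sort(log(m[outside])),
       roots = roots)
}

#' Protected window of the tilt field for a two-bulk geometry
#'
#' Locates the interval `(lam_minus, lam_plus)` around zero on which the
#' winding numbers of the two bulks disagree, `dw = w_L - w_R != 0`. Inside
#' this window the tilted generator of the composite network is guaranteed a
#' zero mode localized at the interface. Endpoints are found by bisection on
#' the integer-valued windings; the endpoints are also the tilt values at
#' which a determinant root crosses the unit circle, which ties them to the
#' bulk localization rates: `eta = 1/kappa` from [bulk_decay_rates()] is
#' reported for each bulk.
#'
#' @param left,right [bulk_cell()] objects for the two bulks.
#' @param search_range Largest |lam| probed for a winding transition.
#' @param tol Bisection tolerance on the endpoints.
#' @param n_k Grid size for the winding evaluations.
#' @return A `topo_window`: list with `lam_minus`, `lam_plus`, `dw`,
#'   `eta_left`, `eta_right`, `empty`.
#' @export
lambda_window <- function(left, right, search_range = 5.0, tol = 1e-6, n_k = 512L) {
  dw_at <- function(lam) {
    tryCatch(
      winding_number(left, lam, n_k)$w - winding_number(right, lam, n_k)$w,
      error = function(e) NA_integer_)
  }
  eps0 <- 0.05
  dw_plus <- dw_at(eps0)
  dw_minus <- dw_at(-eps0)
  # the left bulk's profile decays leftward away from the interface (roots
  # inside the unit circle), the right bulk's rightward (roots outside)
  eta_of <- function(cell, side) {
    d <- suppressWarnings(bulk_decay_rates(cell))
    kap <- if (side == "left") d$decay else d$growth
    if (length(kap)) 1 / min(kap) else NA_real_
  }
  if ((is.na(dw_plus) || dw_plus == 0L) && (is.na(dw_minus) || dw_minus == 0L)) {
    return(structure(list(lam_minus = NA_real_, lam_plus = NA_real_, dw = 0L,
                          eta_left = eta_of(left, "left"), eta_right = eta_of(right, "right"),
                          empty = TRUE),
                     class = "topo_window"))
  }
  find_edge <- function(sign) {
    inner_dw <- if (sign > 0) dw_plus else dw_minus
    if (is.na(inner_dw) || inner_dw == 0L) return(sign * tol) # window collapses on this side
    lo <- eps0
    hi <- lo
    repeat {
      hi <- hi * 1.6
      if (hi > search_range) {
        stop("no winding transition found within search_range = ", search_range,
             " on the lam ", if (sign > 0) "+" else "-",
             " side; increase search_range")
      }
      v <- dw_at(sign * hi)
      if (is.na(v) || v != inner_dw) break
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      v <- dw_at(sign * mid)
      if (!is.na(v) && v == inner_dw) lo <- mid else hi <- mid
    }
    sign * (lo + hi) / 2
  }
  lam_plus <- find_edge(+1)
  lam_minus <- find_edge(-1)
  dw_p <- dw_at(min(eps0, lam_plus / 2))
  dw_m <- dw_at(-min(eps0, abs(lam_minus) / 2))
  if (!identical(dw_p, dw_m)) {
    warning(sprintf("winding mismatch differs across lam = 0 (%d vs %d); reporting the lam > 0 value",
                    dw_p, dw_m), call. = FALSE)
  }
  structure(list(lam_minus = lam_minus, lam_plus = lam_plus, dw = dw_p,
                 eta_left = eta_of(left, "left"), eta_right = eta_of(right, "right"),
                 empty = FALSE),
            class = "topo_window")
}

#' @export
print.topo_window <- function(x, ...) {
  if (x$empty) {
    cat("<topo_window> empty (dw = 0 on both sides of lam = 0)\n")
  } else {
    cat(sprintf("<topo_window> lam in (%.6f, %.6f), dw = %d, eta_L = %.4g, eta_R = %.4g\n",
                x$lam_minus, x$lam_plus, x$dw, x$eta_left, x$eta_right))
  }
  invisible(x)
}
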