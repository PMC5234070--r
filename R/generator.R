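#' Build the master-equation generator of a network
#'
#' Assembles the rate matrix `W` of the master equation `dp/dt = W p` in the
#' column convention: entry `(i, j)` holds the rate of the jump `j -> i` for
#' `i != j`, and each diagonal entry `(j, j)` is minus the total outflow from
#' `j`, so every column sums to zero and total probability is conserved.
#'
#' @param net A validated [stoch_network()].
#' @return A dense base matrix with `dimnames` set to the node ids.
#' @export
#' @examples
#' net <- stoch_network(
#'   nodes = data.frame(id = c("a", "b"), x = 0:1, row = 0L, tag = "bulk_L"),
#'   edges = data.frame(src = c("a", "b"), dst = c("b", "a"),
#'                      rate = c(3, 1), disp = c(1L, -1L))
#' )
#' build_generator(net) # [[-3, 1], [3, -1]]
build_generator <- function(net) {
  validate_stoch_network(net)
  ids <- net$nodes$id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  W[cbind(idx[net$edges$dst], idx[net$edges$src])] <- net$edges$rate
  diag(W) <- -colSums(W)
  W
}

#' Tilt a generator by the current-counting field
#'
#' Produces the tilted current matrix `W(lam)`: each off-diagonal entry is
#' multiplied by `exp(lam * disp)` where `disp` is the horizontal displacement
#' of the corresponding jump; the diagonal is left untilted. At `lam = 0` the
#' untilted generator is returned unchanged. The largest eigenvalue of
#' `W(lam)` is the scaled cumulant generating function of the integrated
#' current along the axis.
#'
#' @param gen Generator matrix from [build_generator()] (same node order as
#'   `net`).
#' @param net The network `gen` was built from (source of the displacements).
#' @param lam Real tilt field.
#' @return A dense matrix with attribute `lam`.
#' @export
tilt_generator <- function(gen, net, lam) {
  stopifnot(is.matrix(gen), nrow(gen) == nrow(net$nodes))
  if (lam == 0) return(gen)
  idx <- stats::setNames(seq_len(nrow(gen)), net$nodes$id)
  W <- gen
  d0 <- diag(gen)
  sel <- cbind(idx[net$edges$dst], idx[net$edges$src])
  W[sel] <- gen[sel] * exp(lam * net$edges$disp)
  diag(W) <- d0
  attr(W, "lam") <- lam
  W
}

#' Steady state of an irreducible generator
#'
#' Solves `W p = 0` for the unique stationary probability vector by
#' Grassmann-Taksar-Heyman (GTH) state elimination. GTH uses only additions,
#' multiplications and divisions of non-negative rates, so every entry of
#' the result carries small relative error even when the chain is severely
#' metastable (wells coupled by exponentially small fluxes) and a generic
#' null-space solve would see a degenerate kernel. Errors if elimination
#' hits a state with no outflow to the remaining states (reducible
#' network).
#'
#' @param x A generator matrix (column convention, `dp/dt = W p`) or a
#'   `stoch_network`.
#' @param ... Unused.
#' @return Named non-negative vector summing to 1.
#' @export
steady_state <- function(x, ...) UseMethod("steady_state")

#' @rdname steady_state
#' @export
steady_state.stoch_network <- function(x, ...) steady_state(build_generator(x), ...)

#' @rdname steady_state
#' @export
steady_state.matrix <- function(x, ...) {
  n <- nrow(x)
  a <- t(x) # a[i, j] = rate i -> j; elimination works on the row convention
  diag(a) <- 0
  if (any(a < 0)) stop("off-diagonal entries must be non-negative rates")
  if (n == 1L) return(stats::setNames(1, rownames(x)))
  s_out <- numeric(n)
  for (k in n:2) {
    kk <- seq_len(k - 1L)
    s <- sum(a[k, kk])
    if (s <= 0) {
      label <- if (!is.null(rownames(x))) rownames(x)[k] else as.character(k)
      stop("null space has dimension > 1; the network appears reducible ",
           "(no outflow from state ", label, " into the remaining states)")
    }
    s_out[k] <- s
    a[k, kk] <- a[k, kk] / s
    a[kk, kk] <- a[kk, kk] + outer(a[kk, k], a[k, kk])
  }
  p <- numeric(n)
  p[1] <- 1
  for (k in 2:n) {
    kk <- seq_len(k - 1L)
    p[k] <- sum(p[kk] * a[kk, k]) / s_out[k]
  }
  p <- p / sum(p)
  names(p) <- rownames(x)
  p
}

#' Scaled cumulant generating function of the horizontal current
#'
#' Computes the leading spectral data of the tilted generator `W(lam)`. The
#' eigenvalue of largest real part is the scaled cumulant generating function
#' `e(lam)` of the time-integrated current along the horizontal axis;
#' `e(0) = 0` and its leading right eigenvector at `lam = 0` is the steady
#' state. The gap between the two leading real parts sets the slowest
#' relaxation timescale.
#'
#' For an open-boundary network a nonzero `lam` does not correspond to a
#' sustained macroscopic current; the result is still computed but flagged
#' (`open_flag`) and a warning is issued once.
#'
#' @param net A `stoch_network`.
#' @param lam Real tilt field.
#' @return A `spectral_result`: list with `e_lam`, `leading_right` (sums to
#'   1), `leading_left` (normalized so `sum(left * right) = 1`), `gap`,
#'   `lam`, `open_flag`.
#' @export
scgf <- function(net, lam = 0) {
  gen <- build_generator(net)
  W <- tilt_generator(gen, net, lam)
  open_flag <- net$boundary == "open" && lam != 0
  if (open_flag) {
    warning("tilting an open-boundary network: e(lam) is not a bulk current SCGF",
            call. = FALSE)
  }
  eig <- tryCatch(eigen(W), error = function(e) {
    stop("eigensolver failed on W(lam): ", conditionMessage(e))
  })
  ord <- order(Re(eig$values), decreasing = TRUE)
  vals <- eig$values[ord]
  e_lam <- Re(vals[1])
  v <- eig$vectors[, ord[1]]
  # Perron vector of an irreducible Metzler matrix is real up to a phase
  v <- Re(v / v[which.max(abs(v))])
  v <- v / sum(v)
  eig_l <- eigen(t(W))
  jl <- which.min(abs(eig_l$values - vals[1]))
  u <- eig_l$vectors[, jl]
  u <- Re(u / u[which.max(abs(u))])
  u <- u / sum(u * v)
  names(v) <- names(u) <- net$nodes$id
  structure(
    list(e_lam = e_lam, leading_right = v, leading_left = u,
         gap = if (length(vals) > 1) e_lam - Re(vals[2]) else NA_real_,
         lam = lam, open_flag = open_flag, n_states = nrow(W)),
    class = "spectral_result"
  )
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf("<spectral_result> lam = %g: e(lam) = %.6g, gap = %.6g (%d states)\n",
              x$lam, x$e_lam, x$gap, x$n_states))
  invisible(x)
}

#' Mean steady-state current along the horizontal axis
#'
#' The net macroscopic current `J = sum over edges of rate * p(src) * disp`,
#' the first derivative of the cumulant generating function `e(lam)` at
#' `lam = 0`.
#'
#' @param net A `stoch_network`.
#' @param p Steady-state probability vector (computed if missing).
#' @return A single number.
#' @export
mean_current <- function(net, p = NULL) {
  if (is.null(p)) p <- steady_state(net)
  p <- p[net$nodes$id]
  sum(net$edges$rate * p[net$edges$src] * net$edges$disp)
}

#' Spectral gap of the untilted generator
#'
#' Distance between the real parts of the two slowest eigenvalues of `W`
#' (0 and the next one). A gap bounded away from zero as the system grows is
#' the relaxation-time signature of the topologically protected regime.
#'
#' @param net A `stoch_network`.
#' @return Non-negative number.
#' @export
spectral_gap <- function(net) {
  W <- build_generator(net)
  vals <- tryCatch(eigen(W, only.values = TRUE)$values, error = function(e) {
    stop("eigensolver failed: ", conditionMessage(e))
  })
  re <- sort(Re(vals), decreasing = TRUE)
  re[1] - re[2]
}
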