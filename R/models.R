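sigmoid <- function(x) 1 / (1 + exp(-x))

mix_cells <- function(left, right, alpha) {
  bulk_cell(intra = (1 - alpha) * left$intra + alpha * right$intra,
            hop_plus = (1 - alpha) * left$hop_plus + alpha * right$hop_plus,
            hop_minus = (1 - alpha) * left$hop_minus + alpha * right$hop_minus)
}

interface_weights <- function(width, rule) {
  t <- (seq_len(width) - 0.5) / width
  if (is.numeric(rule)) {
    if (length(rule) != width) stop("explicit interface weights must have length ", width)
    return(rule)
  }
  switch(rule,
         linear = t,
         sigmoid = sigmoid(8 * (t - 0.5)),
         stop("unknown interface rule: ", rule))
}

#' Build a two-bulk ladder network
#'
#' Assembles the canonical two-bulk geometry: `columns_per_bulk` copies of
#' the left cell, an interface whose rates interpolate toward the right
#' cell, `columns_per_bulk` copies of the right cell, and (for periodic
#' boundary) a second interface interpolating back so the ring closes.
#' Interior bulk columns carry exactly their cell's rates, so translational
#' invariance holds away from the interfaces. Hops across the periodic seam
#' carry displacement +/-1.
#'
#' @param left_cell,right_cell [bulk_cell()] objects with equal row counts.
#' @param columns_per_bulk Number of columns per bulk (>= 4).
#' @param interface_width Number of interpolating columns per interface
#'   (>= 1).
#' @param interface_rates `"sigmoid"` (default), `"linear"`, or a numeric
#'   vector of explicit mixing weights of length `interface_width`.
#' @param boundary `"open"` or `"periodic"`.
#' @return A `stoch_network`; `metadata$interface_centers` records the
#'   interface positions (one for open, two for periodic).
#' @export
#' @examples
#' net <- build_two_bulk_ladder(bulk_cell_1d(2, 1), bulk_cell_1d(1, 2), 10)
#' p <- steady_state(net)
#' column_marginals(net, p) # peaked at the central interface
build_two_bulk_ladder <- function(left_cell, right_cell, columns_per_bulk,
                                  interface_width = 1L,
                                  interface_rates = "sigmoid",
                                  boundary = c("open", "periodic")) {
  boundary <- match.arg(boundary)
  N <- as.integer(columns_per_bulk)
  I <- as.integer(interface_width)
  if (N < 4) stop("columns_per_bulk must be at least 4")
  if (I < 1) stop("interface_width must be at least 1")
  if (left_cell$n_internal != right_cell$n_internal) {
    stop("incompatible cells: ", left_cell$n_internal, " vs ",
         right_cell$n_internal, " rows")
  }
  B <- left_cell$n_internal
  wts <- interface_weights(I, interface_rates)
  alpha <- c(rep(0, N), wts, rep(1, N))
  tag <- c(rep("bulk_L", N), rep("interface", I), rep("bulk_R", N))
  if (boundary == "periodic") {
    alpha <- c(alpha, rev(wts))
    tag <- c(tag, rep("interface", I))
  }
  C <- length(alpha)
  node_id <- function(x, r) sprintf("x%03d_r%d", x, r)
  nodes <- tibble::tibble(
    id = node_id(rep(seq_len(C) - 1L, each = B), rep(seq_len(B) - 1L, C)),
    x = rep(seq_len(C) - 1L, each = B),
    row = rep(seq_len(B) - 1L, C),
    tag = rep(tag, each = B))
  src <- dst <- character(0); rate <- numeric(0); disp <- integer(0)
  add <- function(s, d, r, dp) {
    keep <- r > 0
    src <<- c(src, s[keep]); dst <<- c(dst, d[keep])
    rate <<- c(rate, r[keep]); disp <<- c(disp, rep(dp, sum(keep)))
  }
  for (cidx in seq_len(C) - 1L) {
    cell <- mix_cells(left_cell, right_cell, alpha[cidx + 1L])
    for (j in seq_len(B)) for (i in seq_len(B)) {
      if (i != j && cell$intra[i, j] > 0) {
        add(node_id(cidx, j - 1L), node_id(cidx, i - 1L), cell$intra[i, j], 0L)
      }
    }
    cp <- cidx + 1L; cm <- cidx - 1L
    if (cp > C - 1L) cp <- if (boundary == "periodic") 0L else NA_integer_
    if (cm < 0L) cm <- if (boundary == "periodic") C - 1L else NA_integer_
    for (j in seq_len(B)) for (i in seq_len(B)) {
      if (!is.na(cp) && cell$hop_plus[i, j] > 0) {
        add(node_id(cidx, j - 1L), node_id(cp, i - 1L), cell$hop_plus[i, j], 1L)
      }
      if (!is.na(cm) && cell$hop_minus[i, j] > 0) {
        add(node_id(cidx, j - 1L), node_id(cm, i - 1L), cell$hop_minus[i, j], -1L)
      }
    }
  }
  centers <- N + (I - 1) / 2
  if (boundary == "periodic") centers <- c(centers, 2 * N + I + (I - 1) / 2)
  stoch_network(
    nodes, tibble::tibble(src = src, dst = dst, rate = rate, disp = disp),
    boundary = boundary,
    metadata = list(builder = "two_bulk_ladder", columns_per_bulk = N,
                    interface_width = I, interface_centers = centers))
}

# --- chemosensory adaptation --------------------------------------------

#' Specify the chemosensory adaptation lattice
#'
#' Parameters of the two-row methylation lattice modelling adaptation of a
#' chemoreceptor complex: activity `a` in {0, 1} (rows) and methylation
#' level `m` in 0..M-1 (columns). Activity flips are governed by a free
#' energy `f(a, m) = a E (S - m)`: the flip rates are sigmoid in `m` with
#' crossover at `m = S`, where `S` is the logarithm of the chemoattractant
#' concentration and `E` the energy scale. Methylation kinetics implement
#' the non-equilibrium feedback: when inactive the receptor methylates
#' (`m -> m+1` at `omega_m`), when active it demethylates (`m -> m-1` at
#' `omega_m`), and the reverse moves are suppressed by `exp(-G)` with `G`
#' the driving force. Methylation boundaries are reflecting.
#'
#' @param M Number of methylation levels (>= 4).
#' @param E Energy scale of the activity-methylation coupling.
#' @param S Crossover methylation level (log chemoattractant concentration);
#'   must satisfy `0 < S < M` for an interior interface.
#' @param G Non-equilibrium driving force on the methylation cycle.
#' @param omega_a,omega_m Timescale rates of activity flips / methylation.
#' @param a0_bias Optional log-asymmetry of the flip rates, shifting the
#'   activity set point away from 1/2.
#' @return An `adaptation_spec` list.
#' @export
adaptation_spec <- function(M = 48L, E = 6, S = M / 2, G = 2,
                            omega_a = 1, omega_m = 1, a0_bias = 0) {
  M <- as.integer(M)
  if (M < 4) stop("M must be at least 4")
  if (omega_a <= 0 || omega_m <= 0) stop("omega_a and omega_m must be positive")
  if (!(S > 0 && S < M)) stop("need 0 < S < M for an interior interface")
  if (a0_bias < 0) stop("a0_bias must be >= 0")
  structure(list(M = M, E = E, S = S, G = G, omega_a = omega_a,
                 omega_m = omega_m, a0_bias = a0_bias),
            class = "adaptation_spec")
}

# flip-rate floor keeps far-from-crossover columns irreducible and matches
# the saturated bulk cells of bulk_limits()
adapt_flip_rates <- function(spec, m, floor_distance = 10) {
  floor_val <- exp(-abs(spec$E) * floor_distance)
  up <- pmax(sigmoid(spec$E * (m - spec$S)), floor_val) # a = 0 -> 1
  down <- pmax(sigmoid(spec$E * (spec$S - m)), floor_val) # a = 1 -> 0
  list(up = spec$omega_a * up * exp(spec$a0_bias / 2),
       down = spec$omega_a * down * exp(-spec$a0_bias / 2))
}

#' Build the adaptation network
#'
#' Realizes an [adaptation_spec()] as a `stoch_network`: a 2 x M lattice with
#' activity flips (displacement 0) and methylation hops (displacement +/-1).
#' Columns where the flip sigmoids are saturated are tagged as bulk; the
#' crossover region around `m = S` is the interface.
#'
#' @param spec An [adaptation_spec()].
#' @param floor_distance Flip rates are floored at
#'   `omega_a * exp(-|E| * floor_distance)` so that remote columns stay
#'   connected to both rows.
#' @return A `stoch_network` with `metadata$interface_centers = S`.
#' @export
build_adaptation_network <- function(spec, floor_distance = 10) {
  stopifnot(inherits(spec, "adaptation_spec"))
  M <- spec$M
  m <- seq_len(M) - 1L
  fl <- adapt_flip_rates(spec, m, floor_distance)
  sat <- abs(spec$E * (m - spec$S)) >= -log(1e-6)
  tag <- ifelse(!sat, "interface", ifelse(m < spec$S, "bulk_L", "bulk_R"))
  node_id <- function(mm, a) sprintf("m%03d_a%d", mm, a)
  nodes <- tibble::tibble(id = c(node_id(m, 0L), node_id(m, 1L)),
                          x = c(m, m), row = rep(c(0L, 1L), each = M),
                          tag = c(tag, tag))
  eg <- exp(-spec$G)
  wm <- spec$omega_m
  edges <- dplyr::bind_rows(
    tibble::tibble(src = node_id(m, 0L), dst = node_id(m, 1L), rate = fl$up, disp = 0L),
    tibble::tibble(src = node_id(m, 1L), dst = node_id(m, 0L), rate = fl$down, disp = 0L),
    tibble::tibble(src = node_id(m[-M], 0L), dst = node_id(m[-M] + 1L, 0L), rate = wm, disp = 1L),
    tibble::tibble(src = node_id(m[-1], 0L), dst = node_id(m[-1] - 1L, 0L), rate = wm * eg, disp = -1L),
    tibble::tibble(src = node_id(m[-1], 1L), dst = node_id(m[-1] - 1L, 1L), rate = wm, disp = -1L),
    tibble::tibble(src = node_id(m[-M], 1L), dst = node_id(m[-M] + 1L, 1L), rate = wm * eg, disp = 1L))
  stoch_network(nodes, edges, boundary = "open",
                metadata = c(unclass(spec),
                             list(builder = "adaptation",
                                  interface_centers = spec$S,
                                  floor_distance = floor_distance)))
}

#' Saturated bulk unit cells of the adaptation lattice
#'
#' The translational-invariance limits of the adaptation network far below
#' (`left`) and far above (`right`) the crossover `m = S`: sigmoid flip
#' rates are replaced by their saturated limits, with the strictly-zero side
#' floored at `omega_a * exp(-|E| * floor_distance)` to preserve
#' irreducibility. Errors if `E` is too small for the sigmoids to saturate
#' within 1e-6 over the lattice.
#'
#' @inheritParams build_adaptation_network
#' @return List with [bulk_cell()] members `left` and `right` (rows ordered
#'   a = 0, a = 1).
#' @export
bulk_limits <- function(spec, floor_distance = 10) {
  stopifnot(inherits(spec, "adaptation_spec"))
  sat <- abs(spec$E) * min(spec$S, spec$M - 1 - spec$S)
  if (sat < -log(1e-6)) {
    stop(sprintf(
      "sigmoids do not saturate within 1e-6 (|E|*distance = %.2f < %.2f); increase E or M",
      sat, -log(1e-6)))
  }
  floor_val <- spec$omega_a * exp(-abs(spec$E) * floor_distance)
  bp <- exp(spec$a0_bias / 2); bm <- exp(-spec$a0_bias / 2)
  hop_p <- diag(c(spec$omega_m, spec$omega_m * exp(-spec$G)))
  hop_m <- diag(c(spec$omega_m * exp(-spec$G), spec$omega_m))
  intra_left <- matrix(c(0, floor_val * bp, spec$omega_a * bm, 0), 2, 2)
  intra_right <- matrix(c(0, spec$omega_a * bp, floor_val * bm, 0), 2, 2)
  list(left = bulk_cell(intra_left, hop_p, hop_m),
       right = bulk_cell(intra_right, hop_p, hop_m))
}

#' Sweep the adaptation network over chemoattractant levels
#'
#' For each `S`, builds the lattice, solves the steady state exactly, and
#' reports the mean activity, mean methylation level, and exponential fits
#' of the methylation profile on the two flanks of its peak. In the
#' topologically protected regime (`dw = 1`) the mean activity is pinned at
#' its set point and the mean methylation tracks `S`; with reversed driving
#' (`dw = -1`) the profile is edge-localized and activity follows `S`.
#'
#' @param spec Template [adaptation_spec()]; its `S` is replaced per sweep
#'   point.
#' @param S_values Numeric vector of crossover levels.
#' @param fit_width,fit_gap Columns used for the flank fits: from `gap` to
#'   `width` columns away from the profile peak on each side.
#' @return An `adaptation_sweep` tibble with columns `S`, `mean_activity`,
#'   `mean_methylation`, `kappa_left`, `kappa_right`, `r2`.
#' @export
adaptation_sweep <- function(spec, S_values, fit_width = 12L, fit_gap = 2L) {
  stopifnot(inherits(spec, "adaptation_spec"))
  rows <- purrr::map(S_values, function(S) {
    sp <- spec; sp$S <- S
    net <- build_adaptation_network(sp)
    p <- steady_state(net)
    act <- sum(p[net$nodes$id[net$nodes$row == 1L]])
    mm <- sum(net$nodes$x * p[net$nodes$id])
    prof <- column_marginals(net, p)
    m0 <- prof$x[which.max(prof$mass)]
    flank <- function(cols) {
      cols <- cols[cols >= 0 & cols <= sp$M - 1]
      if (length(cols) < 4) return(list(kappa = NA_real_, r2 = NA_real_))
      fit_decay(prof, cols)
    }
    fl <- flank(seq(m0 - fit_width, m0 - fit_gap))
    fr <- flank(seq(m0 + fit_gap, m0 + fit_width))
    tibble::tibble(S = S, mean_activity = act, mean_methylation = mm,
                   kappa_left = fl$kappa, kappa_right = fr$kappa,
                   r2 = mean(c(fl$r2, fr$r2), na.rm = TRUE))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("adaptation_sweep", class(out))
  out
}

#' Plaquette cycle affinities of a two-row lattice
#'
#' Log ratio of the clockwise to counter-clockwise rate products around each
#' elementary square of a two-row network (columns m, m+1 by rows 0, 1).
#' Zero everywhere means detailed balance (Kolmogorov criterion). For the
#' adaptation lattice the affinity is uniform and equals `2G + E` exactly:
#' the sigmoid identity `sigma(x)/sigma(-x) = e^x` makes the flip-rate
#' contribution `E` per plaquette, so the lattice is equilibrium only at
#' `G = -E/2`.
#'
#' @param net A two-row `stoch_network` (rows 0 and 1 in every column).
#' @return Tibble with columns `m` (left column of the plaquette) and
#'   `affinity`.
#' @export
plaquette_affinities <- function(net) {
  erate <- function(s, d) {
    r <- net$edges$rate[net$edges$src == s & net$edges$dst == d]
    if (length(r) != 1) NA_real_ else r
  }
  idof <- function(x, r) net$nodes$id[net$nodes$x == x & net$nodes$row == r]
  cols <- sort(unique(net$nodes$x))
  rows <- purrr::map(cols[-length(cols)], function(m) {
    a0m <- idof(m, 0); a0p <- idof(m + 1, 0)
    a1m <- idof(m, 1); a1p <- idof(m + 1, 1)
    fwd <- c(erate(a0m, a0p), erate(a0p, a1p), erate(a1p, a1m), erate(a1m, a0m))
    rev <- c(erate(a0m, a1m), erate(a1m, a1p), erate(a1p, a0p), erate(a0p, a0m))
    tibble::tibble(m = m, affinity = sum(log(fwd)) - sum(log(rev)))
  })
  dplyr::bind_rows(rows)
}

# --- kinetic proofreading ------------------------------------------------

#' Build a kinetic proofreading chain
#'
#' A minimal single-row chain of `n_stages + 1` states from the reactant end
#' (column 0) to the product end (column `n_stages`), with uniform forward
#' and backward rates. The bulk of the chain for the correct substrate
#' should carry topological charge +1 (product-localized) and the wrong
#' substrate -1 (reactant-localized); the occupancy ratio between the ends
#' is `(forward/backward)^n_stages`.
#'
#' @param n_stages Number of proofreading stages (>= 2).
#' @param forward,backward Uniform hop rates.
#' @param substrate Label `"R"` (right/correct) or `"W"` (wrong).
#' @return A `stoch_network` tagged with vacuum boundaries at both ends.
#' @export
build_proofreading_chain <- function(n_stages, forward, backward,
                                     substrate = c("R", "W")) {
  substrate <- match.arg(substrate)
  n <- as.integer(n_stages)
  if (n < 2) stop("n_stages must be at least 2")
  if (forward <= 0 || backward <= 0) stop("rates must be positive")
  x <- 0:n
  id <- sprintf("s%02d", x)
  tag <- c("vacuum_boundary", rep(if (forward >= backward) "bulk_R" else "bulk_L", n - 1),
           "vacuum_boundary")
  nodes <- tibble::tibble(id = id, x = x, row = 0L, tag = tag)
  edges <- dplyr::bind_rows(
    tibble::tibble(src = id[-(n + 1)], dst = id[-1], rate = forward, disp = 1L),
    tibble::tibble(src = id[-1], dst = id[-(n + 1)], rate = backward, disp = -1L))
  stoch_network(nodes, edges, boundary = "open",
                metadata = list(builder = "proofreading", substrate = substrate,
                                n_stages = n, forward = forward,
                                backward = backward))
}

# --- quenched disorder ---------------------------------------------------

#' Apply quenched multiplicative disorder to the rates
#'
#' Multiplies every edge rate by `exp(u)` with `u` drawn uniformly from
#' `[-strength, strength]`, in the network's fixed edge order from a seeded
#' stream, so the same seed always reproduces the same disordered network.
#' `strength = 0` returns the input unchanged.
#'
#' @param net A `stoch_network`.
#' @param strength Disorder strength `delta >= 0` (< 5).
#' @param seed Integer seed for the disorder draw.
#' @return A disordered `stoch_network` (metadata records `disorder`).
#' @export
apply_disorder <- function(net, strength, seed = 1L) {
  if (strength < 0 || strength >= 5) stop("disorder strength must be in [0, 5)")
  if (strength == 0) return(net)
  u <- withr::with_seed(seed, stats::runif(nrow(net$edges), -strength, strength))
  net$edges$rate <- net$edges$rate * exp(u)
  net$metadata$disorder <- list(strength = strength, law = "log_uniform", seed = seed)
  net
}
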