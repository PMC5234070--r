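#' Kinetic Monte Carlo (Gillespie) simulation
#'
#' Direct stochastic simulation of the continuous-time Markov chain defined
#' by the network: exponential waiting times with the total exit rate of the
#' current state, next state chosen proportionally to the outgoing rates.
#' A single seeded RNG stream makes runs reproducible.
#'
#' @param net A `stoch_network`.
#' @param t_max Total simulated time.
#' @param start Starting node id; by default the node with the largest
#'   steady-state probability.
#' @param seed Integer seed.
#' @return A `kmc_trajectory`: list with `times` (jump times), `states`
#'   (node indices visited, including the start), `disps` (per-jump
#'   displacement), `t_max`, `seed`, and the node table.
#' @export
gillespie_run <- function(net, t_max, start = NULL, seed = 1L) {
  stopifnot(t_max > 0)
  ids <- net$nodes$id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  if (is.null(start)) {
    start <- ids[which.max(steady_state(net))]
  } else if (!start %in% ids) stop("start node not in network: ", start)
  out_to <- split(idx[net$edges$dst], idx[net$edges$src])
  out_rate <- split(net$edges$rate, idx[net$edges$src])
  out_disp <- split(net$edges$disp, idx[net$edges$src])
  if (length(out_to) != n) stop("absorbing state present: zero exit rate")
  key <- as.character(seq_len(n))
  targets <- out_to[key]
  cumrates <- lapply(out_rate[key], cumsum)
  disps <- out_disp[key]
  totals <- vapply(cumrates, function(x) x[length(x)], numeric(1))
  cap <- 4096L
  times <- numeric(cap); states <- integer(cap); jdisp <- integer(cap)
  withr::with_seed(seed, {
    s <- unname(idx[start])
    t <- 0
    nj <- 0L
    repeat {
      dt <- stats::rexp(1, totals[s])
      if (t + dt > t_max) break
      t <- t + dt
      u <- stats::runif(1) * totals[s]
      j <- findInterval(u, cumrates[[s]]) + 1L
      if (j > length(targets[[s]])) j <- length(targets[[s]])
      nj <- nj + 1L
      if (nj > cap) {
        cap <- cap * 2L
        length(times) <- cap; length(states) <- cap; length(jdisp) <- cap
      }
      times[nj] <- t
      jdisp[nj] <- disps[[s]][j]
      s <- targets[[s]][j]
      states[nj] <- s
    }
  })
  structure(list(times = times[seq_len(nj)],
                 states = c(unname(idx[start]), states[seq_len(nj)]),
                 disps = jdisp[seq_len(nj)],
                 t_max = t_max, seed = seed, start = start,
                 nodes = net$nodes),
            class = "kmc_trajectory")
}

#' @export
print.kmc_trajectory <- function(x, ...) {
  cat(sprintf("<kmc_trajectory> %d jumps over t = %g (seed %d, start %s)\n",
              length(x$times), x$t_max, x$seed, x$start))
  invisible(x)
}

#' Empirical occupancy and current from a trajectory
#'
#' Time-weighted occupancy of every node and the empirical current (total
#' displacement over elapsed time), after discarding an initial burn-in.
#' Standard errors come from means over equal-time batches.
#'
#' @param traj A [gillespie_run()] trajectory.
#' @param burn_in Fraction of `t_max` discarded before estimation.
#' @param n_batches Number of equal time batches for the error bars.
#' @return An `occupancy_estimate` tibble with columns `id`, `x`, `row`,
#'   `occupancy`, `stderr`; attributes `current`, `current_se`, `t_total`.
#' @export
occupancy <- function(traj, burn_in = 0.1, n_batches = 10L) {
  t0 <- burn_in * traj$t_max
  t1 <- traj$t_max
  n <- nrow(traj$nodes)
  seg_start <- c(0, traj$times)
  seg_end <- c(traj$times, traj$t_max)
  seg_state <- traj$states
  edges_b <- seq(t0, t1, length.out = n_batches + 1L)
  occ_b <- matrix(0, n, n_batches)
  cur_b <- numeric(n_batches)
  jump_t <- traj$times
  for (b in seq_len(n_batches)) {
    lo <- edges_b[b]; hi <- edges_b[b + 1L]
    dwell <- pmax(0, pmin(seg_end, hi) - pmax(seg_start, lo))
    keep <- dwell > 0
    agg <- rowsum(dwell[keep], seg_state[keep])
    occ_b[as.integer(rownames(agg)), b] <- agg[, 1] / (hi - lo)
    inb <- jump_t > lo & jump_t <= hi
    cur_b[b] <- sum(traj$disps[inb]) / (hi - lo)
  }
  occ <- rowMeans(occ_b)
  occ_se <- apply(occ_b, 1, stats::sd) / sqrt(n_batches)
  out <- tibble::tibble(id = traj$nodes$id, x = traj$nodes$x,
                        row = traj$nodes$row,
                        occupancy = occ, stderr = occ_se)
  class(out) <- c("occupancy_estimate", class(out))
  attr(out, "current") <- mean(cur_b)
  attr(out, "current_se") <- stats::sd(cur_b) / sqrt(n_batches)
  attr(out, "t_total") <- t1 - t0
  out
}
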