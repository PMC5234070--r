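test_that("ladder bulks are translationally invariant; interfaces interpolate", {
  net <- t1_ring(10)
  # identical outgoing rate pattern for any two interior left-bulk columns
  out_pattern <- function(net, col) {
    ids <- net$nodes$id[net$nodes$x == col]
    e <- net$edges[net$edges$src %in% ids, ]
    sort(paste(e$disp, signif(e$rate, 12)))
  }
  expect_identical(out_pattern(net, 3), out_pattern(net, 6))
  expect_identical(out_pattern(net, 13), out_pattern(net, 17))
  expect_false(identical(out_pattern(net, 3), out_pattern(net, 13)))
  expect_error(build_two_bulk_ladder(t1_left(), withr::with_seed(1, random_cell(2)), 10),
               "incompatible")
})

test_that("open two-bulk chain peaks at the interface; identical bulks stay flat", {
  chain <- t1_chain(10)
  prof <- column_marginals(chain, steady_state(chain))
  expect_equal(prof$x[which.max(prof$mass)],
               chain$metadata$interface_centers[1])
  flat <- build_two_bulk_ladder(t1_left(), t1_left(), 10, 1, "linear", "periodic")
  pf <- column_marginals(flat, steady_state(flat))
  expect_lt(diff(range(pf$mass)), 1e-12)
})

test_that("periodic ladder has two seams with opposite winding mismatch", {
  ring <- t1_ring(10)
  expect_length(ring$metadata$interface_centers, 2L)
  # seam A: left bulk on the left, right bulk on the right; seam B reversed
  wl <- winding_number(t1_left(), 0.05)$w
  wr <- winding_number(t1_right(), 0.05)$w
  expect_identical(wl - wr, 1L)
  expect_identical(wr - wl, -1L)
})

test_that("adaptation lattice: structure, plaquette affinities, equilibrium point", {
  spec <- adaptation_spec(M = 16L, E = 6, G = 2)
  net <- build_adaptation_network(spec, floor_distance = Inf)
  expect_identical(nrow(net$nodes), 32L)
  # uniform cycle affinity 2G + E on every plaquette (sigma(x)/sigma(-x) = e^x)
  aff <- plaquette_affinities(net)
  expect_equal(aff$affinity, rep(2 * 2 + 6, 15), tolerance = 1e-9)
  # detailed balance at G = -E/2, not at G = 0
  db <- build_adaptation_network(adaptation_spec(M = 16L, E = 6, G = -3),
                                 floor_distance = Inf)
  expect_equal(plaquette_affinities(db)$affinity, rep(0, 15), tolerance = 1e-9)
  g0 <- build_adaptation_network(adaptation_spec(M = 16L, E = 6, G = 0),
                                 floor_distance = Inf)
  expect_equal(plaquette_affinities(g0)$affinity, rep(6, 15), tolerance = 1e-9)
})

test_that("saturated bulk cells: limits, mirror symmetry, winding mismatches", {
  spec <- adaptation_spec(M = 48L, E = 6, G = 2)
  bl <- bulk_limits(spec)
  floor_val <- exp(-6 * 10)
  expect_equal(bl$left$intra[2, 1], floor_val)
  expect_equal(bl$left$intra[1, 2], 1)
  # left and right cells are mirror images under (m -> -m, a -> 1 - a)
  flip <- function(m) m[2:1, 2:1]
  expect_equal(flip(bl$right$intra), bl$left$intra)
  expect_equal(flip(bl$right$hop_plus), bl$left$hop_minus)

  dw <- function(G) {
    b <- bulk_limits(adaptation_spec(M = 48L, E = 6, G = G))
    winding_number(b$left, 0.05)$w - winding_number(b$right, 0.05)$w
  }
  expect_identical(dw(2), 1L)
  expect_identical(dw(-2), -1L)

  expect_error(bulk_limits(adaptation_spec(M = 8L, E = 0.5, G = 2)),
               "increase E or M")
  # cells feed lambda_window directly
  win <- lambda_window(bl$left, bl$right)
  expect_identical(win$dw, 1L)
  expect_true(win$lam_plus > 0.05 && win$lam_minus < -0.05)
})

test_that("adaptation sweep: protected regime is flat and tracking, reversed is not", {
  sv <- seq(12, 36, by = 4)
  sw <- adaptation_sweep(adaptation_spec(M = 48L, E = 6, G = 2), sv)
  spread <- (max(sw$mean_activity) - min(sw$mean_activity)) / mean(sw$mean_activity)
  expect_lt(spread, 0.02)
  expect_lt(max(sw$mean_methylation - sw$S) - min(sw$mean_methylation - sw$S), 0.5)
  swn <- adaptation_sweep(adaptation_spec(M = 48L, E = 6, G = -2), sv)
  spread_n <- (max(swn$mean_activity) - min(swn$mean_activity)) / mean(swn$mean_activity)
  expect_gt(spread_n, 0.2)
})

test_that("adaptation activity is insensitive to disorder in the protected regime", {
  spec <- adaptation_spec(M = 48L, E = 6, G = 2)
  for (S in c(14, 24, 34)) {
    sp <- spec; sp$S <- S
    net <- build_adaptation_network(sp)
    clean <- sum(steady_state(net)[net$nodes$id[net$nodes$row == 1L]])
    acts <- vapply(1:10, function(seed) {
      dis <- apply_disorder(net, 0.2, seed)
      sum(steady_state(dis)[dis$nodes$id[dis$nodes$row == 1L]])
    }, numeric(1))
    expect_lt(abs(mean(acts) - clean) / clean, 0.05)
  }
})

test_that("proofreading chains discriminate geometrically in the stage count", {
  chainR <- build_proofreading_chain(5, 2, 1, "R")
  pR <- steady_state(chainR)
  expect_equal(unname(pR["s05"] / pR["s00"]), 2^5, tolerance = 1e-10)
  chainW <- build_proofreading_chain(5, 1, 2, "W")
  pW <- steady_state(chainW)
  expect_equal(unname(pW["s05"] / pW["s00"]), 2^-5, tolerance = 1e-10)
  # discrimination ratio (f_R b_W / (b_R f_W))^n
  expect_equal(unname((pR["s05"] / pR["s00"]) / (pW["s05"] / pW["s00"])),
               (2 * 2 / (1 * 1))^5, tolerance = 1e-10)
  expect_identical(topological_charge(bulk_cell_1d(2, 1)), 1L)
  expect_identical(topological_charge(bulk_cell_1d(1, 2)), -1L)
})

test_that("quenched disorder is deterministic, positive, and inert at zero strength", {
  ring <- t1_ring(6)
  expect_identical(apply_disorder(ring, 0), ring)
  d1 <- apply_disorder(ring, 0.3, 42)
  d2 <- apply_disorder(ring, 0.3, 42)
  expect_identical(d1$edges, d2$edges)
  expect_false(identical(d1$edges$rate, ring$edges$rate))
  expect_true(all(d1$edges$rate > 0))
  expect_true(all(abs(log(d1$edges$rate / ring$edges$rate)) <= 0.3))
  expect_error(apply_disorder(ring, 7), "strength")
})
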