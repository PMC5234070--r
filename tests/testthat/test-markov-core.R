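test_that("generator assembly follows the column convention", {
  W <- build_generator(two_state_net(3, 1))
  expect_equal(unname(W), matrix(c(-3, 3, 1, -1), 2, 2))

  W3 <- build_generator(ring3(2, 1))
  expect_equal(unname(diag(W3)), rep(-3, 3))
  expect_equal(max(abs(colSums(W3))), 0)

  net <- t1_ring(6)
  expect_lt(max(abs(colSums(build_generator(net)))),
            1e-12 * max(net$edges$rate))
})

test_that("generator construction rejects invalid networks", {
  nodes <- data.frame(id = c("a", "b", "c", "d"), x = 0:3, row = 0L, tag = "bulk_L")
  split_edges <- data.frame(src = c("a", "b", "c", "d"), dst = c("b", "a", "d", "c"),
                            rate = 1, disp = 0L)
  expect_error(stoch_network(nodes, split_edges), "strongly connected")
  dup <- data.frame(src = c("a", "a", "b"), dst = c("b", "b", "a"), rate = 1, disp = 0L)
  expect_error(stoch_network(nodes[1:2, ], dup), "duplicate edge")
})

test_that("tilting scales off-diagonals by exp(lam * disp) and keeps the diagonal", {
  net <- two_state_net(3, 1)
  gen <- build_generator(net)
  expect_identical(unname(tilt_generator(gen, net, 0)), unname(gen))
  Wt <- tilt_generator(gen, net, 0.1)
  expect_equal(Wt["b", "a"], 3 * exp(0.1))
  expect_equal(Wt["a", "b"], 1 * exp(-0.1))
  expect_equal(diag(Wt), diag(gen))
})

test_that("steady states match symmetry and zero-current predictions", {
  expect_equal(unname(steady_state(two_state_net(1, 1))), c(0.5, 0.5))
  # translational symmetry of a ring, any bias
  expect_equal(unname(steady_state(ring3(5, 0.3))), rep(1 / 3, 3))
  # open two-bulk chain: ratio p/q = 2 per step toward the interface
  chain <- t1_chain(10)
  prof <- column_marginals(chain, steady_state(chain))
  left_ratios <- prof$mass[2:10] / prof$mass[1:9]
  expect_equal(left_ratios, rep(2, 9), tolerance = 1e-10)
  right_ratios <- prof$mass[13:21] / prof$mass[12:20]
  expect_equal(right_ratios, rep(0.5, 9), tolerance = 1e-10)
})

test_that("steady_state is equivariant under node reordering", {
  net <- t1_chain(5)
  p <- steady_state(net)
  perm <- withr::with_seed(1, sample(nrow(net$nodes)))
  net2 <- stoch_network(net$nodes[perm, ], net$edges, net$boundary)
  p2 <- steady_state(net2)
  expect_equal(p2[names(p)], p, tolerance = 1e-12)
})

test_that("scgf matches the biased-ring closed form and ties to the steady state", {
  ring <- biased_ring(2, 1, 10)
  closed <- function(lam) 2 * (exp(lam) - 1) + (exp(-lam) - 1)
  for (lam in c(-1, -0.5, 0.1, 0.5, 1)) {
    expect_equal(scgf(ring, lam)$e_lam, closed(lam), tolerance = 1e-10)
  }
  sr0 <- scgf(ring, 0)
  expect_lt(abs(sr0$e_lam), 1e-10)
  expect_equal(unname(sr0$leading_right), unname(steady_state(ring)),
               tolerance = 1e-8)
  expect_equal(sum(sr0$leading_left * sr0$leading_right), 1)
})

test_that("tilting an open network is flagged", {
  expect_warning(sr <- scgf(t1_chain(5), 0.1), "open-boundary")
  expect_true(sr$open_flag)
})

test_that("mean current: equilibrium zero, biased ring J = 1, derivative of e(lam)", {
  expect_equal(mean_current(two_state_net(2, 2)), 0)
  ring <- biased_ring(2, 1, 10)
  expect_equal(mean_current(ring), 1, tolerance = 1e-12)
  h <- 1e-4
  deriv <- (scgf(ring, h)$e_lam - scgf(ring, -h)$e_lam) / (2 * h)
  expect_equal(deriv, mean_current(ring), tolerance = 1e-6)
})

test_that("spectral gap: two-state, circulant ring, and protected-size series", {
  expect_equal(spectral_gap(two_state_net(1, 1)), 2)
  n <- 8L
  ru <- biased_ring(1, 1, n)
  expect_equal(spectral_gap(ru), 2 * (1 - cos(2 * pi / n)), tolerance = 1e-10)
  # protected two-bulk ring: gap approaches the bulk band edge (sqrt(p)-sqrt(q))^2
  # instead of closing as the bulks grow
  gap20 <- spectral_gap(t1_ring(20))
  gap40 <- spectral_gap(t1_ring(40))
  asymptote <- (sqrt(2) - 1)^2
  expect_lt(abs(gap20 - asymptote) / asymptote, 0.2)
  expect_lt(abs(gap40 - asymptote) / asymptote, 0.2)
  expect_lt(abs(gap40 - asymptote), abs(gap20 - asymptote))
})

test_that("two-bulk ring zero mode: e(lam) vanishes inside the window and improves with size", {
  e_by_size <- vapply(c(10L, 20L, 40L),
                      function(N) scgf(t1_ring(N), 0.05)$e_lam, numeric(1))
  expect_lt(abs(e_by_size[3]), 1e-6)
  expect_true(all(diff(abs(e_by_size)) < 0))
  expect_lt(abs(mean_current(t1_ring(40))), 1e-6)
})
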