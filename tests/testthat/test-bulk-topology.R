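test_that("bloch matrix: scalar form, conservation at the origin, periodicity", {
  cell <- bulk_cell_1d(3, 2)
  for (k in c(0.3, 2)) {
    expect_equal(bloch_matrix(cell, k, 0.1)[1, 1],
                 3 * exp(1i * k + 0.1) + 2 * exp(-1i * k - 0.1) - 5)
  }
  B2 <- withr::with_seed(5, random_cell(2))
  expect_lt(Mod(stochtopo:::complex_det(bloch_matrix(B2, 0, 0))), 1e-12)
  expect_equal(bloch_matrix(B2, 0.7, 0.2), bloch_matrix(B2, 0.7 + 2 * pi, 0.2),
               tolerance = 1e-12)
})

test_that("winding numbers of the solvable single-row bulks", {
  expect_equal(winding_number(bulk_cell_1d(2, 1), 0.1)$w, 1L)
  expect_equal(winding_number(bulk_cell_1d(2, 1), -0.1)$w, 0L)
  expect_equal(winding_number(bulk_cell_1d(1, 2), -0.05)$w, -1L)
  expect_error(winding_number(bulk_cell_1d(2, 1), 0), "lam = 0")
})

test_that("argument-principle oracle: closed-form roots", {
  or <- winding_oracle_roots(bulk_cell_1d(2, 1), 0.1)
  expect_equal(or$charge, 1L)
  expect_equal(sort(Mod(or$roots)), sort(c(exp(-0.1), 0.5 * exp(-0.1))),
               tolerance = 1e-10)
  # p = q: double root at e^{-lam}
  or2 <- winding_oracle_roots(bulk_cell_1d(1, 1), 0.2)
  expect_equal(or2$charge, 1L)
  expect_equal(Mod(or2$roots), rep(exp(-0.2), 2), tolerance = 1e-6)
})

test_that("phase winding equals root counting on seeded random cells", {
  set.seed(20240901)
  compared <- 0L
  for (i in 1:40) {
    cell <- random_cell(sample(1:3, 1))
    for (lam in c(-0.3, -0.05, 0.05, 0.3)) {
      w_phase <- tryCatch(winding_number(cell, lam)$w, error = function(e) NA)
      w_roots <- tryCatch(winding_oracle_roots(cell, lam)$charge,
                          error = function(e) NA)
      if (!is.na(w_phase) && !is.na(w_roots)) {
        compared <- compared + 1L
        expect_identical(w_phase, w_roots)
      }
    }
  }
  expect_gt(compared, 100L)
})

test_that("winding is grid-independent and saturates at large |lam|", {
  set.seed(7)
  for (i in 1:8) {
    cell <- random_cell(sample(1:3, 1))
    for (lam in c(-0.3, 0.05)) {
      w512 <- tryCatch(winding_number(cell, lam, 512L)$w, error = function(e) NA)
      w4096 <- tryCatch(winding_number(cell, lam, 4096L)$w, error = function(e) NA)
      if (!is.na(w512) && !is.na(w4096)) expect_identical(w512, w4096)
    }
    expect_identical(winding_number(cell, 10)$w, winding_number(cell, 20)$w)
    expect_identical(winding_number(cell, -10)$w, winding_number(cell, -20)$w)
  }
})

test_that("sign convention: rightward bias gives +1; mirror reverses the winding", {
  expect_equal(winding_number(bulk_cell_1d(2, 1), 0.05)$w, 1L)
  set.seed(11)
  cell <- random_cell(2)
  mirror <- bulk_cell(cell$intra, cell$hop_minus, cell$hop_plus)
  for (lam in c(0.05, 0.3, -0.2)) {
    expect_identical(winding_number(mirror, lam)$w,
                     -winding_number(cell, -lam)$w)
  }
})

test_that("topological charge labels the proofreading kinetics", {
  expect_identical(topological_charge(bulk_cell_1d(2, 1)), 1L)
  expect_identical(topological_charge(bulk_cell_1d(1, 2)), -1L)
  expect_identical(topological_charge(bulk_cell_1d(1.5, 1.5)), 0L)
})

test_that("solvable window is (-log 2, log 2) with dw = 1 and matching decay rates", {
  win <- lambda_window(t1_left(), t1_right())
  expect_false(win$empty)
  expect_equal(win$lam_plus, log(2), tolerance = 1e-6)
  expect_equal(win$lam_minus, -log(2), tolerance = 1e-6)
  expect_identical(win$dw, 1L)

  dl <- bulk_decay_rates(t1_left())
  expect_equal(dl$decay, log(2), tolerance = 1e-9)
  expect_equal(dl$decay, abs(win$lam_minus), tolerance = 1e-6)
  expect_equal(1 / dl$decay, win$eta_left, tolerance = 1e-6)

  swapped <- lambda_window(t1_right(), t1_left())
  expect_identical(swapped$dw, -1L)
  expect_equal(swapped$lam_plus, log(2), tolerance = 1e-6)

  same <- lambda_window(t1_left(), t1_left())
  expect_true(same$empty)
  expect_identical(same$dw, 0L)
})

test_that("winding transitions coincide with a determinant root crossing the unit circle", {
  # for the solvable bulk the root (q/p) e^{-2 lam} family crosses |z| = 1 at lam = -log 2
  cell <- t1_left()
  for (eps in c(1e-4, 1e-5)) {
    expect_identical(winding_number(cell, -log(2) + eps)$w, 0L)
    expect_identical(winding_number(cell, -log(2) - eps)$w, -1L)
    rr <- winding_oracle_roots(cell, -log(2) + eps)
    expect_lt(min(abs(Mod(rr$roots) - 1)), 2 * eps)
  }
})

test_that("unbiased bulk is marginal: no decaying determinant root", {
  expect_warning(d <- bulk_decay_rates(bulk_cell_1d(1, 1)), "marginal")
  expect_length(d$decay, 0)
})
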