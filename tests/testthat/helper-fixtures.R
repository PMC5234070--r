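# canonical study fixtures, built in code

t1_left <- function() bulk_cell_1d(2, 1)
t1_right <- function() bulk_cell_1d(1, 2)

t1_ring <- function(columns_per_bulk = 40L) {
  build_two_bulk_ladder(t1_left(), t1_right(), columns_per_bulk,
                        interface_width = 1L, interface_rates = "linear",
                        boundary = "periodic")
}

t1_chain <- function(columns_per_bulk = 10L) {
  build_two_bulk_ladder(t1_left(), t1_right(), columns_per_bulk,
                        interface_width = 1L, interface_rates = "linear",
                        boundary = "open")
}

# homogeneous biased ring of exactly `n` columns
biased_ring <- function(p = 2, q = 1, n = 10L) {
  ids <- sprintf("r%02d", seq_len(n) - 1L)
  nxt <- ids[c(2:n, 1)]
  stoch_network(
    nodes = data.frame(id = ids, x = seq_len(n) - 1L, row = 0L, tag = "bulk_L"),
    edges = data.frame(src = c(ids, ids), dst = c(nxt, ids[c(n, 1:(n - 1))]),
                       rate = c(rep(p, n), rep(q, n)),
                       disp = rep(c(1L, -1L), each = n)),
    boundary = "periodic")
}

two_state_net <- function(r12 = 1, r21 = 1) {
  stoch_network(
    nodes = data.frame(id = c("a", "b"), x = 0:1, row = 0L, tag = "bulk_L"),
    edges = data.frame(src = c("a", "b"), dst = c("b", "a"),
                       rate = c(r12, r21), disp = c(1L, -1L)))
}

ring3 <- function(cw = 2, ccw = 1) {
  ids <- c("a", "b", "c")
  stoch_network(
    nodes = data.frame(id = ids, x = 0:2, row = 0L, tag = "bulk_L"),
    edges = data.frame(
      src = c(ids, ids),
      dst = c(ids[c(2, 3, 1)], ids[c(3, 1, 2)]),
      rate = c(rep(cw, 3), rep(ccw, 3)),
      disp = c(1L, 1L, 1L, -1L, -1L, -1L)),
    boundary = "periodic")
}

random_cell <- function(B) {
  lr <- function(n) exp(stats::runif(n, log(0.1), log(10)))
  intra <- matrix(0, B, B)
  if (B > 1) {
    off <- which(row(intra) != col(intra))
    intra[off] <- lr(length(off))
  }
  bulk_cell(intra, matrix(lr(B * B), B), matrix(lr(B * B), B))
}
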