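canonical_json <- function(x, path) {
  txt <- jsonlite::toJSON(x, dataframe = "rows", auto_unbox = TRUE,
                          digits = NA, pretty = 2, na = "null")
  writeLines(txt, path)
  invisible(path)
}

#' Read and write networks as JSON
#'
#' The network format has top-level keys `nodes` (list of
#' `{id, x, row, tag}`), `edges` (list of `{src, dst, rate, disp}`),
#' `boundary` and `metadata`. Serialization is canonical (fixed key order,
#' full-precision floats), so write -> read -> write is byte-identical.
#' Schema violations error naming the offending field; `disp` values other
#' than -1, 0, +1 are rejected (longer hops are reserved, unimplemented).
#'
#' @param path File path.
#' @param net A `stoch_network`.
#' @return `read_network()` returns a validated `stoch_network`;
#'   `write_network()` the path, invisibly.
#' @export
read_network <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (key in c("nodes", "edges", "boundary")) {
    if (is.null(obj[[key]])) stop("network file missing field '", key, "'")
  }
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(what, " entries missing field(s): ", paste(miss, collapse = ", "))
  }
  need(obj$nodes, c("id", "x", "row", "tag"), "node")
  need(obj$edges, c("src", "dst", "rate", "disp"), "edge")
  if (!obj$boundary %in% c("open", "periodic")) {
    stop("boundary must be 'open' or 'periodic', got '", obj$boundary, "'")
  }
  meta <- obj$metadata
  if (is.null(meta)) meta <- list()
  stoch_network(obj$nodes, obj$edges, boundary = obj$boundary, metadata = meta)
}

#' @rdname read_network
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "stoch_network"))
  canonical_json(
    list(nodes = as.data.frame(net$nodes),
         edges = as.data.frame(net$edges),
         boundary = net$boundary,
         metadata = net$metadata),
    path)
}

#' Read and write bulk unit cells as JSON
#'
#' Format: `{"n_internal": B, "intra": [[..]], "hop_plus": [[..]],
#' "hop_minus": [[..]]}` with row-major matrices.
#'
#' @param path File path.
#' @param cell A [bulk_cell()].
#' @export
read_cell <- function(path) {
  obj <- jsonlite::fromJSON(path)
  for (key in c("n_internal", "intra", "hop_plus", "hop_minus")) {
    if (is.null(obj[[key]])) stop("cell file missing field '", key, "'")
  }
  as_mat <- function(m) matrix(as.numeric(m), obj$n_internal, obj$n_internal)
  if (obj$n_internal == 1L) {
    bulk_cell(as_mat(obj$intra), as_mat(obj$hop_plus), as_mat(obj$hop_minus))
  } else {
    bulk_cell(obj$intra, obj$hop_plus, obj$hop_minus)
  }
}

#' @rdname read_cell
#' @export
write_cell <- function(cell, path) {
  stopifnot(inherits(cell, "bulk_cell"))
  canonical_json(list(n_internal = cell$n_internal, intra = cell$intra,
                      hop_plus = cell$hop_plus, hop_minus = cell$hop_minus),
                 path)
}

#' Generate the canonical test fixtures
#'
#' Writes the study networks and cells used throughout the test-suite to a
#' directory: the solvable single-row two-bulk pair (open and periodic, hop
#' rates 2/1 against 1/2), an identical-bulk control ring, a two-row ladder,
#' adaptation networks at G in {-2, 0, 2} (M = 48, E = 6), proofreading
#' chains for the correct and wrong substrate (n = 5), and a disordered
#' variant of the two-bulk ring. A `manifest.json` records the expected
#' derived quantities (window endpoints +/- log 2, winding mismatches,
#' decay rates) and the provenance of each file. Deterministic given the
#' seed.
#'
#' @param out_dir Writable directory (created if needed).
#' @param seed Seed for the disordered fixture.
#' @param columns_per_bulk Bulk width of the ladder fixtures.
#' @return Invisibly, the manifest list.
#' @export
make_fixtures <- function(out_dir, seed = 1L, columns_per_bulk = 40L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  left <- bulk_cell_1d(2, 1); right <- bulk_cell_1d(1, 2)
  write_cell(left, fp("cell_left.json"))
  write_cell(right, fp("cell_right.json"))
  write_network(build_two_bulk_ladder(left, right, columns_per_bulk, 1, "linear", "open"),
                fp("two_bulk_open.json"))
  ring <- build_two_bulk_ladder(left, right, columns_per_bulk, 1, "linear", "periodic")
  write_network(ring, fp("two_bulk_ring.json"))
  write_network(apply_disorder(ring, 0.3, seed), fp("two_bulk_ring_disordered.json"))
  write_network(build_two_bulk_ladder(left, left, columns_per_bulk, 1, "linear", "periodic"),
                fp("identical_bulk_ring.json"))
  two_row_left <- bulk_cell(matrix(c(0, 0.5, 0.5, 0), 2, 2), diag(c(2, 2)), diag(c(1, 1)))
  two_row_right <- bulk_cell(matrix(c(0, 0.5, 0.5, 0), 2, 2), diag(c(1, 1)), diag(c(2, 2)))
  write_network(build_two_bulk_ladder(two_row_left, two_row_right, columns_per_bulk,
                                      1, "linear", "periodic"),
                fp("two_row_ladder_ring.json"))
  for (G in c(-2, 0, 2)) {
    write_network(build_adaptation_network(adaptation_spec(M = 48L, E = 6, G = G)),
                  fp(sprintf("adaptation_G%+d.json", G)))
  }
  write_network(build_proofreading_chain(5, 2, 1, "R"), fp("proofreading_R.json"))
  write_network(build_proofreading_chain(5, 1, 2, "W"), fp("proofreading_W.json"))
  manifest <- list(
    seed = seed,
    columns_per_bulk = columns_per_bulk,
    solvable_pair = list(
      lam_minus = -log(2), lam_plus = log(2), dw = 1,
      decay_rate = log(2), eta = 1 / log(2)),
    identical_bulk = list(dw = 0),
    proofreading = list(charge_R = 1, charge_W = -1,
                        end_ratio_R = 2^5, end_ratio_W = 2^-5),
    adaptation = list(dw_G_plus2 = 1, dw_G_minus2 = -1, M = 48, E = 6),
    files = list.files(out_dir))
  canonical_json(manifest, fp("manifest.json"))
  invisible(manifest)
}
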