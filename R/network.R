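#' Markov state networks on a horizontal axis
#'
#' A `stoch_network` is a directed rate graph whose nodes carry an integer
#' horizontal coordinate `x` (the axis along which probability current is
#' counted) and an internal row index, and whose edges carry a positive
#' transition rate and an integer current displacement `disp`. The
#' displacement is the winding-corrected jump length along the axis: a hop
#' across a periodic seam counts +1 or -1, never the raw coordinate
#' difference.
#'
#' @param nodes A data frame with columns `id` (unique character), `x`
#'   (integer column index), `row` (integer row within the column) and `tag`
#'   (one of `"bulk_L"`, `"bulk_R"`, `"interface"`, `"vacuum_boundary"`).
#' @param edges A data frame with columns `src`, `dst` (node ids), `rate`
#'   (positive, 1/time) and `disp` (integer in -1, 0, +1).
#' @param boundary `"open"` or `"periodic"`.
#' @param metadata Free-form provenance list (builder name, parameters,
#'   disorder seed).
#' @param validate Run the full invariant check (strong connectivity, unique
#'   ids, no self or duplicate edges). Default `TRUE`.
#'
#' @return An object of class `stoch_network`: a list with tibble members
#'   `nodes` and `edges` plus `boundary` and `metadata`.
#' @export
#' @examples
#' net <- stoch_network(
#'   nodes = data.frame(id = c("a", "b"), x = 0:1, row = 0L, tag = "bulk_L"),
#'   edges = data.frame(src = c("a", "b"), dst = c("b", "a"),
#'                      rate = c(3, 1), disp = c(1L, -1L))
#' )
#' build_generator(net)
stoch_network <- function(nodes, edges, boundary = c("open", "periodic"),
                          metadata = list(), validate = TRUE) {
  boundary <- match.arg(boundary)
  nodes <- tibble::as_tibble(nodes)[, c("id", "x", "row", "tag")]
  edges <- tibble::as_tibble(edges)[, c("src", "dst", "rate", "disp")]
  nodes$id <- as.character(nodes$id)
  nodes$x <- as.integer(nodes$x)
  nodes$row <- as.integer(nodes$row)
  nodes$tag <- as.character(nodes$tag)
  edges$src <- as.character(edges$src)
  edges$dst <- as.character(edges$dst)
  edges$rate <- as.double(edges$rate)
  edges$disp <- as.integer(edges$disp)
  net <- structure(
    list(nodes = nodes, edges = edges, boundary = boundary,
         metadata = metadata),
    class = "stoch_network"
  )
  if (validate) validate_stoch_network(net)
  net
}

#' Validate a stochastic network
#'
#' Checks the structural invariants: unique node ids, known tags, positive
#' rates, displacements in -1/0/+1, no self-edges, at most one edge per
#' ordered node pair, and strong connectivity (irreducibility of the
#' generator). Errors name the offending nodes/edges; a reducible network is
#' reported with its strongly connected components.
#'
#' @param net A `stoch_network`.
#' @return `net`, invisibly, if valid.
#' @export
validate_stoch_network <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }
  bad_tag <- setdiff(unique(nodes$tag),
                     c("bulk_L", "bulk_R", "interface", "vacuum_boundary"))
  if (length(bad_tag)) stop("unknown node tag(s): ", paste(bad_tag, collapse = ", "))
  unknown <- setdiff(c(edges$src, edges$dst), nodes$id)
  if (length(unknown)) {
    stop("edges reference unknown node id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (any(!is.finite(edges$rate)) || any(edges$rate <= 0)) {
    i <- which(!is.finite(edges$rate) | edges$rate <= 0)[1]
    stop(sprintf("edge %s -> %s has non-positive rate %g",
                 edges$src[i], edges$dst[i], edges$rate[i]))
  }
  if (any(!edges$disp %in% c(-1L, 0L, 1L))) {
    i <- which(!edges$disp %in% c(-1L, 0L, 1L))[1]
    stop(sprintf("edge %s -> %s has disp = %d; only -1, 0, +1 are supported",
                 edges$src[i], edges$dst[i], edges$disp[i]))
  }
  if (any(edges$src == edges$dst)) {
    i <- which(edges$src == edges$dst)[1]
    stop("self-edge on node ", edges$src[i])
  }
  key <- paste(edges$src, edges$dst, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop(sprintf("duplicate edge %s -> %s", edges$src[i], edges$dst[i]))
  }
  g <- igraph::graph_from_data_frame(edges[, c("src", "dst")],
                                     directed = TRUE, vertices = nodes$id)
  comp <- igraph::components(g, mode = "strong")
  if (comp$no > 1L) {
    parts <- split(nodes$id, comp$membership[nodes$id])
    desc <- vapply(parts, function(p) {
      p <- sort(p)
      if (length(p) > 4) paste0("{", paste(p[1:4], collapse = ","), ",... (", length(p), " nodes)}")
      else paste0("{", paste(p, collapse = ","), "}")
    }, character(1))
    stop("network is not strongly connected (reducible generator); ",
         comp$no, " components: ", paste(desc, collapse = " "))
  }
  invisible(net)
}

#' @export
print.stoch_network <- function(x, ...) {
  cat(sprintf("<stoch_network> %d nodes, %d edges, %s boundary\n",
              nrow(x$nodes), nrow(x$edges), x$boundary))
  cat(sprintf("  columns %d..%d, rows per column <= %d\n",
              min(x$nodes$x), max(x$nodes$x), max(x$nodes$row) + 1L))
  if (!is.null(x$metadata$builder)) {
    cat("  builder:", x$metadata$builder, "\n")
  }
  invisible(x)
}

# --- region helpers -----------------------------------------------------

#' Select node ids by column
#'
#' Region projectors are plain character vectors of node ids; these helpers
#' build the usual ones. `region_columns()` takes explicit column indices,
#' `interface_region()` expands a stored interface centre by `pad` columns on
#' each side (builders record `metadata$interface_centers`).
#'
#' @param net A `stoch_network`.
#' @param columns Integer vector of column indices (`x` values).
#' @param which Which interface (1-based) among the stored centres.
#' @param pad Columns to include on each side of the interface centre.
#' @return Character vector of node ids.
#' @export
region_columns <- function(net, columns) {
  ids <- net$nodes$id[net$nodes$x %in% as.integer(columns)]
  if (!length(ids)) stop("region is empty: no nodes in the given columns")
  ids
}

#' @rdname region_columns
#' @export
interface_region <- function(net, which = 1L, pad = 3L) {
  centers <- net$metadata$interface_centers
  if (is.null(centers)) {
    stop("network metadata carries no interface_centers; use region_columns()")
  }
  if (which > length(centers)) stop("network has ", length(centers), " interfaces")
  ctr <- centers[[which]]
  cols <- seq.int(floor(ctr - pad), ceiling(ctr + pad))
  nc <- max(net$nodes$x) + 1L
  if (net$boundary == "periodic") cols <- cols %% nc else cols <- cols[cols >= 0 & cols < nc]
  region_columns(net, cols)
}
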