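# Travel-time catchments: road graphs, centroid snapping, and the sparse
# origin-destination matrix.

#' Construct a road graph from node and edge tables
#'
#' Edge traversal times are minutes directly; no speed-limit or length
#' conversion is done here, which keeps the module agnostic of the routing
#' engine that produced the data.  Undirected edges are expanded to two
#' arcs.
#'
#' @param nodes `data.frame` with columns `node_id`, `x`, `y`.
#' @param edges `data.frame` with columns `from_node`, `to_node`,
#'   `minutes` and optionally logical `oneway` (default `FALSE`, i.e.
#'   two-way).
#' @return An object of class `road_graph` holding the node table and the
#'   directed arc table.
#' @export
road_graph <- function(nodes, edges) {
  stopifnot(all(c("node_id", "x", "y") %in% names(nodes)),
            all(c("from_node", "to_node", "minutes") %in% names(edges)))
  nodes <- data.frame(node_id = as.character(nodes$node_id),
                      x = as.numeric(nodes$x), y = as.numeric(nodes$y),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$node_id))
    stop("duplicate node_id in road graph")
  if (nrow(edges) > 0 &&
      (any(!is.finite(edges$minutes)) || any(edges$minutes <= 0)))
    stop("edge traversal times must be strictly positive")
  oneway <- if ("oneway" %in% names(edges)) as.logical(edges$oneway)
            else rep(FALSE, nrow(edges))
  arcs <- data.frame(from = as.character(edges$from_node),
                     to = as.character(edges$to_node),
                     minutes = as.numeric(edges$minutes),
                     stringsAsFactors = FALSE)
  back <- arcs[!oneway, c("to", "from", "minutes")]
  names(back) <- c("from", "to", "minutes")
  arcs <- rbind(arcs, back)
  unknown <- setdiff(unique(c(arcs$from, arcs$to)), nodes$node_id)
  if (length(unknown))
    stop("edge references unknown node(s): ",
         paste(unknown, collapse = ", "))
  structure(list(nodes = nodes, arcs = arcs), class = "road_graph")
}

#' @export
print.road_graph <- function(x, ...) {
  cat(sprintf("<road_graph> %d nodes, %d directed arcs\n",
              nrow(x$nodes), nrow(x$arcs)))
  invisible(x)
}

as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    graph$arcs[, c("from", "to")], directed = TRUE,
    vertices = graph$nodes$node_id)
  igraph::E(g)$weight <- graph$arcs$minutes
  g
}

#' Snap block centroids to their nearest road-graph node
#'
#' Each centroid maps to the nearest node by Euclidean distance in the
#' working coordinate system; ties break deterministically to the smallest
#' `node_id`.
#'
#' @param points `data.frame` with columns `block_id`, `x`, `y` (a
#'   [blocks()] table works).
#' @param graph a [road_graph()].
#' @return Named character vector: `block_id -> node_id`.
#' @export
snap_to_graph <- function(points, graph) {
  if (nrow(graph$nodes) == 0L)
    stop("road graph has no nodes")
  nd <- graph$nodes[order(graph$nodes$node_id), ]
  out <- vapply(seq_len(nrow(points)), function(i) {
    d2 <- (nd$x - points$x[i])^2 + (nd$y - points$y[i])^2
    nd$node_id[which.min(d2)]   # first minimum = smallest node_id
  }, character(1))
  names(out) <- points$block_id
  out
}

#' Shortest-path origin-destination travel-time matrix
#'
#' Computes, for every origin block and destination block, the
#' shortest-path travel time in minutes between their snapped road-graph
#' nodes.  Pairs with no connecting path -- or beyond `cutoff`, when one
#' is given -- are absent from the result (unreachable), never recorded
#' as 0.  Self-pairs are present with the node-to-node shortest time
#' (0 when both blocks snap to the same node).
#'
#' Pruning at the largest catchment radius of interest via `cutoff` is the
#' supported way to keep the matrix sparse: the full cross-product over a
#' large study area is neither feasible nor needed.
#'
#' @param graph a [road_graph()].
#' @param origins,destinations named character vectors
#'   (`block_id -> node_id`) as returned by [snap_to_graph()].
#' @param cutoff optional travel-time cutoff in minutes.
#' @return An [od_pairs()] table.
#' @export
od_matrix <- function(graph, origins, destinations = origins,
                      cutoff = NULL) {
  g <- as_igraph(graph)
  known <- graph$nodes$node_id
  bad <- setdiff(unique(c(origins, destinations)), known)
  if (length(bad))
    stop("unknown node(s): ", paste(bad, collapse = ", "))
  onodes <- unique(unname(origins))
  dnodes <- unique(unname(destinations))
  dm <- igraph::distances(g, v = onodes, to = dnodes, mode = "out")
  t_o <- dm[match(unname(origins), onodes),
            match(unname(destinations), dnodes), drop = FALSE]
  df <- data.frame(
    origin = rep(names(origins), times = length(destinations)),
    destination = rep(names(destinations), each = length(origins)),
    minutes = as.vector(t_o),
    stringsAsFactors = FALSE
  )
  df <- df[is.finite(df$minutes), , drop = FALSE]
  if (!is.null(cutoff))
    df <- df[df$minutes <= cutoff, , drop = FALSE]
  od_pairs(df$origin, df$destination, df$minutes)
}

#' Number of entries in a full origin-destination cross product
#'
#' The size of a dense block-to-block matrix grows quadratically: a study
#' area of 166,980 blocks implies 27,882,320,400 pairs, which is why the
#' package stores travel times sparsely and prunes at the catchment
#' radius.
#'
#' @param n_blocks number of blocks.
#' @return `n_blocks^2` as a double (exceeds 32-bit integer range
#'   quickly).
#' @export
od_pair_count <- function(n_blocks) {
  as.numeric(n_blocks)^2
}
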