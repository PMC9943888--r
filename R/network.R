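#' Genetic network
#'
#' A weighted node/edge representation of genetic covariance among lek
#' clusters (or any spatially referenced populations). Edge weights are
#' non-negative genetic covariances; an optional betweenness attribute
#' carries externally computed prioritization values.
#'
#' @param nodes data.frame with columns id, x, y (projected coordinates).
#' @param edges data.frame with columns node_a, node_b, weight and
#'   optionally edge_id, betweenness, in_mst. Missing edge ids are assigned
#'   1..n in row order.
#' @return an object of class \code{genetic_network}.
#' @export
genetic_network <- function(nodes, edges) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  stopifnot(all(c("id", "x", "y") %in% names(nodes)),
            all(c("node_a", "node_b", "weight") %in% names(edges)))
  if (anyDuplicated(nodes$id)) stop("node ids must be unique", call. = FALSE)
  if (any(edges$node_a == edges$node_b))
    stop("self-loops are not allowed", call. = FALSE)
  key <- paste(pmin(as.character(edges$node_a), as.character(edges$node_b)),
               pmax(as.character(edges$node_a), as.character(edges$node_b)))
  if (anyDuplicated(key))
    stop("at most one edge per unordered node pair", call. = FALSE)
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0))
    stop("edge weights must be finite and >= 0", call. = FALSE)
  if (is.null(edges$edge_id)) edges$edge_id <- seq_len(nrow(edges))
  structure(list(nodes = nodes, edges = edges), class = "genetic_network")
}

#' @export
print.genetic_network <- function(x, ...) {
  cat(sprintf("<genetic_network> %d nodes, %d edges%s\n",
              nrow(x$nodes), nrow(x$edges),
              if (!is.null(x$edges$betweenness)) " (betweenness attached)" else ""))
  invisible(x)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    data.frame(from = as.character(network$edges$node_a),
               to = as.character(network$edges$node_b),
               weight = network$edges$weight,
               edge_id = network$edges$edge_id),
    directed = FALSE,
    vertices = data.frame(name = as.character(network$nodes$id)))
}

#' Maximum-covariance spanning tree
#'
#' Returns the spanning tree maximizing total genetic covariance: the edge
#' subset connecting all nodes, representing maximum genetic covariance,
#' without cycles. (Such trees are often labelled "minimum spanning trees"
#' when the network is expressed in genetic distance; both senses are
#' available.) Kruskal's algorithm with ties broken on ascending edge id
#' makes the result reproducible under equal weights. A disconnected
#' network yields a spanning forest with a warning.
#'
#' @param network a \code{genetic_network}.
#' @param sense "max" (default, maximum covariance) or "min".
#' @return integer/character vector of edge ids in the tree; the network
#'   with flags is available via \code{flag_mst}.
#' @export
spanning_tree <- function(network, sense = c("max", "min")) {
  sense <- match.arg(sense)
  e <- network$edges
  ord <- if (sense == "max") order(-e$weight, e$edge_id)
         else order(e$weight, e$edge_id)
  ids <- as.character(network$nodes$id)
  parent <- stats::setNames(ids, ids)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  picked <- e$edge_id[0]
  for (k in ord) {
    ra <- find(as.character(e$node_a[k])); rb <- find(as.character(e$node_b[k]))
    if (ra != rb) { parent[ra] <- rb; picked <- c(picked, e$edge_id[k]) }
  }
  n_comp <- length(unique(vapply(ids, find, character(1))))
  if (n_comp > 1L)
    warning(sprintf("network is disconnected (%d components): returning a spanning forest",
                    n_comp), call. = FALSE)
  picked
}

#' Flag spanning-tree membership on a network
#' @param network a \code{genetic_network}.
#' @param tree_ids edge ids from \code{spanning_tree}.
#' @export
flag_mst <- function(network, tree_ids = spanning_tree(network)) {
  network$edges$in_mst <- network$edges$edge_id %in% tree_ids
  network
}

#' Shortest-path edge betweenness
#'
#' Counts, for each edge, the (fractionally split) number of node pairs
#' whose shortest path traverses it; larger values mark edges fostering
#' more pairwise genetic interconnectivity. With the default reciprocal
#' weight rule an edge's path length is 1/weight, so high-covariance edges
#' attract shortest paths; unit lengths are available for sensitivity
#' checks.
#'
#' @param network a \code{genetic_network}.
#' @param length_rule "reciprocal-weight" (default) or "unit".
#' @return numeric vector of betweenness values in the order of
#'   \code{network$edges}.
#' @export
edge_betweenness <- function(network,
                             length_rule = c("reciprocal-weight", "unit")) {
  length_rule <- match.arg(length_rule)
  if (nrow(network$edges) == 0L) stop("network has no edges", call. = FALSE)
  ig <- as_igraph(network)
  len <- if (length_rule == "unit") rep(1, nrow(network$edges)) else {
    if (any(network$edges$weight <= 0))
      stop("reciprocal-weight lengths require strictly positive weights",
           call. = FALSE)
    1 / network$edges$weight
  }
  bt <- igraph::edge_betweenness(ig, weights = len, directed = FALSE)
  # igraph preserves the edge order of the input data.frame
  bt
}

#' Rank spanning-tree edges by betweenness
#'
#' Orders the spanning-tree edges by betweenness, descending, breaking ties
#' on ascending edge id. Provided betweenness attributes (e.g. loaded from
#' an external network-model table) are preferred when requested and
#' present; otherwise betweenness is computed from the network.
#'
#' @param network a \code{genetic_network}.
#' @param use_provided prefer an existing \code{betweenness} edge column.
#' @param top_k truncate the ranking (default all tree edges).
#' @param length_rule passed to \code{edge_betweenness} when computing.
#' @return data.frame: rank, edge_id, node_a, node_b, betweenness, source.
#' @export
rank_mst_edges <- function(network, use_provided = TRUE, top_k = Inf,
                           length_rule = "reciprocal-weight") {
  if (is.null(network$edges$in_mst)) network <- flag_mst(network)
  e <- network$edges
  if (use_provided && !is.null(e$betweenness) && !anyNA(e$betweenness)) {
    bt <- e$betweenness; src <- "provided"
  } else {
    if (use_provided && !is.null(e$betweenness))
      warning("provided betweenness has missing values: computing instead",
              call. = FALSE)
    bt <- edge_betweenness(network, length_rule); src <- "computed"
  }
  m <- e$in_mst
  ord <- order(-bt[m], e$edge_id[m])
  out <- data.frame(rank = seq_len(sum(m)),
                    edge_id = e$edge_id[m][ord],
                    node_a = e$node_a[m][ord],
                    node_b = e$node_b[m][ord],
                    betweenness = bt[m][ord],
                    source = src)
  utils::head(out, n = if (is.finite(top_k)) top_k else nrow(out))
}

#' Read/write node and edge tables
#'
#' Headered CSV interchange: nodes as id,x,y; edges as
#' edge_id,node_a,node_b,weight with optional betweenness.
#'
#' @param network a \code{genetic_network}.
#' @param nodes_path,edges_path file paths.
#' @export
write_network_csv <- function(network, nodes_path, edges_path) {
  utils::write.csv(network$nodes[, c("id", "x", "y")], nodes_path,
                   row.names = FALSE)
  cols <- intersect(c("edge_id", "node_a", "node_b", "weight", "betweenness"),
                    names(network$edges))
  utils::write.csv(network$edges[, cols], edges_path, row.names = FALSE)
  invisible(network)
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(nodes_path, edges_path) {
  genetic_network(utils::read.csv(nodes_path), utils::read.csv(edges_path))
}
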