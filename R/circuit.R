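#' Build a resistance graph from a raster
#'
#' Treats each non-nodata cell as a vertex and connects adjacent cells under
#' the chosen neighbourhood. The resistance of an inter-cell link is the
#' arithmetic mean of the two cell resistances, multiplied by sqrt(2) for
#' diagonal neighbours (the standard raster circuit convention); conductance
#' is its reciprocal. Queen's-case (8-neighbour) adjacency is the default,
#' matching how gene-flow analyses treat movement to all eight neighbouring
#' cells.
#'
#' @param raster a \code{resistance_raster}.
#' @param neighborhood "queen-8" (default) or "rook-4".
#' @return an object of class \code{resistance_graph} with fields:
#'   \code{vertex_of} (integer matrix mapping cells to vertex ids, NA on
#'   nodata), \code{cells} (row/col per vertex), \code{edges} (data.frame
#'   v1, v2, resistance, conductance), \code{component} (integer label per
#'   vertex), \code{georef}.
#' @export
build_resistance_graph <- function(raster, neighborhood = c("queen-8", "rook-4")) {
  neighborhood <- match.arg(neighborhood)
  g <- raster$georef
  ok <- !g$nodata_mask
  n_v <- sum(ok)
  if (n_v == 0L) stop("raster has no non-nodata cells", call. = FALSE)
  vertex_of <- matrix(NA_integer_, g$n_rows, g$n_cols)
  vertex_of[ok] <- seq_len(n_v)  # column-major order: deterministic
  idx <- which(ok, arr.ind = TRUE)
  cells <- data.frame(row = idx[, 1], col = idx[, 2])
  o <- order(vertex_of[ok])
  cells <- cells[o, , drop = FALSE]
  rownames(cells) <- NULL

  offs <- list(c(0L, 1L), c(1L, 0L))
  if (neighborhood == "queen-8") offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  vals <- raster$values
  e1 <- integer(); e2 <- integer(); res <- numeric()
  for (d in offs) {
    dr <- d[1]; dc <- d[2]
    r1 <- seq_len(g$n_rows - dr)
    c1 <- if (dc >= 0) seq_len(g$n_cols - dc) else seq.int(1L - dc, g$n_cols)
    a <- as.matrix(expand.grid(row = r1, col = c1))
    b <- cbind(a[, 1] + dr, a[, 2] + dc)
    va <- vertex_of[a]; vb <- vertex_of[b]
    keep <- !is.na(va) & !is.na(vb)
    if (!any(keep)) next
    r_link <- (vals[a[keep, , drop = FALSE]] + vals[b[keep, , drop = FALSE]]) / 2
    if (dr != 0L && dc != 0L) r_link <- r_link * sqrt(2)
    e1 <- c(e1, va[keep]); e2 <- c(e2, vb[keep]); res <- c(res, r_link)
  }
  edges <- data.frame(v1 = pmin(e1, e2), v2 = pmax(e1, e2),
                      resistance = res, conductance = 1 / res)
  edges <- edges[order(edges$v1, edges$v2), , drop = FALSE]
  rownames(edges) <- NULL

  comp <- if (nrow(edges)) {
    ig <- igraph::graph_from_edgelist(cbind(edges$v1, edges$v2),
                                      directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0L, n_v - igraph::vcount(ig)))
    igraph::components(ig)$membership
  } else seq_len(n_v)

  structure(list(vertex_of = vertex_of, cells = cells, edges = edges,
                 component = as.integer(comp), georef = g,
                 neighborhood = neighborhood),
            class = "resistance_graph")
}

#' @export
print.resistance_graph <- function(x, ...) {
  cat(sprintf("<resistance_graph> %d vertices, %d edges (%s), %d component(s)\n",
              nrow(x$cells), nrow(x$edges), x$neighborhood,
              length(unique(x$component))))
  invisible(x)
}

# Sparse graph Laplacian of the conductance-weighted resistance graph.
graph_laplacian <- function(graph) {
  n <- nrow(graph$cells)
  e <- graph$edges
  A <- Matrix::sparseMatrix(i = c(e$v1, e$v2), j = c(e$v2, e$v1),
                            x = c(e$conductance, e$conductance),
                            dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(A)) - A
}

# Factorize the Laplacian grounded at a reference vertex of each component:
# returns a solver closure mapping a right-hand side over all vertices
# (which must sum to zero within each component touched) to a potential
# vector that is zero at each component's reference vertex.
laplacian_solver <- function(graph) {
  n <- nrow(graph$cells)
  comp <- graph$component
  ref <- vapply(split(seq_len(n), comp), min, integer(1))  # one ground/comp
  keep <- setdiff(seq_len(n), ref)
  L <- graph_laplacian(graph)
  Lr <- L[keep, keep, drop = FALSE]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Lr), LDL = FALSE, perm = TRUE)
  function(b) {
    v <- numeric(n)
    v[keep] <- as.numeric(Matrix::solve(ch, b[keep]))
    v
  }
}

pair_solution <- function(edge_id, source_vertex, ground_vertex, graph,
                          potentials = NULL, infinite = FALSE) {
  g <- graph$georef
  cur <- matrix(0, g$n_rows, g$n_cols)
  if (infinite) {
    cur[g$nodata_mask] <- NA_real_
    return(structure(list(edge_id = edge_id, source_vertex = source_vertex,
                          ground_vertex = ground_vertex,
                          effective_resistance = Inf,
                          current_map = conn_raster(cur, g, "current_map"),
                          potentials = NULL),
                     class = "pair_solution"))
  }
  e <- graph$edges
  branch <- abs(potentials[e$v1] - potentials[e$v2]) * e$conductance
  per_vertex <- numeric(nrow(graph$cells))
  agg1 <- tapply(branch, e$v1, sum); agg2 <- tapply(branch, e$v2, sum)
  per_vertex[as.integer(names(agg1))] <- per_vertex[as.integer(names(agg1))] + agg1
  per_vertex[as.integer(names(agg2))] <- per_vertex[as.integer(names(agg2))] + agg2
  per_vertex <- per_vertex / 2
  per_vertex[c(source_vertex, ground_vertex)] <- 1  # terminals carry the unit injection
  cur[cbind(graph$cells$row, graph$cells$col)] <- per_vertex
  cur[g$nodata_mask] <- NA_real_
  structure(list(edge_id = edge_id, source_vertex = source_vertex,
                 ground_vertex = ground_vertex,
                 effective_resistance =
                   potentials[source_vertex] - potentials[ground_vertex],
                 current_map = conn_raster(cur, g, "current_map"),
                 potentials = potentials),
            class = "pair_solution")
}

#' @export
print.pair_solution <- function(x, ...) {
  cat(sprintf("<pair_solution> edge %s: R_eff = %g\n",
              as.character(x$edge_id), x$effective_resistance))
  invisible(x)
}

#' Solve one pairwise circuit problem
#'
#' Injects a unit current at the source cell and grounds the ground cell,
#' solving the conductance-weighted graph Laplacian system. The effective
#' resistance is the source potential (ground at zero); the per-cell current
#' is half the sum of absolute branch currents incident to the cell, with
#' the two terminal cells carrying the full injected current (1). A
#' source/ground pair in different graph components yields an infinite
#' resistance with an all-zero current map and a warning, not an error.
#'
#' @param graph a \code{resistance_graph}.
#' @param source_cell,ground_cell length-2 integer (row, col) cell indices.
#' @param edge_id identifier carried into the solution (default NA).
#' @param solver optional pre-factorized solver from repeated use; internal.
#' @return a \code{pair_solution}.
#' @export
solve_pair <- function(graph, source_cell, ground_cell, edge_id = NA,
                       solver = NULL) {
  vs <- graph$vertex_of[source_cell[1], source_cell[2]]
  vg <- graph$vertex_of[ground_cell[1], ground_cell[2]]
  if (is.na(vs) || is.na(vg))
    stop("source or ground cell is nodata", call. = FALSE)
  if (vs == vg) stop("source and ground must differ", call. = FALSE)
  if (graph$component[vs] != graph$component[vg]) {
    warning(sprintf("source and ground are in different components (edge %s): infinite resistance",
                    as.character(edge_id)), call. = FALSE)
    return(pair_solution(edge_id, vs, vg, graph, infinite = TRUE))
  }
  if (is.null(solver)) solver <- laplacian_solver(graph)
  b <- numeric(nrow(graph$cells)); b[vs] <- 1; b[vg] <- -1
  v <- solver(b)
  # residual check on the full system (rank-deficient directions excluded
  # because b sums to zero per component)
  L <- graph_laplacian(graph)
  resid <- sqrt(sum((as.numeric(L %*% v) - b)^2)) / sqrt(2)
  if (!is.finite(resid) || resid > 1e-8)
    stop(sprintf("linear solve failed: relative residual %g > 1e-8", resid),
         call. = FALSE)
  v <- v - v[vg]  # ground at zero potential
  pair_solution(edge_id, vs, vg, graph, potentials = v)
}

#' Solve all pairwise circuit problems of a genetic network
#'
#' Snaps every network node to its containing cell, factorizes the grounded
#' Laplacian once, and solves one circuit problem per network edge. Results
#' are identical to independent \code{solve_pair} calls and are returned in
#' edge-id order.
#'
#' @param graph a \code{resistance_graph}.
#' @param network a \code{genetic_network}.
#' @param keep_maps logical; retain each pair's current map (default TRUE).
#'   With FALSE only the running cumulative map and the resistance table are
#'   kept, bounding memory for large edge sets.
#' @return list with \code{solutions} (list of \code{pair_solution}, or NULL
#'   entries when \code{keep_maps = FALSE}), \code{resistance_table}
#'   (data.frame edge_id, node_a, node_b, effective_resistance) and
#'   \code{cumulative} (a \code{cumulative_map}).
#' @export
solve_all_pairs <- function(graph, network, keep_maps = TRUE) {
  nodes <- network$nodes
  rc <- snap_to_cell(graph$georef, nodes$x, nodes$y)
  vtx <- graph$vertex_of[cbind(rc$row, rc$col)]
  if (any(is.na(vtx))) {
    # allow a one-cell-radius rescue onto the nearest valid neighbour
    for (i in which(is.na(vtx))) {
      nb <- expand.grid(r = rc$row[i] + (-1:1), c = rc$col[i] + (-1:1))
      nb <- nb[nb$r >= 1 & nb$r <= graph$georef$n_rows &
                 nb$c >= 1 & nb$c <= graph$georef$n_cols, ]
      cand <- graph$vertex_of[cbind(nb$r, nb$c)]
      cand <- cand[!is.na(cand)]
      if (!length(cand))
        stop(sprintf("node '%s' falls on nodata with no valid neighbour",
                     as.character(nodes$id[i])), call. = FALSE)
      vtx[i] <- cand[1]
    }
  }
  names(vtx) <- as.character(nodes$id)
  solver <- laplacian_solver(graph)
  edges <- network$edges[order(network$edges$edge_id), , drop = FALSE]
  g <- graph$georef
  cum <- matrix(0, g$n_rows, g$n_cols)
  sols <- vector("list", nrow(edges))
  reff <- numeric(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    vs <- vtx[[as.character(edges$node_a[k])]]
    vg <- vtx[[as.character(edges$node_b[k])]]
    if (graph$component[vs] != graph$component[vg]) {
      warning(sprintf("edge %s spans components: infinite resistance",
                      as.character(edges$edge_id[k])), call. = FALSE)
      sol <- pair_solution(edges$edge_id[k], vs, vg, graph, infinite = TRUE)
    } else {
      b <- numeric(nrow(graph$cells)); b[vs] <- 1; b[vg] <- -1
      v <- solver(b)
      v <- v - v[vg]
      sol <- pair_solution(edges$edge_id[k], vs, vg, graph, potentials = v)
    }
    reff[k] <- sol$effective_resistance
    if (is.finite(sol$effective_resistance)) {
      m <- sol$current_map$values
      m[is.na(m)] <- 0
      cum <- cum + m
    }
    sols[[k]] <- if (keep_maps) sol else NULL
  }
  cum[g$nodata_mask] <- NA_real_
  list(solutions = sols,
       resistance_table = data.frame(edge_id = edges$edge_id,
                                     node_a = edges$node_a,
                                     node_b = edges$node_b,
                                     effective_resistance = reff),
       cumulative = cumulative_map(cum, g, n_pairs = nrow(edges)))
}

#' Effective-resistance matrix among a set of cells
#'
#' Computes pairwise effective resistances among k terminal cells with k
#' grounded solves (one per terminal against a common reference) instead of
#' k(k-1)/2 pair solves, using linearity of the Laplacian system. Pairs in
#' different components get Inf.
#'
#' @param graph a \code{resistance_graph}.
#' @param cells data.frame with columns row, col (one terminal per row).
#' @return symmetric k x k matrix of effective resistances (0 diagonal).
#' @export
effective_resistance_matrix <- function(graph, cells) {
  vtx <- graph$vertex_of[cbind(cells$row, cells$col)]
  if (any(is.na(vtx))) stop("terminal cell is nodata", call. = FALSE)
  k <- length(vtx)
  solver <- laplacian_solver(graph)
  comp <- graph$component[vtx]
  n <- nrow(graph$cells)
  # one solve per terminal, grounded at the first terminal of its component
  ref_of <- vapply(comp, function(cc) vtx[match(cc, comp)], integer(1))
  pots <- matrix(0, n, k)
  for (i in seq_len(k)) {
    if (vtx[i] == ref_of[i]) next
    b <- numeric(n); b[vtx[i]] <- 1; b[ref_of[i]] <- -1
    pots[, i] <- solver(b)
  }
  R <- matrix(Inf, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (comp[i] != comp[j]) next
    x <- pots[, i] - pots[, j]
    R[i, j] <- x[vtx[i]] - x[vtx[j]]
  }
  diag(R) <- 0
  R
}
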