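# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's graph/solver code paths: the Laplacian is assembled
# densely straight from the raster, and solved by pseudoinverse.

# Dense Laplacian from a raster (mean-resistance links, sqrt(2) on
# diagonals), indexed over non-NA cells in column-major order.
oracle_dense_laplacian <- function(raster, neighborhood = "queen-8") {
  vals <- raster$values
  nr <- nrow(vals); nc <- ncol(vals)
  ok <- !is.na(vals)
  vid <- matrix(NA_integer_, nr, nc)
  vid[ok] <- seq_len(sum(ok))
  n <- sum(ok)
  L <- matrix(0, n, n)
  offs <- rbind(c(0, 1), c(1, 0))
  if (neighborhood == "queen-8") offs <- rbind(offs, c(1, 1), c(1, -1))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!ok[r, c]) next
    for (k in seq_len(nrow(offs))) {
      r2 <- r + offs[k, 1]; c2 <- c + offs[k, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || !ok[r2, c2]) next
      res <- (vals[r, c] + vals[r2, c2]) / 2
      if (offs[k, 1] != 0 && offs[k, 2] != 0) res <- res * sqrt(2)
      con <- 1 / res
      i <- vid[r, c]; j <- vid[r2, c2]
      L[i, j] <- L[i, j] - con; L[j, i] <- L[j, i] - con
      L[i, i] <- L[i, i] + con; L[j, j] <- L[j, j] + con
    }
  }
  list(L = L, vid = vid)
}

# Moore-Penrose pseudoinverse via SVD (no dependency on the solver).
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% diag(1 / s$d[keep], sum(keep)) %*%
    t(s$u[, keep, drop = FALSE])
}

# Full pairwise oracle: effective resistance and per-cell current grid.
oracle_solve <- function(raster, source, ground, neighborhood = "queen-8") {
  o <- oracle_dense_laplacian(raster, neighborhood)
  Lp <- pinv(o$L)
  vs <- o$vid[source[1], source[2]]; vg <- o$vid[ground[1], ground[2]]
  reff <- Lp[vs, vs] + Lp[vg, vg] - 2 * Lp[vs, vg]
  b <- numeric(nrow(Lp)); b[vs] <- 1; b[vg] <- -1
  v <- as.numeric(Lp %*% b)
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  vals <- raster$values
  cur <- matrix(NA_real_, nr, nc)
  offs <- rbind(c(0, 1), c(1, 0))
  if (neighborhood == "queen-8") offs <- rbind(offs, c(1, 1), c(1, -1))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(vals[r, c])) next
    tot <- 0
    for (k in seq_len(nrow(offs))) for (sgn in c(1, -1)) {
      r2 <- r + sgn * offs[k, 1]; c2 <- c + sgn * offs[k, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || is.na(vals[r2, c2])) next
      res <- (vals[r, c] + vals[r2, c2]) / 2
      if (offs[k, 1] != 0 && offs[k, 2] != 0) res <- res * sqrt(2)
      tot <- tot + abs(v[o$vid[r, c]] - v[o$vid[r2, c2]]) / res
    }
    cur[r, c] <- tot / 2
  }
  cur[source[1], source[2]] <- 1
  cur[ground[1], ground[2]] <- 1
  list(effective_resistance = reff, current = cur)
}

# Exhaustive maximum-weight spanning tree by enumerating all (n-1)-edge
# subsets; returns the maximal total weight.
oracle_max_tree_weight <- function(network) {
  e <- network$edges
  ids <- as.character(network$nodes$id)
  n <- length(ids)
  best <- -Inf
  for (sub in utils::combn(nrow(e), n - 1, simplify = FALSE)) {
    sel <- e[sub, ]
    # connectivity check by label propagation
    comp <- stats::setNames(seq_len(n), ids)
    repeat {
      changed <- FALSE
      for (k in seq_len(nrow(sel))) {
        a <- as.character(sel$node_a[k]); b <- as.character(sel$node_b[k])
        m <- min(comp[a], comp[b])
        if (comp[a] != m || comp[b] != m) {
          comp[comp == comp[a] | comp == comp[b]] <- m
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (length(unique(comp)) == 1L) best <- max(best, sum(sel$weight))
  }
  best
}

# Exhaustive shortest-path edge betweenness: enumerate all simple paths per
# node pair by DFS, keep the minimum-length ones, split counts fractionally.
oracle_edge_betweenness <- function(network, length_rule = "reciprocal-weight") {
  e <- network$edges
  ids <- as.character(network$nodes$id)
  len <- if (length_rule == "unit") rep(1, nrow(e)) else 1 / e$weight
  adj <- lapply(stats::setNames(ids, ids), function(v) {
    k <- which(as.character(e$node_a) == v | as.character(e$node_b) == v)
    data.frame(edge = k,
               to = ifelse(as.character(e$node_a[k]) == v,
                           as.character(e$node_b[k]),
                           as.character(e$node_a[k])))
  })
  bt <- numeric(nrow(e))
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    paths <- list(); lens <- numeric()
    dfs <- function(v, target, visited, edges_used, d) {
      if (v == target) {
        paths[[length(paths) + 1]] <<- edges_used
        lens[length(lens) + 1] <<- d
        return(invisible())
      }
      a <- adj[[v]]
      for (k in seq_len(nrow(a))) {
        if (a$to[k] %in% visited) next
        dfs(a$to[k], target, c(visited, a$to[k]),
            c(edges_used, a$edge[k]), d + len[a$edge[k]])
      }
    }
    dfs(ids[i], ids[j], ids[i], integer(), 0)
    if (!length(paths)) next
    short <- which(abs(lens - min(lens)) < 1e-12)
    for (s in short) bt[paths[[s]]] <- bt[paths[[s]]] + 1 / length(short)
  }
  bt
}

# Brute-force circular focal mean.
oracle_focal <- function(vals, cell_size, radius_m) {
  nr <- nrow(vals); nc <- ncol(vals)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(vals[r, c])) next
    acc <- 0; n <- 0
    for (r2 in seq_len(nr)) for (c2 in seq_len(nc)) {
      if (is.na(vals[r2, c2])) next
      if (sqrt((r - r2)^2 + (c - c2)^2) * cell_size <= radius_m) {
        acc <- acc + vals[r2, c2]; n <- n + 1
      }
    }
    out[r, c] <- if (n > 0) acc / n else NA_real_
  }
  out
}

# Small random connected network for graph-algorithm oracle tests.
random_connected_network <- function(n_nodes, seed) {
  set.seed(seed)
  repeat {
    m <- matrix(stats::runif(n_nodes^2) < 0.55, n_nodes, n_nodes)
    pairs <- which(upper.tri(m) & m, arr.ind = TRUE)
    if (nrow(pairs) < n_nodes - 1) next
    ig <- igraph::graph_from_edgelist(pairs, directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0L, n_nodes - igraph::vcount(ig)))
    if (igraph::components(ig)$no == 1L) break
  }
  genetic_network(
    data.frame(id = seq_len(n_nodes), x = stats::runif(n_nodes),
               y = stats::runif(n_nodes)),
    data.frame(node_a = pairs[, 1], node_b = pairs[, 2],
               weight = round(stats::runif(nrow(pairs), 0.1, 5), 3)))
}

# Small random raster (values >= 1, optional NA holes).
random_small_raster <- function(nr, nc, seed, p_na = 0) {
  set.seed(seed)
  vals <- matrix(stats::runif(nr * nc, 1, 50), nr, nc)
  if (p_na > 0) vals[stats::runif(nr * nc) < p_na] <- NA
  resistance_raster(vals, grid_georef(nr, nc, 1))
}
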