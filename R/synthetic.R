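#' Landscape specification for the synthetic generator
#'
#' Defaults mirror the empirical resistance-surface conventions: 1200 m
#' cells and resistance values spanning 1 (least resistance to gene flow)
#' to 161 (greatest).
#'
#' @param n_rows,n_cols grid dimensions (>= 2).
#' @param cell_size cell edge in metres.
#' @param resistance_range (low, high) positive reals, low >= 1 keeps all
#'   generated resistances >= 1.
#' @param autocorrelation_scale Gaussian smoothing scale in cells.
#' @param n_corridors number of embedded low-resistance corridors.
#' @param corridor_resistance resistance assigned to corridor cells; must
#'   not exceed the background low when corridors are requested.
#' @param seed integer seed.
#' @export
landscape_spec <- function(n_rows, n_cols, cell_size = 1200,
                           resistance_range = c(1, 161),
                           autocorrelation_scale = 5,
                           n_corridors = 0, corridor_resistance = 1,
                           seed = 1) {
  if (n_rows < 2 || n_cols < 2)
    stop("n_rows and n_cols must be >= 2", call. = FALSE)
  if (any(resistance_range <= 0) || diff(resistance_range) < 0)
    stop("resistance_range must be positive with low <= high", call. = FALSE)
  if (n_corridors > 0 && corridor_resistance > resistance_range[1])
    stop("corridor_resistance must not exceed the background low",
         call. = FALSE)
  if (corridor_resistance <= 0)
    stop("corridor_resistance must be positive", call. = FALSE)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, resistance_range = resistance_range,
                 autocorrelation_scale = autocorrelation_scale,
                 n_corridors = as.integer(n_corridors),
                 corridor_resistance = corridor_resistance,
                 seed = as.integer(seed)),
            class = "landscape_spec")
}

# Separable Gaussian smoothing with edge renormalization (kernel mass
# falling off the grid is redistributed, so edges are not damped).
gauss_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  smooth_1d <- function(m) {  # smooth down columns
    n <- nrow(m)
    out <- matrix(0, n, ncol(m)); wt <- matrix(0, n, ncol(m))
    for (o in -half:half) {
      if (1 - o > n || n - o < 1) next  # offset falls fully off the grid
      src <- max(1, 1 - o):min(n, n - o)
      w <- k[o + half + 1]
      out[src, ] <- out[src, ] + w * m[src + o, ]
      wt[src, ] <- wt[src, ] + w
    }
    out / wt
  }
  t(smooth_1d(t(smooth_1d(mat))))
}

rescale_to <- function(mat, lo, hi) {
  rng <- range(mat)
  if (diff(rng) == 0) return(matrix(lo, nrow(mat), ncol(mat)))
  lo + (mat - rng[1]) / diff(rng) * (hi - lo)
}

# 8-connected raster line between two cells (Bresenham), as a row/col matrix.
raster_line <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  err <- dc - dr
  n_max <- dr + dc + 1L
  path <- matrix(integer(), n_max, 2)
  r <- r0; c <- c0
  for (k in seq_len(n_max)) {
    path[k, ] <- c(r, c)
    if (r == r1 && c == c1) { path <- path[seq_len(k), , drop = FALSE]; break }
    e2 <- 2 * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc) { err <- err + dc; r <- r + sr }
  }
  path
}

#' Generate a spatially autocorrelated resistance raster
#'
#' White noise convolved with a Gaussian kernel, affinely rescaled to the
#' target resistance range, with optional low-resistance corridors rendered
#' as 8-connected bands between random left/right edge cells. The corridor
#' mask and endpoints are attached as attributes \code{corridor_mask} and
#' \code{corridor_endpoints}. Deterministic for a fixed spec (seed
#' included).
#'
#' @param spec a \code{landscape_spec}.
#' @return a \code{resistance_raster}.
#' @export
generate_resistance_raster <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  set.seed(spec$seed)
  noise <- matrix(stats::rnorm(spec$n_rows * spec$n_cols),
                  spec$n_rows, spec$n_cols)
  field <- gauss_smooth(noise, spec$autocorrelation_scale)
  vals <- rescale_to(field, spec$resistance_range[1], spec$resistance_range[2])
  corridor_mask <- matrix(FALSE, spec$n_rows, spec$n_cols)
  endpoints <- NULL
  if (spec$n_corridors > 0) {
    endpoints <- vector("list", spec$n_corridors)
    for (k in seq_len(spec$n_corridors)) {
      r0 <- sample.int(spec$n_rows, 1); r1 <- sample.int(spec$n_rows, 1)
      path <- raster_line(r0, 1L, r1, spec$n_cols)
      corridor_mask[path] <- TRUE
      endpoints[[k]] <- list(from = c(r0, 1L), to = c(r1, spec$n_cols))
    }
    vals[corridor_mask] <- spec$corridor_resistance
  }
  georef <- grid_georef(spec$n_rows, spec$n_cols, spec$cell_size)
  r <- resistance_raster(vals, georef)
  attr(r, "corridor_mask") <- corridor_mask
  attr(r, "corridor_endpoints") <- endpoints
  r
}

#' Sample node locations preferentially in permeable habitat
#'
#' Draws n distinct cells without replacement with sampling weight
#' proportional to the reciprocal of cell resistance (leks concentrate in
#' low-resistance habitat), snapping node coordinates to cell centres.
#'
#' @param raster a \code{resistance_raster}.
#' @param n number of nodes (>= 2).
#' @param seed integer seed.
#' @return data.frame node table: id, x, y (plus row, col helper columns).
#' @export
generate_nodes <- function(raster, n, seed = 1) {
  g <- raster$georef
  ok <- which(!g$nodata_mask)
  if (n > length(ok))
    stop(sprintf("requested %d nodes but only %d cells available", n,
                 length(ok)), call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  w <- 1 / raster$values[ok]
  pick <- sample(ok, n, replace = FALSE, prob = w)
  rc <- arrayInd(pick, dim(raster$values))
  ctr <- cell_centre(g, rc[, 1], rc[, 2])
  data.frame(id = seq_len(n), x = ctr$x, y = ctr$y,
             row = rc[, 1], col = rc[, 2])
}

#' Network specification for the synthetic generator
#'
#' @param edge_rule "gabriel" (default), "complete" or "radius".
#' @param radius_m pair radius for the "radius" rule, metres.
#' @param weight_decay decay of genetic covariance with effective
#'   resistance; weight = exp(-weight_decay * R_eff) + noise.
#' @param noise_sd standard deviation of additive Gaussian weight noise.
#' @param seed integer seed.
#' @export
network_spec <- function(edge_rule = c("gabriel", "complete", "radius"),
                         radius_m = Inf, weight_decay = 0.1, noise_sd = 0,
                         seed = 1) {
  edge_rule <- match.arg(edge_rule)
  if (weight_decay < 0 || noise_sd < 0)
    stop("weight_decay and noise_sd must be >= 0", call. = FALSE)
  structure(list(edge_rule = edge_rule, radius_m = radius_m,
                 weight_decay = weight_decay, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "network_spec")
}

gabriel_pairs <- function(x, y) {
  n <- length(x)
  out <- matrix(integer(), 0, 2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    mx <- (x[i] + x[j]) / 2; my <- (y[i] + y[j]) / 2
    r2 <- ((x[i] - x[j])^2 + (y[i] - y[j])^2) / 4
    others <- setdiff(seq_len(n), c(i, j))
    if (all((x[others] - mx)^2 + (y[others] - my)^2 > r2 - 1e-9))
      out <- rbind(out, c(i, j))
  }
  out
}

#' Generate a synthetic genetic network over a landscape
#'
#' Edge weights decay exponentially with the landscape effective resistance
#' between node cells (so network and landscape structure are mutually
#' consistent), plus optional Gaussian noise, floored at 1e-6. If the edge
#' rule leaves the network disconnected, minimal bridging edges (shortest
#' Euclidean links between components) are added.
#'
#' @param nodes node table from \code{generate_nodes} (needs row/col).
#' @param raster the \code{resistance_raster} the nodes live on.
#' @param spec a \code{network_spec}.
#' @param graph optional prebuilt \code{resistance_graph} to reuse.
#' @return a \code{genetic_network}.
#' @export
generate_network <- function(nodes, raster, spec = network_spec(),
                             graph = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  n <- nrow(nodes)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  if (is.null(graph)) graph <- build_resistance_graph(raster)
  pairs <- switch(spec$edge_rule,
    complete = t(utils::combn(n, 2)),
    gabriel = gabriel_pairs(nodes$x, nodes$y),
    radius = {
      d <- as.matrix(stats::dist(cbind(nodes$x, nodes$y)))
      w <- which(upper.tri(d) & d <= spec$radius_m, arr.ind = TRUE)
      cbind(w[, 1], w[, 2])
    })
  # bridge components until connected (deterministic: shortest link first)
  repeat {
    ig <- igraph::graph_from_edgelist(pairs, directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0L, n - igraph::vcount(ig)))
    comp <- igraph::components(ig)$membership
    if (length(unique(comp)) == 1L) break
    d <- as.matrix(stats::dist(cbind(nodes$x, nodes$y)))
    cross <- which(outer(comp, comp, "!=") & upper.tri(d), arr.ind = TRUE)
    if (!nrow(cross)) stop("cannot connect network", call. = FALSE)
    best <- cross[which.min(d[cross]), ]
    pairs <- rbind(pairs, best)
  }
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  R <- effective_resistance_matrix(graph, nodes[, c("row", "col")])
  set.seed(spec$seed)
  w <- exp(-spec$weight_decay * R[pairs]) +
    if (spec$noise_sd > 0) stats::rnorm(nrow(pairs), sd = spec$noise_sd) else 0
  w <- pmax(w, 1e-6)
  genetic_network(nodes[, c("id", "x", "y")],
                  data.frame(edge_id = seq_len(nrow(pairs)),
                             node_a = nodes$id[pairs[, 1]],
                             node_b = nodes$id[pairs[, 2]],
                             weight = w))
}

#' Generate conservation or management-zone polygons
#'
#' For \code{kind = "pac"}: circular buffers around k-means clusters of the
#' node locations, with a common buffer radius searched so the rasterized
#' polygons cover approximately the requested fraction of the grid (the
#' default 0.30 echoes conservation designs covering roughly a quarter to a
#' third of a species' range). For \code{kind = "mz"}: a partition of the
#' full grid extent into k vertical bands labelled with roman numerals.
#'
#' @param nodes node table (used for pac clustering; ignored for mz).
#' @param georef a \code{grid_georef}.
#' @param kind "pac" or "mz".
#' @param coverage target covered fraction for pac, in (0, 1).
#' @param k number of clusters (pac) or zones (mz).
#' @param seed integer seed.
#' @return a \code{polygon_set}.
#' @export
generate_polygons <- function(nodes, georef, kind = c("pac", "mz"),
                              coverage = 0.30, k = NULL, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "mz") {
    if (is.null(k)) k <- 5
    x0 <- georef$origin[1]; y1 <- georef$origin[2]
    w <- georef$n_cols * georef$cell_size
    y0 <- y1 - georef$n_rows * georef$cell_size
    cuts <- x0 + w * seq(0, 1, length.out = k + 1)
    rings <- lapply(seq_len(k), function(i)
      rbind(c(cuts[i], y0), c(cuts[i + 1], y0),
            c(cuts[i + 1], y1), c(cuts[i], y1)))
    return(polygon_set(rings, labels = as.character(utils::as.roman(1:k)),
                       kind = "mz", crs_label = georef$crs_label))
  }
  if (coverage <= 0 || coverage >= 1)
    stop("pac coverage must lie in (0, 1)", call. = FALSE)
  if (is.null(k)) k <- max(1L, min(5L, nrow(nodes) %/% 4L))
  set.seed(seed)
  centres <- if (k >= nrow(nodes)) cbind(nodes$x, nodes$y)
             else stats::kmeans(cbind(nodes$x, nodes$y), centers = k,
                                nstart = 5)$centers
  circle <- function(cx, cy, r) {
    th <- seq(0, 2 * pi, length.out = 33)[-33]
    cbind(cx + r * cos(th), cy + r * sin(th))
  }
  build <- function(radius) {
    polygon_set(lapply(seq_len(nrow(centres)), function(i)
      circle(centres[i, 1], centres[i, 2], radius)),
      labels = paste0("PAC", seq_len(nrow(centres))),
      kind = "pac", crs_label = georef$crs_label)
  }
  frac_covered <- function(radius)
    sum(rasterize_polygons(build(radius), georef)$mask) /
      sum(!georef$nodata_mask)
  extent <- max(georef$n_rows, georef$n_cols) * georef$cell_size
  lo <- georef$cell_size / 2; hi <- extent
  for (it in 1:25) {  # bisection on the common buffer radius
    mid <- (lo + hi) / 2
    if (frac_covered(mid) < coverage) lo <- mid else hi <- mid
    if (abs(frac_covered(mid) - coverage) < 0.01) break
  }
  build((lo + hi) / 2)
}

#' Generate a synthetic land-cover layer
#'
#' Cultivation: binary clustered patches obtained by thresholding an
#' autocorrelated field at the (1 - patch_density) quantile. Canopy: the
#' same field rescaled to [0, 1] and masked to its patches, giving patchy
#' fractional cover. \code{patch_density = 0} yields an all-zero layer.
#'
#' @param georef a \code{grid_georef}.
#' @param kind "cultivation" or "canopy".
#' @param patch_density expected covered fraction, in [0, 1).
#' @param scale autocorrelation scale in cells.
#' @param seed integer seed.
#' @return a \code{landcover_raster}.
#' @export
generate_landcover <- function(georef, kind = c("cultivation", "canopy"),
                               patch_density = 0.2, scale = 3, seed = 1) {
  kind <- match.arg(kind)
  if (patch_density < 0 || patch_density >= 1)
    stop("patch_density must lie in [0, 1)", call. = FALSE)
  set.seed(seed)
  field <- gauss_smooth(matrix(stats::rnorm(georef$n_rows * georef$n_cols),
                               georef$n_rows, georef$n_cols), scale)
  if (patch_density == 0) {
    vals <- matrix(0, georef$n_rows, georef$n_cols)
  } else {
    thr <- stats::quantile(field, 1 - patch_density, names = FALSE)
    patch <- field >= thr
    vals <- if (kind == "cultivation") patch + 0
            else rescale_to(field, 0, 1) * patch
  }
  landcover_raster(vals, georef, kind)
}

#' Micro-fixtures with known circuit solutions
#'
#' A named suite of tiny landscapes bundled with their expected effective
#' resistances, used throughout validation:
#' \itemize{
#'   \item \code{chain_1x3}: resistances 2, 4, 6 in a row; endpoint
#'     effective resistance 8 by the series law ((2+4)/2 + (4+6)/2).
#'   \item \code{uniform_2x2}: unit resistances under queen-8 adjacency;
#'     the side-pair effective resistance below was derived from the dense
#'     Laplacian pseudoinverse of the 4-vertex conductance graph.
#'   \item \code{two_component}: a nodata column splits the grid; expected
#'     resistance between the halves is infinite.
#'   \item \code{corridor_50x50}: high-resistance autocorrelated background
#'     with a 25-cell interior unit-resistance corridor whose endpoint cells
#'     are the terminals (no closed-form resistance; used for recovery
#'     checks). The corridor is kept to 1\% of the grid so that even the
#'     strictest delineation levels can contain it.
#' }
#'
#' @return named list; each entry holds \code{raster}, terminal cells, and
#'   any analytically known \code{expected_resistance}.
#' @export
fixture_suite <- function() {
  chain <- resistance_raster(matrix(c(2, 4, 6), 1, 3), grid_georef(1, 3, 1))
  uni <- resistance_raster(matrix(1, 2, 2), grid_georef(2, 2, 1))
  twoc_vals <- matrix(1, 3, 5); twoc_vals[, 3] <- NA
  twoc <- resistance_raster(twoc_vals, grid_georef(3, 5, 1))
  corr_spec <- landscape_spec(50, 50, cell_size = 1200,
                              resistance_range = c(50, 100),
                              autocorrelation_scale = 5, n_corridors = 0,
                              seed = 42)
  corr <- generate_resistance_raster(corr_spec)
  seg <- raster_line(25L, 13L, 25L, 37L)  # interior 25-cell corridor
  corr_mask <- matrix(FALSE, 50, 50); corr_mask[seg] <- TRUE
  vals <- corr$values; vals[corr_mask] <- 1
  corr <- resistance_raster(vals, corr$georef)
  attr(corr, "corridor_mask") <- corr_mask
  ep <- list(from = c(25L, 13L), to = c(25L, 37L))
  list(
    chain_1x3 = list(raster = chain, source = c(1L, 1L), ground = c(1L, 3L),
                     expected_resistance = 8),
    uniform_2x2 = list(raster = uni, source = c(1L, 1L), ground = c(1L, 2L),
                       # frozen from the dense pseudoinverse of the 4-vertex
                       # queen-8 conductance graph
                       expected_resistance = 0.542893218813452),
    two_component = list(raster = twoc, source = c(2L, 1L),
                         ground = c(2L, 5L), expected_resistance = Inf),
    corridor_50x50 = list(raster = corr, source = ep$from, ground = ep$to,
                          corridor_mask = attr(corr, "corridor_mask"),
                          expected_resistance = NA_real_)
  )
}
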