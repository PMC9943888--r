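test_that("resistance generator honours range, determinism and degeneracy", {
  # degenerate range collapses to a constant surface
  flat <- generate_resistance_raster(
    landscape_spec(10, 10, resistance_range = c(1, 1), n_corridors = 0))
  expect_true(all(flat$values == 1))

  spec <- landscape_spec(40, 40, resistance_range = c(1, 161),
                         autocorrelation_scale = 8, seed = 7)
  a <- generate_resistance_raster(spec)
  b <- generate_resistance_raster(spec)
  expect_identical(a$values, b$values)
  expect_gte(min(a$values), 1)
  expect_lte(max(a$values), 161)

  # smoothing leaves neighbouring cells correlated
  v <- a$values
  expect_gt(stats::cor(as.vector(v[, -1]), as.vector(v[, -ncol(v)])), 0.5)

  expect_error(landscape_spec(1, 10), ">= 2")
  expect_error(landscape_spec(10, 10, resistance_range = c(-1, 5)),
               "positive")
  expect_error(landscape_spec(10, 10, n_corridors = 1,
                              corridor_resistance = 60,
                              resistance_range = c(50, 100)),
               "background low")
})

test_that("planted corridors form one 8-connected band across the grid", {
  spec <- landscape_spec(30, 30, resistance_range = c(50, 100),
                         n_corridors = 1, corridor_resistance = 1, seed = 3)
  r <- generate_resistance_raster(spec)
  mask <- attr(r, "corridor_mask")
  expect_identical(mask, r$values == 1)
  # connected-component labelling under 8-adjacency
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j)); lab[i, j] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        qi <- p[1] + di; qj <- p[2] + dj
        if (qi < 1 || qi > nrow(mask) || qj < 1 || qj > ncol(mask)) next
        if (mask[qi, qj] && lab[qi, qj] == 0L) {
          lab[qi, qj] <- nxt
          stack[[length(stack) + 1]] <- c(qi, qj)
        }
      }
    }
  }
  expect_equal(nxt, 1L)
  ep <- attr(r, "corridor_endpoints")[[1]]
  expect_true(mask[ep$from[1], ep$from[2]] && mask[ep$to[1], ep$to[2]])
  expect_true(any(mask[, 1]) && any(mask[, ncol(mask)]))
})

test_that("node placement weights are proportional to reciprocal resistance", {
  # one highly permeable cell among hostile ones is selected almost always
  vals <- matrix(1000, 5, 5); vals[3, 3] <- 1
  ras <- resistance_raster(vals, grid_georef(5, 5, 1))
  hits <- vapply(1:400, function(s) {
    n <- generate_nodes(ras, 1, seed = s)
    n$row == 3 && n$col == 3
  }, logical(1))
  # theoretical selection probability 1000/1024 = 0.9766
  expect_gt(mean(hits), 0.93)

  # uniform raster: selection frequencies uniform within binomial tolerance
  uni <- resistance_raster(matrix(1, 4, 4), grid_georef(4, 4, 1))
  counts <- matrix(0, 4, 4)
  n_rep <- 300
  for (s in seq_len(n_rep)) {
    nd <- generate_nodes(uni, 4, seed = s)
    counts[cbind(nd$row, nd$col)] <- counts[cbind(nd$row, nd$col)] + 1
  }
  p <- 4 / 16  # 4 of 16 cells drawn per replicate
  expect_true(all(abs(counts / n_rep - p) < 4 * sqrt(p * (1 - p) / n_rep)))

  expect_error(generate_nodes(uni, 17), "available")
  nd2 <- generate_nodes(resistance_raster(matrix(1, 1, 3), grid_georef(1, 3, 1)),
                        2, seed = 1)
  expect_equal(nrow(unique(nd2[, c("row", "col")])), 2)
})

test_that("synthetic edge weights track landscape effective resistance", {
  # three collinear nodes on a uniform strip: weight decays with separation
  ras <- resistance_raster(matrix(1, 1, 9), grid_georef(1, 9, 1))
  nodes <- data.frame(id = 1:3,
                      x = c(0.5, 4.5, 8.5), y = rep(0.5, 3),
                      row = c(1, 1, 1), col = c(1, 5, 9))
  net <- generate_network(nodes, ras,
                          network_spec("complete", weight_decay = 0.5,
                                       noise_sd = 0, seed = 1))
  w <- stats::setNames(net$edges$weight,
                       paste(net$edges$node_a, net$edges$node_b))
  expect_gt(w[["1 2"]], w[["1 3"]])
  expect_gt(w[["2 3"]], w[["1 3"]])
  expect_equal(w[["1 2"]], w[["2 3"]], tolerance = 1e-10)

  # zero decay, zero noise: all weights equal 1
  net1 <- generate_network(nodes, ras,
                           network_spec("complete", weight_decay = 0,
                                        noise_sd = 0, seed = 1))
  expect_true(all(net1$edges$weight == 1))

  # determinism and connectivity across rules
  scene_r <- synthetic_scene(n_rows = 15, n_cols = 15, n_nodes = 8, seed = 9)
  net_a <- generate_network(scene_r$nodes, scene_r$raster,
                            network_spec("gabriel", noise_sd = 0.05, seed = 4),
                            graph = scene_r$graph)
  net_b <- generate_network(scene_r$nodes, scene_r$raster,
                            network_spec("gabriel", noise_sd = 0.05, seed = 4),
                            graph = scene_r$graph)
  expect_identical(net_a$edges, net_b$edges)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = net_a$edges$node_a, to = net_a$edges$node_b),
    directed = FALSE,
    vertices = data.frame(name = as.character(scene_r$nodes$id)))
  expect_equal(igraph::components(ig)$no, 1L)
})

test_that("generated polygons meet coverage and partition contracts", {
  scene <- synthetic_scene(n_rows = 30, n_cols = 30, n_nodes = 12, seed = 2)
  g <- scene$raster$georef

  pac <- generate_polygons(scene$nodes, g, "pac", coverage = 0.30, seed = 1)
  frac <- sum(rasterize_polygons(pac, g)$mask) / sum(!g$nodata_mask)
  expect_lt(abs(frac - 0.30), 0.05)
  expect_error(generate_polygons(scene$nodes, g, "pac", coverage = 1.5),
               "coverage")

  mz <- generate_polygons(scene$nodes, g, "mz", k = 3)
  zm <- rasterize_polygons(mz, g, labelled = TRUE)
  expect_true(all(zm$mask[!g$nodata_mask]))          # exhaustive
  expect_false(anyNA(zm$zone_of[!g$nodata_mask]))    # every cell labelled
  expect_setequal(unique(as.vector(zm$zone_of)), c("I", "II", "III"))

  mz1 <- generate_polygons(scene$nodes, g, "mz", k = 1)
  expect_true(all(rasterize_polygons(mz1, g)$mask))
})

test_that("land-cover generators respect value ranges and determinism", {
  g <- grid_georef(25, 25, 1200)
  expect_true(all(generate_landcover(g, "cultivation",
                                     patch_density = 0)$values == 0))
  cult <- generate_landcover(g, "cultivation", patch_density = 0.3, seed = 8)
  expect_true(all(cult$values %in% c(0, 1)))
  expect_equal(mean(cult$values), 0.3, tolerance = 0.02)
  can <- generate_landcover(g, "canopy", patch_density = 0.4, seed = 8)
  expect_gte(min(can$values), 0)
  expect_lte(max(can$values), 1)
  expect_identical(can$values,
                   generate_landcover(g, "canopy", patch_density = 0.4,
                                      seed = 8)$values)
})

test_that("fixture suite carries its analytic expectations", {
  fx <- fixture_suite()
  expect_named(fx, c("chain_1x3", "uniform_2x2", "two_component",
                     "corridor_50x50"))
  expect_equal(fx$chain_1x3$expected_resistance, 8)
  expect_identical(fx$two_component$expected_resistance, Inf)
  expect_equal(sum(is.na(fx$two_component$raster$values)), 3)
  expect_equal(sum(fx$corridor_50x50$corridor_mask), 25)
  expect_true(all(fx$corridor_50x50$raster$values[fx$corridor_50x50$corridor_mask] == 1))
})
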