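grid10 <- function() grid_georef(10, 10, 1, origin = c(0, 10))

test_that("rasterization uses cell-centre containment", {
  g <- grid10()
  # bounding box of the whole grid: every cell centre inside
  bbox <- polygon_set(list(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))),
                      crs_label = g$crs_label)
  expect_true(all(rasterize_polygons(bbox, g)$mask))

  empty <- polygon_set(list(), labels = character(), crs_label = g$crs_label)
  expect_false(any(rasterize_polygons(empty, g)$mask))

  # rectangle covering exactly the left half (edges on cell boundaries)
  half <- polygon_set(list(rbind(c(0, 0), c(5, 0), c(5, 10), c(0, 10))),
                      crs_label = g$crs_label)
  zm <- rasterize_polygons(half, g)
  expect_equal(sum(zm$mask), 50)
  expect_true(all(zm$mask[, 1:5]) && !any(zm$mask[, 6:10]))

  bad <- polygon_set(list(rbind(c(0, 0), c(5, 0), c(5, 10))),
                     crs_label = "other-crs")
  expect_error(rasterize_polygons(bad, g), "CRS")
})

test_that("connectivity proportions behave at the extremes and midpoint", {
  g <- grid10()
  m <- cumulative_map(matrix(1, 10, 10), g)
  all_zone <- zone_mask(matrix(TRUE, 10, 10), g)
  none <- zone_mask(matrix(FALSE, 10, 10), g)
  half <- zone_mask(col(matrix(0, 10, 10)) <= 5, g)

  expect_equal(connectivity_within(m, all_zone)$proportion, 1)
  expect_equal(connectivity_within(m, none)$proportion, 0)
  expect_equal(connectivity_within(m, half)$proportion, 0.5)
  expect_equal(connectivity_within(m, half)$proportion_area, 0.5)

  zero <- cumulative_map(matrix(0, 10, 10), g)
  expect_error(connectivity_within(zero, half), "undefined")
})

test_that("decile partition conserves mass and localizes zone membership", {
  g <- grid10()
  m <- cumulative_map(matrix(1:100, 10, 10), g)

  everything <- zone_mask(matrix(TRUE, 10, 10), g)
  tab <- decile_partition(m, everything)
  expect_equal(tab$proportion_in, rep(1, 10))

  # zone holding exactly the top-valued ten cells
  top <- zone_mask(matrix(1:100, 10, 10) >= 91, g)
  tab2 <- decile_partition(m, top)
  expect_equal(tab2$proportion_in, c(rep(0, 9), 1))
  expect_true(all(abs(tab2$proportion_in + tab2$proportion_out - 1) < 1e-9))

  # random half-cover zone on a uniform map: each decile near 0.5
  set.seed(9)
  mu <- cumulative_map(matrix(1 + stats::runif(100, 0, 1e-6), 10, 10), g)
  zr <- zone_mask(matrix(stats::runif(100) < 0.5, 10, 10), g)
  tab3 <- decile_partition(mu, zr, weighted = FALSE)
  expect_true(all(abs(tab3$proportion_in - 0.5) < 0.5))  # binomial n=10/bin
  expect_equal(mean(tab3$proportion_in), 0.5, tolerance = 0.2)
})

test_that("threshold-area tables normalize to the most inclusive level", {
  g <- grid10()
  vals <- matrix(1:100, 10, 10)
  m <- cumulative_map(vals, g)
  masks <- threshold_series(m, levels = seq(50, 95, 5))
  # zone constructed so the in-zone share of cells rises with value: each
  # 5-value block from the top contributes a non-increasing in-count
  in_per_block <- c(2, 2, 3, 3, 3, 4, 4, 4, 4, 4)  # blocks 51-55 .. 96-100
  in_vals <- unlist(lapply(seq_along(in_per_block), function(b) {
    block <- (46 + 5 * b):(50 + 5 * b)  # 51-55 for b=1 ... 96-100 for b=10
    utils::head(block, in_per_block[b])
  }))
  zone <- zone_mask(matrix(vals %in% in_vals, 10, 10), g)
  tab <- threshold_area_table(masks, zone)
  expect_equal(tab$factor_vs_base[1], 1)
  expect_true(all(diff(tab$factor_vs_base) >= -1e-12))
  expect_true(all(is.finite(tab$ratio_in_out)))
  expect_equal(tab$area_in_km2 + tab$area_out_km2, tab$area_total_km2)
  # areas reconcile exactly with the masks they came from
  expect_equal(tab$area_total_km2,
               vapply(masks, `[[`, numeric(1), "area_km2"))

  all_zone <- zone_mask(matrix(TRUE, 10, 10), g)
  tab_inf <- threshold_area_table(masks, all_zone)
  expect_true(all(is.infinite(tab_inf$ratio_in_out)))
})

test_that("pathway overlap is a straight cell percentage", {
  g <- grid10()
  mask <- matrix(FALSE, 10, 10); mask[1, 1:10] <- TRUE
  pw <- structure(list(edge_id = 1, georef = g, rank = 1, levels = 99,
                       masks = list(p99 = mask)), class = "pathway_mask")
  inside6 <- matrix(FALSE, 10, 10); inside6[1, 1:6] <- TRUE
  expect_equal(unname(pathway_overlap(pw, zone_mask(inside6, g))["p99"]), 60)
  expect_equal(unname(pathway_overlap(pw, zone_mask(matrix(TRUE, 10, 10), g))), 100)
  expect_equal(unname(pathway_overlap(pw, zone_mask(matrix(FALSE, 10, 10), g))), 0)
  pw$masks$p99[] <- FALSE
  expect_error(pathway_overlap(pw, zone_mask(inside6, g)), "undefined")
})

test_that("random-placement baseline is unbiased, sensitive and reproducible", {
  g <- grid_georef(30, 30, 1, origin = c(0, 30))
  sq <- polygon_set(list(rbind(c(2, 2), c(10, 2), c(10, 10), c(2, 10))),
                    kind = "pac", crs_label = g$crs_label)

  # uniform map: observed/expected ratio ~ 1
  mu <- cumulative_map(matrix(1, 30, 30), g)
  bu <- bootstrap_random_overlap(mu, sq, n_reps = 50, seed = 3)
  expect_equal(bu$ratio, 1, tolerance = 1e-9)

  # zone drawn over a high-connectivity patch: ratio clearly > 1
  vals <- matrix(0.01, 30, 30)
  vals[rasterize_polygons(sq, g)$mask] <- 5
  mh <- cumulative_map(vals, g)
  bh <- bootstrap_random_overlap(mh, sq, n_reps = 200, seed = 4)
  q95 <- stats::quantile(bh$replicates, 0.95)
  expect_gt(bh$observed, q95)
  expect_gt(bh$ratio, 1)

  # seed-for-seed determinism
  b1 <- bootstrap_random_overlap(mh, sq, n_reps = 30, seed = 11)
  b2 <- bootstrap_random_overlap(mh, sq, n_reps = 30, seed = 11)
  expect_identical(b1$replicates, b2$replicates)

  big <- polygon_set(list(rbind(c(-5, -5), c(40, -5), c(40, 40), c(-5, 40))),
                     crs_label = g$crs_label)
  expect_error(bootstrap_random_overlap(mu, big, n_reps = 2, seed = 1),
               "too large")
})

test_that("GeoJSON polygon round-trip preserves geometry and labels", {
  ps <- polygon_set(list(rbind(c(0, 0), c(4, 0), c(4, 3), c(0, 3)),
                         rbind(c(5, 5), c(8, 5), c(6, 9))),
                    labels = c("A", "B"), kind = "pac")
  p <- tempfile(fileext = ".geojson")
  write_geojson(ps, p)
  back <- read_geojson(p)
  expect_equal(back$labels, c("A", "B"))
  expect_equal(back$kind, "pac")
  expect_equal(back$rings[[1]], ps$rings[[1]])
  expect_equal(ring_area(back$rings[[2]]), ring_area(ps$rings[[2]]))
})
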