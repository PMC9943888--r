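test_that("focal fractions match brute-force window enumeration", {
  g <- grid_georef(20, 20, 1200)
  set.seed(5)
  vals <- matrix(as.numeric(stats::runif(400) < 0.3), 20, 20)
  layer <- landcover_raster(vals, g, "cultivation")
  got <- focal_fraction(layer, 6440)
  expect_equal(got$values, oracle_focal(vals, 1200, 6440), tolerance = 1e-12)

  # bounds and trivial inputs
  ones <- landcover_raster(matrix(1, 20, 20), g, "cultivation")
  expect_true(all(focal_fraction(ones, 6440)$values == 1))
  zeros <- landcover_raster(matrix(0, 20, 20), g, "cultivation")
  expect_true(all(focal_fraction(zeros, 6440)$values == 0))

  # single 1-cell: focal value equals 1 / window size, everywhere in range
  single <- matrix(0, 20, 20); single[10, 10] <- 1
  fs <- focal_fraction(landcover_raster(single, g, "cultivation"), 6440)
  expect_equal(fs$values, oracle_focal(single, 1200, 6440), tolerance = 1e-12)
  n_window <- sum(sqrt(outer((-5:5)^2, (-5:5)^2, "+")) * 1200 <= 6440)
  expect_equal(fs$values[10, 10], 1 / n_window)

  expect_error(focal_fraction(ones, 100), "cell size")
})

test_that("focal windows truncate over nodata instead of diluting", {
  g <- grid_georef(10, 10, 1200)
  vals <- matrix(1, 10, 10); vals[, 6:10] <- NA
  fr <- focal_fraction(landcover_raster(vals, g, "canopy"), 6440)
  expect_true(all(fr$values[, 1:5] == 1))
  expect_true(all(is.na(fr$values[, 6:10])))
})

test_that("resampling aggregates by block mean or nearest centre", {
  src <- grid_georef(4, 4, 600, origin = c(0, 2400))
  tgt <- grid_georef(2, 2, 1200, origin = c(0, 2400))

  # identity on an already-matching grid
  same <- landcover_raster(matrix(stats::runif(4), 2, 2), tgt, "canopy")
  expect_equal(resample_to_grid(same, tgt)$values, same$values)

  blk <- matrix(0, 4, 4); blk[1:2, 3:4] <- 1  # one target cell all ones
  lay <- landcover_raster(blk, src, "cultivation")
  out <- resample_to_grid(lay, tgt, "mean")
  expect_equal(out$values, rbind(c(0, 1), c(0, 0)))

  checker <- matrix(rep(c(0, 1), 8), 4, 4)
  checker <- (row(checker) + col(checker)) %% 2
  out2 <- resample_to_grid(landcover_raster(checker, src, "cultivation"),
                           tgt, "mean")
  expect_true(all(out2$values == 0.5))

  out3 <- resample_to_grid(lay, tgt, "nearest")
  expect_true(all(out3$values %in% c(0, 1)))

  bad <- landcover_raster(matrix(0, 4, 4),
                          grid_georef(4, 4, 600, crs_label = "other"), "cultivation")
  expect_error(resample_to_grid(bad, tgt), "CRS")
})

test_that("exceedance masks follow per-zone rules with strict inequality", {
  g <- grid_georef(6, 6, 1200)
  mk_zone <- function(cols) zone_mask(matrix(col(matrix(0, 6, 6)) %in% cols,
                                             6, 6), g)
  mz <- list(I = mk_zone(1:2), II = mk_zone(3:4), IV = mk_zone(5),
             V = mk_zone(6))
  rules <- impedance_rules("default")

  # uniform 0.30 cultivation: above 0.25 everywhere a rule exists
  f30 <- conn_raster(matrix(0.30, 6, 6), g)
  exc <- exceedance_mask(f30, mz, rules, "cultivation")
  expect_true(all(exc$mask))

  # exactly at the threshold: strict > excludes
  f25 <- conn_raster(matrix(0.25, 6, 6), g)
  expect_false(any(exceedance_mask(f25, mz, rules, "cultivation")$mask))

  # canopy rules exist only for MZs I, II, IV: zone V stays clear
  f15 <- conn_raster(matrix(0.15, 6, 6), g)
  exc_c <- exceedance_mask(f15, mz, rules, "canopy")
  expect_true(all(exc_c$mask[, 1:5]))
  expect_false(any(exc_c$mask[, 6]))

  # the alternative rule set lowers the MZ V cultivation threshold
  f10 <- conn_raster(matrix(0.10, 6, 6), g)
  expect_false(any(exceedance_mask(f10, mz, rules, "cultivation")$mask))
  exc_alt <- exceedance_mask(f10, mz, impedance_rules("mzV5"), "cultivation")
  expect_true(all(exc_alt$mask[, 6]))
  expect_false(any(exc_alt$mask[, 1:5]))

  # lowering a threshold is monotone: no flagged cell disappears
  lower <- rules; lower$threshold <- lower$threshold / 2
  exc_lo <- exceedance_mask(f15, mz, lower, "canopy")
  expect_true(all(exc_lo$mask >= exc_c$mask))

  overlap <- list(I = mk_zone(1:3), II = mk_zone(3:4))
  expect_error(exceedance_mask(f30, overlap, rules, "cultivation"), "overlap")
  expect_error(exceedance_mask(f30, mz[1:2], rules, "cultivation"), "unknown")
})

test_that("action-map summaries classify every cell consistently", {
  g <- grid_georef(10, 10, 1200)
  m <- matrix(FALSE, 10, 10)
  exc <- zone_mask({z <- m; z[1:5, ] <- TRUE; z}, g)
  top <- structure(list(georef = g, mask = {z <- m; z[3:8, ] <- TRUE; z},
                        percentile_level = 95, threshold_value = 0,
                        area_km2 = 60 * 1.44), class = "threshold_mask")
  pac <- zone_mask({z <- m; z[, 1:4] <- TRUE; z}, g)

  tab <- action_map_summary(exc, top, pac)
  # brute-force cell classification
  for (k in seq_len(nrow(tab))) {
    sel <- top$mask &
      (if (tab$class[k] == "above") exc$mask else !exc$mask) &
      (if (tab$location[k] == "in_pac") pac$mask else !pac$mask)
    expect_equal(tab$area_km2[k], sum(sel) * 1.44)
  }
  expect_equal(tab$area_ha, tab$area_km2 * 100)
  # partition conservation: the four classes tile the top mask
  expect_equal(sum(tab$area_km2), sum(top$mask) * 1.44)

  # degenerate identical masks: 100 cells at 1200 m = 144 km2 in-PAC
  all100 <- zone_mask(matrix(TRUE, 10, 10), g)
  top100 <- structure(list(georef = g, mask = matrix(TRUE, 10, 10),
                           percentile_level = 95, threshold_value = 0,
                           area_km2 = 144), class = "threshold_mask")
  tab2 <- action_map_summary(all100, top100, all100)
  expect_equal(tab2$area_km2[tab2$class == "above" &
                               tab2$location == "in_pac"], 144)

  none <- zone_mask(matrix(FALSE, 10, 10), g)
  tab3 <- action_map_summary(none, top, pac)
  expect_equal(sum(tab3$area_km2[tab3$class == "above"]), 0)

  am <- action_map(exc, top)
  expect_setequal(unique(as.vector(am$values)), c(0, 1, 2))
  expect_equal(sum(am$values == 2), sum(exc$mask & top$mask))
})
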