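#' Rasterize a polygon set onto the analysis grid
#'
#' A cell belongs to the zone when its centre lies inside (or on the
#' boundary of) any polygon of the set — the cell-centre containment rule.
#' The polygon CRS tag must match the grid's; no silent reprojection.
#'
#' @param polygons a \code{polygon_set}.
#' @param georef a \code{grid_georef}.
#' @param labelled return a per-cell label matrix instead of a single
#'   membership mask (later polygons win on overlap).
#' @return an object of class \code{zone_mask}: georef, logical \code{mask},
#'   \code{label} (set label), and for \code{labelled = TRUE} a character
#'   matrix \code{zone_of}.
#' @export
rasterize_polygons <- function(polygons, georef, labelled = FALSE) {
  if (!identical(polygons$crs_label, georef$crs_label))
    stop(sprintf("polygon CRS '%s' does not match grid CRS '%s'",
                 polygons$crs_label, georef$crs_label), call. = FALSE)
  cells <- expand.grid(row = seq_len(georef$n_rows),
                       col = seq_len(georef$n_cols))
  ctr <- cell_centre(georef, cells$row, cells$col)
  mask <- matrix(FALSE, georef$n_rows, georef$n_cols)
  zone_of <- if (labelled) matrix(NA_character_, georef$n_rows, georef$n_cols)
  for (i in seq_along(polygons$rings)) {
    ring <- polygons$rings[[i]]
    # bounding-box prefilter
    inbb <- ctr$x >= min(ring[, 1]) & ctr$x <= max(ring[, 1]) &
      ctr$y >= min(ring[, 2]) & ctr$y <= max(ring[, 2])
    if (!any(inbb)) next
    hit <- which(inbb)
    inside <- point_in_ring(ctr$x[hit], ctr$y[hit], ring)
    idx <- cbind(cells$row[hit][inside], cells$col[hit][inside])
    mask[idx] <- TRUE
    if (labelled) zone_of[idx] <- polygons$labels[i]
  }
  mask[georef$nodata_mask] <- FALSE
  if (labelled) zone_of[georef$nodata_mask] <- NA_character_
  structure(list(georef = georef, mask = mask, label = polygons$kind,
                 zone_of = zone_of),
            class = "zone_mask")
}

#' Build a zone mask directly from a logical grid
#' @param mask logical matrix.
#' @param georef a \code{grid_georef}.
#' @param label zone label.
#' @export
zone_mask <- function(mask, georef, label = "custom") {
  mask <- as.matrix(mask); storage.mode(mask) <- "logical"
  stopifnot(identical(dim(mask), c(georef$n_rows, georef$n_cols)))
  mask[georef$nodata_mask] <- FALSE
  structure(list(georef = georef, mask = mask, label = label,
                 zone_of = NULL),
            class = "zone_mask")
}

#' @export
print.zone_mask <- function(x, ...) {
  cat(sprintf("<zone_mask> %s: %d cells (%.2f km2)\n", x$label, sum(x$mask),
              sum(x$mask) * cell_area_km2(x$georef)))
  invisible(x)
}

#' Proportion of cumulative connectivity within a zone
#'
#' Value-weighted by default: the sum of cell values inside the zone over
#' the sum of all cell values ("proportion of cumulative gene flow"). The
#' area-weighted alternative (cell counts) is returned alongside.
#'
#' @param map a \code{cumulative_map}.
#' @param zone a \code{zone_mask}.
#' @return list with \code{proportion} (value-weighted) and
#'   \code{proportion_area} (cell-count-weighted).
#' @export
connectivity_within <- function(map, zone) {
  stopifnot_aligned(map$georef, zone$georef)
  ok <- !is.na(map$values)
  total <- sum(map$values[ok])
  if (total <= 0) stop("total connectivity is zero: proportion undefined",
                       call. = FALSE)
  list(proportion = sum(map$values[ok & zone$mask]) / total,
       proportion_area = sum(ok & zone$mask) / sum(ok))
}

#' Decile partition of connectivity inside/outside a zone
#'
#' Bins non-nodata cells by deciles (10% quantiles) of the cumulative value
#' and reports, per bin, the proportion of summed connectivity inside
#' versus outside the zone (or cell-count proportions with
#' \code{weighted = FALSE}).
#'
#' @param map a \code{cumulative_map}.
#' @param zone a \code{zone_mask}.
#' @param weighted value-weighted proportions (default) or area-weighted.
#' @return data.frame: decile, value_lo, value_hi, proportion_in,
#'   proportion_out.
#' @export
decile_partition <- function(map, zone, weighted = TRUE) {
  stopifnot_aligned(map$georef, zone$georef)
  ok <- !is.na(map$values)
  if (sum(ok) < 10L) stop("need >= 10 non-nodata cells", call. = FALSE)
  v <- map$values[ok]; inz <- zone$mask[ok]
  brk <- stats::quantile(v, probs = seq(0, 1, by = 0.1), type = 7, names = FALSE)
  bin <- cut(v, breaks = unique(brk), include.lowest = TRUE, labels = FALSE)
  # degenerate (tied) break points collapse bins; re-spread by rank order
  if (length(unique(brk)) < 11L)
    bin <- as.integer(cut(rank(v, ties.method = "first"),
                          breaks = seq(0, length(v), length.out = 11),
                          labels = FALSE))
  out <- lapply(1:10, function(d) {
    sel <- bin == d
    w_in <- if (weighted) sum(v[sel & inz]) else sum(sel & inz)
    w_all <- if (weighted) sum(v[sel]) else sum(sel)
    p_in <- if (w_all > 0) w_in / w_all else NA_real_
    data.frame(decile = d,
               value_lo = if (any(sel)) min(v[sel]) else NA_real_,
               value_hi = if (any(sel)) max(v[sel]) else NA_real_,
               proportion_in = p_in, proportion_out = 1 - p_in)
  })
  do.call(rbind, out)
}

#' Threshold-area table against a zone
#'
#' For each threshold mask: total area, areas inside and outside the zone,
#' the in/out ratio, and the factor of that ratio relative to the most
#' inclusive (lowest) level — an index of how strongly higher-connectivity
#' landscapes concentrate inside the zone.
#'
#' @param masks list of \code{threshold_mask} (one per level).
#' @param zone a \code{zone_mask}.
#' @return data.frame: level, area_total_km2, area_in_km2, area_out_km2,
#'   ratio_in_out, factor_vs_base.
#' @export
threshold_area_table <- function(masks, zone) {
  a_km2 <- cell_area_km2(zone$georef)
  rows <- lapply(masks, function(m) {
    stopifnot_aligned(m$georef, zone$georef)
    n_in <- sum(m$mask & zone$mask); n_out <- sum(m$mask & !zone$mask)
    data.frame(level = m$percentile_level,
               area_total_km2 = (n_in + n_out) * a_km2,
               area_in_km2 = n_in * a_km2, area_out_km2 = n_out * a_km2,
               ratio_in_out = if (n_out > 0) n_in / n_out else Inf)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$level), , drop = FALSE]
  base <- tab$ratio_in_out[1]
  tab$factor_vs_base <- if (is.finite(base) && base > 0)
    tab$ratio_in_out / base else NA_real_
  rownames(tab) <- NULL
  tab
}

#' Pathway overlap with a zone
#'
#' Percentage of pathway cells (per delineation level) falling inside the
#' zone.
#'
#' @param pathway a \code{pathway_mask}.
#' @param zone a \code{zone_mask}.
#' @return named numeric vector of percentages, one per level.
#' @export
pathway_overlap <- function(pathway, zone) {
  stopifnot_aligned(pathway$georef, zone$georef)
  vapply(pathway$masks, function(m) {
    n <- sum(m)
    if (n == 0L) stop("empty pathway mask: overlap undefined", call. = FALSE)
    100 * sum(m & zone$mask) / n
  }, numeric(1))
}

#' Equal-area random-placement baseline for zone connectivity
#'
#' Quantifies how much more connectivity the observed polygons encompass
#' than equally sized, randomly placed ones. Each replicate independently
#' translates every polygon (optionally also rotating it by a random
#' multiple of 90 degrees about its centroid) to a uniform-random position
#' whose bounding box lies fully inside the grid extent, rasterizes the
#' displaced set and recomputes the value-weighted proportion of
#' connectivity inside.
#'
#' @param map a \code{cumulative_map}.
#' @param polygons the observed \code{polygon_set}.
#' @param n_reps number of replicates.
#' @param seed integer seed (all randomness local to this call).
#' @param rotate also rotate by random right angles (default TRUE).
#' @return list: \code{observed} proportion, \code{replicates} (numeric
#'   vector), \code{expected} (replicate mean), \code{ratio}
#'   (observed/expected).
#' @export
bootstrap_random_overlap <- function(map, polygons, n_reps = 200, seed = 1,
                                     rotate = TRUE) {
  stopifnot(n_reps >= 1)
  g <- map$georef
  obs <- connectivity_within(map, rasterize_polygons(polygons, g))$proportion
  x0 <- g$origin[1]; y1 <- g$origin[2]
  x1 <- x0 + g$n_cols * g$cell_size; y0 <- y1 - g$n_rows * g$cell_size
  set.seed(seed)
  reps <- vapply(seq_len(n_reps), function(r) {
    rings <- lapply(seq_along(polygons$rings), function(i) {
      ring <- polygons$rings[[i]]
      if (rotate) {
        k <- floor(stats::runif(1) * 4)  # 0..3 quarter turns
        ctr <- colMeans(ring)
        rel <- sweep(ring, 2, ctr)
        for (q in seq_len(k)) rel <- cbind(-rel[, 2], rel[, 1])
        ring <- sweep(rel, 2, ctr, "+")
      }
      bw <- range(ring[, 1]); bh <- range(ring[, 2])
      w <- diff(bw); h <- diff(bh)
      if (w > x1 - x0 || h > y1 - y0)
        stop(sprintf("polygon '%s' is too large to place inside the grid",
                     polygons$labels[i]), call. = FALSE)
      nx <- x0 + stats::runif(1) * (x1 - x0 - w) - bw[1]
      ny <- y0 + stats::runif(1) * (y1 - y0 - h) - bh[1]
      sweep(ring, 2, c(nx, ny), "+")
    })
    ps <- polygon_set(rings, polygons$labels, kind = polygons$kind,
                      crs_label = polygons$crs_label)
    connectivity_within(map, rasterize_polygons(ps, g))$proportion
  }, numeric(1))
  list(observed = obs, replicates = reps, expected = mean(reps),
       ratio = obs / mean(reps))
}
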