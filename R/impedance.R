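#' Land-cover raster
#'
#' Either a binary cultivation layer (values in {0, 1}) or a fractional
#' woodland canopy-cover layer (values in [0, 1]).
#'
#' @param values numeric matrix; NA marks nodata.
#' @param georef a \code{grid_georef} (native resolution may differ from
#'   the analysis grid).
#' @param kind "cultivation" or "canopy".
#' @export
landcover_raster <- function(values, georef, kind = c("cultivation", "canopy")) {
  kind <- match.arg(kind)
  r <- conn_raster(values, georef, "landcover_raster")
  v <- r$values[!r$georef$nodata_mask]
  if (kind == "cultivation" && length(v) && !all(v %in% c(0, 1)))
    stop("cultivation layer must be binary", call. = FALSE)
  if (kind == "canopy" && length(v) && (any(v < 0) || any(v > 1)))
    stop("canopy fractions must lie in [0, 1]", call. = FALSE)
  r$kind <- kind
  r
}

#' Circular moving-window land-cover fraction
#'
#' Per-cell mean of the layer over a circular window: cells whose centres
#' lie within \code{radius_m} of the focal cell centre. The default 6440 m
#' radius matches the 6.44 km window used for connectivity impedance
#' screening. At raster edges and next to nodata the window is truncated
#' (mean over the available cells), which avoids biasing range-edge
#' fractions toward zero.
#'
#' @param layer a \code{landcover_raster}.
#' @param radius_m window radius in metres (>= the cell size).
#' @return a \code{landcover_raster} of kind "canopy" semantics (fractions).
#' @export
focal_fraction <- function(layer, radius_m = 6440) {
  g <- layer$georef
  if (radius_m < g$cell_size)
    stop("radius must be at least one cell size", call. = FALSE)
  r_cells <- floor(radius_m / g$cell_size)
  offs <- expand.grid(dr = -r_cells:r_cells, dc = -r_cells:r_cells)
  keep <- sqrt(offs$dr^2 + offs$dc^2) * g$cell_size <= radius_m
  offs <- offs[keep, , drop = FALSE]
  vals <- layer$values
  ok <- !is.na(vals)
  v0 <- vals; v0[!ok] <- 0
  acc <- matrix(0, g$n_rows, g$n_cols)
  cnt <- matrix(0, g$n_rows, g$n_cols)
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    sr <- max(1, 1 - dr):min(g$n_rows, g$n_rows - dr)
    sc <- max(1, 1 - dc):min(g$n_cols, g$n_cols - dc)
    tr <- sr + dr; tc <- sc + dc
    acc[sr, sc] <- acc[sr, sc] + v0[tr, tc]
    cnt[sr, sc] <- cnt[sr, sc] + ok[tr, tc]
  }
  out <- ifelse(cnt > 0, acc / cnt, NA_real_)
  out[g$nodata_mask] <- NA_real_
  res <- conn_raster(out, g, "landcover_raster")
  res$kind <- "fraction"
  res
}

#' Resample a layer onto the analysis grid
#'
#' Same-CRS resampling between aligned grids whose cell sizes differ by an
#' integer factor. Fraction layers aggregate by the mean of covered source
#' cells (default); \code{method = "nearest"} samples the source cell
#' containing each target cell centre (for categorical layers).
#'
#' @param layer a \code{landcover_raster} (or any \code{conn_raster}).
#' @param target target \code{grid_georef}.
#' @param method "mean" (default) or "nearest".
#' @export
resample_to_grid <- function(layer, target, method = c("mean", "nearest")) {
  method <- match.arg(method)
  g <- layer$georef
  if (!identical(g$crs_label, target$crs_label))
    stop("CRS mismatch between layer and target grid", call. = FALSE)
  if (same_georef(g, target)) return(conn_raster(layer$values, target,
                                                 "landcover_raster"))
  f <- target$cell_size / g$cell_size
  if (abs(f - round(f)) > 1e-9 || !isTRUE(all.equal(g$origin, target$origin)))
    stop("resampling supports integer aggregation factors on a shared origin",
         call. = FALSE)
  f <- as.integer(round(f))
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  for (i in seq_len(target$n_rows)) {
    rs <- ((i - 1) * f + 1):min(i * f, g$n_rows)
    for (j in seq_len(target$n_cols)) {
      cs <- ((j - 1) * f + 1):min(j * f, g$n_cols)
      blk <- layer$values[rs, cs]
      out[i, j] <- if (method == "mean") mean(blk, na.rm = TRUE)
                   else blk[ceiling(length(rs) / 2), ceiling(length(cs) / 2)]
    }
  }
  out[is.nan(out)] <- NA_real_
  conn_raster(out, target, "landcover_raster")
}

#' Impedance threshold rule sets
#'
#' Per-management-zone land-cover fractions beyond which functional
#' connectivity is empirically reduced. The default set applies
#' cultivation > 0.25 in MZs I, II, IV and V and canopy > 0.10 in
#' MZs I, II and IV; the \code{"mzV5"} variant lowers the MZ V cultivation
#' threshold to 0.05 (both variants circulate in the source models, so
#' neither is chosen silently — pick one explicitly for sensitivity work).
#'
#' @param variant "default" or "mzV5".
#' @return data.frame: kind, mz, threshold.
#' @export
impedance_rules <- function(variant = c("default", "mzV5")) {
  variant <- match.arg(variant)
  cult_thr <- c(I = 0.25, II = 0.25, IV = 0.25,
                V = if (variant == "mzV5") 0.05 else 0.25)
  rbind(data.frame(kind = "cultivation", mz = names(cult_thr),
                   threshold = unname(cult_thr)),
        data.frame(kind = "canopy", mz = c("I", "II", "IV"),
                   threshold = 0.10))
}

#' Threshold-exceedance mask
#'
#' A cell is flagged when its management zone carries a rule for the layer
#' kind and the focal fraction strictly exceeds that rule's threshold
#' ("greater than"); cells in zones without a rule are never flagged.
#'
#' @param fraction a fraction \code{landcover_raster} on the analysis grid.
#' @param mz_masks named list of \code{zone_mask}, one per management zone;
#'   must not overlap.
#' @param rules rule data.frame from \code{impedance_rules} (or same shape).
#' @param kind layer kind the rules apply to.
#' @return a \code{zone_mask} of exceedance cells.
#' @export
exceedance_mask <- function(fraction, mz_masks, rules, kind) {
  g <- fraction$georef
  occ <- Reduce(`+`, lapply(mz_masks, function(z) {
    stopifnot_aligned(g, z$georef); z$mask + 0
  }))
  if (any(occ > 1)) stop("management-zone masks overlap", call. = FALSE)
  rules <- rules[rules$kind == kind, , drop = FALSE]
  unknown <- setdiff(rules$mz, names(mz_masks))
  if (length(unknown))
    stop(sprintf("rules name unknown management zone(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  out <- matrix(FALSE, g$n_rows, g$n_cols)
  for (k in seq_len(nrow(rules))) {
    z <- mz_masks[[rules$mz[k]]]
    out <- out | (z$mask & !is.na(fraction$values) &
                    fraction$values > rules$threshold[k])
  }
  zone_mask(out, g, label = paste0("exceedance:", kind))
}

#' Spatial action-map summary
#'
#' Intersects threshold exceedance with the top-connectivity mask and
#' partitions the result by conservation-polygon membership, reporting
#' above- and below-threshold areas inside and outside the zone in both
#' km2 and ha.
#'
#' @param exceedance exceedance \code{zone_mask}.
#' @param top_mask a \code{threshold_mask} (e.g. the 95th percentile of
#'   cumulative connectivity).
#' @param pac conservation-area \code{zone_mask}.
#' @return data.frame: class ("above"/"below"), location ("in_pac"/
#'   "out_pac"), area_km2, area_ha.
#' @export
action_map_summary <- function(exceedance, top_mask, pac) {
  g <- exceedance$georef
  stopifnot_aligned(g, top_mask$georef); stopifnot_aligned(g, pac$georef)
  a <- cell_area_km2(g)
  top <- top_mask$mask
  combos <- expand.grid(class = c("above", "below"),
                        location = c("in_pac", "out_pac"),
                        stringsAsFactors = FALSE)
  combos$area_km2 <- mapply(function(cl, loc) {
    sel <- top & (if (cl == "above") exceedance$mask else !exceedance$mask) &
      (if (loc == "in_pac") pac$mask else !pac$mask)
    sum(sel) * a
  }, combos$class, combos$location)
  combos$area_ha <- combos$area_km2 * 100
  combos
}

#' Classified spatial action map
#'
#' Per-cell classes: 0 = outside the top-connectivity mask, 1 = top
#' connectivity below the impedance threshold, 2 = top connectivity
#' exceeding it.
#'
#' @inheritParams action_map_summary
#' @return a \code{conn_raster} of classes {0, 1, 2}.
#' @export
action_map <- function(exceedance, top_mask) {
  g <- exceedance$georef
  stopifnot_aligned(g, top_mask$georef)
  cls <- matrix(0, g$n_rows, g$n_cols)
  cls[top_mask$mask] <- 1
  cls[top_mask$mask & exceedance$mask] <- 2
  cls[g$nodata_mask] <- NA_real_
  conn_raster(cls, g, "action_map")
}
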