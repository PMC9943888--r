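#' Cumulative connectivity map
#'
#' The cell-wise sum of pairwise current maps over all network edges: the
#' surface that is thresholded, overlaid and intersected downstream.
#'
#' @param values numeric matrix of summed currents (NA = nodata).
#' @param georef a \code{grid_georef}.
#' @param n_pairs number of pairwise maps summed.
#' @export
cumulative_map <- function(values, georef, n_pairs = NA_integer_) {
  r <- conn_raster(values, georef, "cumulative_map")
  v <- r$values[!r$georef$nodata_mask]
  if (length(v) && any(v < 0)) stop("cumulative values must be >= 0", call. = FALSE)
  r$n_pairs_summed <- as.integer(n_pairs)
  r
}

#' Sum pairwise current maps
#'
#' @param solutions list of \code{pair_solution} objects sharing one
#'   georeference; infinite-resistance solutions contribute zero.
#' @return a \code{cumulative_map}.
#' @export
accumulate_currents <- function(solutions) {
  solutions <- Filter(Negate(is.null), solutions)
  if (!length(solutions)) stop("no solutions to accumulate", call. = FALSE)
  g <- solutions[[1]]$current_map$georef
  cum <- matrix(0, g$n_rows, g$n_cols)
  for (s in solutions) {
    stopifnot_aligned(g, s$current_map$georef, "current maps")
    m <- s$current_map$values
    m[is.na(m)] <- 0
    cum <- cum + m
  }
  cum[g$nodata_mask] <- NA_real_
  cumulative_map(cum, g, n_pairs = length(solutions))
}

# Linear-interpolation quantile (type 7) over non-nodata values; fixed so
# that masks are bit-reproducible.
map_quantile <- function(map, probs, include_zero = TRUE) {
  v <- map$values[!map$georef$nodata_mask]
  if (!include_zero) v <- v[v > 0]
  if (!length(v)) stop("map has no usable cells", call. = FALSE)
  stats::quantile(v, probs = probs, type = 7, names = FALSE)
}

#' Threshold a cumulative map at a percentile level
#'
#' The threshold value is the level-th percentile (linear-interpolation
#' quantile) of all non-nodata cell values; the mask keeps cells with value
#' greater than or equal to the threshold, so ties at the threshold are
#' included (the conservative, larger footprint). By default the percentile
#' base includes zero-current cells, matching whole-raster percentile
#' semantics; set \code{include_zero = FALSE} to restrict the base to cells
#' carrying current.
#'
#' @param map a \code{cumulative_map} (or any \code{conn_raster}).
#' @param level percentile in (0, 100).
#' @param include_zero include zero-valued cells in the percentile base.
#' @return an object of class \code{threshold_mask}: georef, logical
#'   \code{mask}, \code{percentile_level}, \code{threshold_value},
#'   \code{area_km2}.
#' @export
percentile_threshold <- function(map, level, include_zero = TRUE) {
  if (!is.numeric(level) || level <= 0 || level >= 100)
    stop("level must lie in (0, 100)", call. = FALSE)
  thr <- map_quantile(map, level / 100, include_zero)
  # tiny value-scaled tolerance keeps the >= rule robust to interpolation
  # round-off (e.g. the level -> 0 limit includes the minimum-valued cell)
  eps <- 1e-9 * diff(range(map$values, na.rm = TRUE))
  mask <- !is.na(map$values) & map$values >= thr - eps
  structure(list(georef = map$georef, mask = mask,
                 percentile_level = level, threshold_value = thr,
                 area_km2 = sum(mask) * cell_area_km2(map$georef)),
            class = "threshold_mask")
}

#' @export
print.threshold_mask <- function(x, ...) {
  cat(sprintf("<threshold_mask> p%g: value >= %g, %d cells (%.2f km2)\n",
              x$percentile_level, x$threshold_value, sum(x$mask), x$area_km2))
  invisible(x)
}

#' Default percentile level series: 50th to 95th by 5, plus the 99th
#' @export
default_threshold_levels <- function() c(seq(50, 95, by = 5), 99)

#' Threshold a map across a level series
#'
#' @param map a \code{cumulative_map}.
#' @param levels percentile levels (default 50..95 by 5 plus 99).
#' @param include_zero passed to \code{percentile_threshold}.
#' @return list of \code{threshold_mask}, ordered by level; areas are
#'   non-increasing with level.
#' @export
threshold_series <- function(map, levels = default_threshold_levels(),
                             include_zero = TRUE) {
  levels <- sort(levels)
  lapply(levels, function(l) percentile_threshold(map, l, include_zero))
}

#' Delineate a pathway from one edge's current map
#'
#' Thresholds a single pair's connectivity map at the given percentile
#' levels of its own value distribution, producing nested masks (higher
#' levels are subsets of lower ones). An infinite-resistance solution
#' yields empty masks with a warning.
#'
#' @param solution a \code{pair_solution}.
#' @param levels percentile levels (default 99, 99.5, 99.75).
#' @param rank optional priority rank carried from an edge ranking.
#' @return an object of class \code{pathway_mask}: edge_id, georef, rank,
#'   \code{levels}, and \code{masks} (named list of logical grids).
#' @export
delineate_pathway <- function(solution, levels = c(99, 99.5, 99.75),
                              rank = NA_integer_) {
  levels <- sort(levels)
  g <- solution$current_map$georef
  if (!is.finite(solution$effective_resistance)) {
    warning("infinite-resistance solution: empty pathway masks", call. = FALSE)
    masks <- lapply(levels, function(l) matrix(FALSE, g$n_rows, g$n_cols))
  } else {
    masks <- lapply(levels, function(l) {
      m <- percentile_threshold(solution$current_map, l)
      m$mask
    })
  }
  names(masks) <- paste0("p", levels)
  structure(list(edge_id = solution$edge_id, georef = g, rank = rank,
                 levels = levels, masks = masks),
            class = "pathway_mask")
}

#' @export
print.pathway_mask <- function(x, ...) {
  cat(sprintf("<pathway_mask> edge %s (rank %s): %s cells at p{%s}\n",
              as.character(x$edge_id), as.character(x$rank),
              paste(vapply(x$masks, sum, numeric(1)), collapse = "/"),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Write a threshold-series table as CSV
#' @param masks list of \code{threshold_mask}.
#' @param path output path.
#' @export
write_threshold_table <- function(masks, path) {
  tab <- data.frame(level = vapply(masks, `[[`, numeric(1), "percentile_level"),
                    threshold_value = vapply(masks, `[[`, numeric(1), "threshold_value"),
                    area_km2 = vapply(masks, `[[`, numeric(1), "area_km2"))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
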