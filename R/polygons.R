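#' Polygon set
#'
#' A labelled collection of simple polygons in the grid CRS. Each polygon is
#' a closed ring given as a two-column (x, y) matrix; the last vertex need
#' not repeat the first. Holes are not supported: conservation-area and
#' management-zone outlines used here are simple.
#'
#' @param rings list of two-column numeric matrices.
#' @param labels character vector, one label per ring (default P1, P2, ...).
#' @param kind polygon-set kind tag: "pac", "mz" or "custom".
#' @param crs_label CRS tag; must match the grid it is rasterized onto.
#' @return an object of class \code{polygon_set}.
#' @export
polygon_set <- function(rings, labels = NULL, kind = "custom",
                        crs_label = "local-projected") {
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2L || nrow(r) < 3L)
      stop("each ring must be a >= 3 row, 2 column matrix", call. = FALSE)
    storage.mode(r) <- "double"
    # drop an explicitly closed final vertex
    if (nrow(r) > 3L && all(r[1L, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    r
  })
  if (is.null(labels)) labels <- paste0("P", seq_along(rings))
  if (length(labels) != length(rings))
    stop("one label per ring required", call. = FALSE)
  structure(list(rings = rings, labels = as.character(labels),
                 kind = kind, crs_label = crs_label),
            class = "polygon_set")
}

#' @export
print.polygon_set <- function(x, ...) {
  cat(sprintf("<polygon_set> kind=%s, %d polygon(s): %s\n", x$kind,
              length(x$rings), paste(utils::head(x$labels, 6), collapse = ", ")))
  invisible(x)
}

#' @export
length.polygon_set <- function(x) length(x$rings)

#' Point-in-polygon test (even-odd ray casting)
#'
#' Vectorized over points; a point exactly on an edge counts as inside,
#' consistent with the conservative cell-centre rasterization rule.
#'
#' @param px,py point coordinates.
#' @param ring two-column vertex matrix (open ring).
#' @return logical vector.
#' @export
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    # edge-incidence check (collinear and within segment bbox)
    cross <- (xj - xi) * (py - yi) - (px - xi) * (yj - yi)
    on_seg <- abs(cross) < 1e-9 * (abs(xj - xi) + abs(yj - yi) + 1) &
      px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
      py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | on_seg
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Polygon ring area (shoelace formula)
#' @param ring two-column vertex matrix.
#' @export
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

# ---- GeoJSON IO ----

#' Write a polygon set as GeoJSON
#' @param polygons a \code{polygon_set}.
#' @param path output path.
#' @export
write_geojson <- function(polygons, path) {
  feats <- lapply(seq_along(polygons$rings), function(i) {
    ring <- polygons$rings[[i]]
    closed <- rbind(ring, ring[1L, ])
    list(type = "Feature",
         properties = list(label = polygons$labels[i], kind = polygons$kind),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(closed)),
                                                   function(k) closed[k, ]))))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a polygon set from GeoJSON
#' @param path file path.
#' @param crs_label CRS tag to attach.
#' @return a \code{polygon_set} (outer rings only).
#' @export
read_geojson <- function(path, crs_label = "local-projected") {
  fc <- jsonlite::read_json(path)
  rings <- list(); labels <- character(); kind <- "custom"
  for (f in fc$features) {
    coords <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    rings[[length(rings) + 1L]] <- m
    labels <- c(labels, if (!is.null(f$properties$label)) f$properties$label
                        else paste0("P", length(rings)))
    if (!is.null(f$properties$kind)) kind <- f$properties$kind
  }
  polygon_set(rings, labels, kind = kind, crs_label = crs_label)
}
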