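#' Grid georeference
#'
#' Describes the analysis grid: dimensions, square cell size, origin of the
#' upper-left corner in a projected CRS, and an optional nodata mask.
#' Row 1 is the northernmost row; cell area is \code{cell_size^2}
#' (a 1200 m grid gives 1.44 km2 per cell).
#'
#' @param n_rows,n_cols grid dimensions (positive integers).
#' @param cell_size cell edge length in metres.
#' @param origin numeric length-2, (x, y) of the upper-left grid corner.
#' @param crs_label free-text tag for the projected CRS (e.g. an Albers
#'   Equal Area Conic label); never interpreted, only carried through IO.
#' @param nodata_mask logical matrix of dim (n_rows, n_cols); TRUE marks
#'   cells outside the modelled extent. Default: all cells valid.
#' @return an object of class \code{grid_georef}.
#' @export
grid_georef <- function(n_rows, n_cols, cell_size = 1200,
                        origin = c(0, n_rows * cell_size),
                        crs_label = "local-projected",
                        nodata_mask = NULL) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("grid dimensions must be positive integers", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive number", call. = FALSE)
  if (is.null(nodata_mask)) {
    nodata_mask <- matrix(FALSE, n_rows, n_cols)
  } else {
    nodata_mask <- as.matrix(nodata_mask)
    if (!identical(dim(nodata_mask), c(n_rows, n_cols)))
      stop("nodata_mask dimensions do not match the grid", call. = FALSE)
    storage.mode(nodata_mask) <- "logical"
  }
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin), crs_label = crs_label,
                 nodata_mask = nodata_mask),
            class = "grid_georef")
}

#' @export
print.grid_georef <- function(x, ...) {
  cat(sprintf("<grid_georef> %d x %d cells @ %g m (%s), %d nodata\n",
              x$n_rows, x$n_cols, x$cell_size, x$crs_label,
              sum(x$nodata_mask)))
  invisible(x)
}

#' @rdname grid_georef
#' @param x object to test
#' @export
is_grid_georef <- function(x) inherits(x, "grid_georef")

same_georef <- function(a, b) {
  identical(c(a$n_rows, a$n_cols), c(b$n_rows, b$n_cols)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stopifnot_aligned <- function(a, b, what = "grids") {
  if (!same_georef(a, b))
    stop(sprintf("%s are not aligned (dimensions, cell size or origin differ)",
                 what), call. = FALSE)
  invisible(TRUE)
}

#' Cell-centre coordinates
#'
#' @param georef a \code{grid_georef}.
#' @param row,col cell indices (vectorized).
#' @return data.frame with columns x, y.
#' @export
cell_centre <- function(georef, row, col) {
  data.frame(x = georef$origin[1] + (col - 0.5) * georef$cell_size,
             y = georef$origin[2] - (row - 0.5) * georef$cell_size)
}

#' Snap projected coordinates to cell indices
#'
#' Points exactly on a cell boundary resolve toward the lower row index,
#' then the lower column index; points outside the grid extent error.
#'
#' @param georef a \code{grid_georef}.
#' @param x,y projected coordinates (vectorized).
#' @return data.frame with integer columns row, col.
#' @export
snap_to_cell <- function(georef, x, y) {
  fx <- (x - georef$origin[1]) / georef$cell_size
  fy <- (georef$origin[2] - y) / georef$cell_size
  col <- as.integer(ceiling(fx)); col[fx <= 0] <- 1L
  row <- as.integer(ceiling(fy)); row[fy <= 0] <- 1L
  bad <- fx < 0 | fy < 0 | fx > georef$n_cols | fy > georef$n_rows
  if (any(bad))
    stop(sprintf("%d point(s) fall outside the grid extent", sum(bad)),
         call. = FALSE)
  data.frame(row = row, col = col)
}

#' Cell area in square kilometres
#' @param georef a \code{grid_georef}.
#' @export
cell_area_km2 <- function(georef) (georef$cell_size / 1000)^2

new_raster <- function(values, georef, class) {
  values <- as.matrix(values)
  if (!identical(dim(values), c(georef$n_rows, georef$n_cols)))
    stop("value matrix dimensions do not match the georeference",
         call. = FALSE)
  storage.mode(values) <- "double"
  values[georef$nodata_mask] <- NA_real_
  structure(list(georef = georef, values = values),
            class = c(class, "conn_raster"))
}

#' Landscape resistance raster
#'
#' Per-cell positive resistance to gene flow. All non-nodata values must be
#' finite and strictly positive (the empirical convention runs from 1, least
#' resistance, upward).
#'
#' @param values numeric matrix (n_rows x n_cols); NA marks nodata and is
#'   merged into the georeference mask.
#' @param georef a \code{grid_georef}.
#' @return an object of class \code{resistance_raster}.
#' @export
resistance_raster <- function(values, georef) {
  values <- as.matrix(values)
  georef$nodata_mask <- georef$nodata_mask | is.na(values)
  r <- new_raster(values, georef, "resistance_raster")
  v <- r$values[!r$georef$nodata_mask]
  if (length(v) && (any(!is.finite(v)) || any(v <= 0)))
    stop("resistance values must be finite and > 0", call. = FALSE)
  r
}

#' Generic raster layer (land cover, currents, cumulative connectivity)
#' @inheritParams resistance_raster
#' @param class extra S3 class prepended to \code{conn_raster}.
#' @export
conn_raster <- function(values, georef, class = character()) {
  values <- as.matrix(values)
  georef$nodata_mask <- georef$nodata_mask | is.na(values)
  new_raster(values, georef, class)
}

#' @export
print.conn_raster <- function(x, ...) {
  v <- x$values[!x$georef$nodata_mask]
  cat(sprintf("<%s> %d x %d @ %g m; range [%g, %g]\n", class(x)[1],
              x$georef$n_rows, x$georef$n_cols, x$georef$cell_size,
              suppressWarnings(min(v)), suppressWarnings(max(v))))
  invisible(x)
}

# ---- ESRI ASCII grid IO (plain-text raster interchange) ----

#' Write a raster as an ESRI ASCII grid
#'
#' @param raster a \code{conn_raster} (or subclass).
#' @param path output file path.
#' @param nodata_value value written for nodata cells (default -9999).
#' @export
write_ascii_grid <- function(raster, path, nodata_value = -9999) {
  g <- raster$georef
  vals <- raster$values
  vals[is.na(vals)] <- nodata_value
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.10g", g$origin[1]),
           sprintf("yllcorner %.10g", g$origin[2] - g$n_rows * g$cell_size),
           sprintf("cellsize %.10g", g$cell_size),
           sprintf("NODATA_value %.10g", nodata_value))
  body <- apply(vals, 1L, function(r) paste(format(r, digits = 15,
                                                   trim = TRUE,
                                                   scientific = FALSE),
                                            collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param crs_label CRS tag to attach (the format itself carries none).
#' @return a \code{conn_raster}.
#' @export
read_ascii_grid <- function(path, crs_label = "local-projected") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  n_rows <- as.integer(hdr$nrows); n_cols <- as.integer(hdr$ncols)
  vals <- matrix(scan(text = paste(lines[i:length(lines)], collapse = "\n"),
                      quiet = TRUE),
                 nrow = n_rows, ncol = n_cols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA_real_
  georef <- grid_georef(n_rows, n_cols, hdr$cellsize,
                        origin = c(hdr$xllcorner,
                                   hdr$yllcorner + n_rows * hdr$cellsize),
                        crs_label = crs_label)
  conn_raster(vals, georef)
}
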