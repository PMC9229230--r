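#' Georeferenced raster grid
#'
#' A minimal single-band raster container: a numeric matrix of cell values
#' plus a square cell size and the map coordinate of the north-west corner.
#' Row 1 is the northernmost row; cells are half-open intervals
#' `[x0, x0 + cell_size)` in x and `(y0 - cell_size, y0]` going south in y,
#' so every map point belongs to exactly one cell.
#'
#' @param values numeric matrix (row 1 = north).
#' @param cell_size cell edge length in meters, > 0.
#' @param origin length-2 numeric, map (x, y) of the north-west corner.
#' @param nodata value marking missing cells (default -9999).
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size, origin, nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    stop_invalid("cell_size must be a single positive number")
  }
  if (length(origin) != 2) stop_invalid("origin must be (x, y)")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.numeric(nodata)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  e <- grid_extent(x)
  cat(sprintf("raster_grid: %d rows x %d cols, cell %g m\n",
              nrow(x$values), ncol(x$values), x$cell_size))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n", e[1], e[3], e[2], e[4]))
  v <- x$values[x$values != x$nodata & is.finite(x$values)]
  if (length(v)) cat(sprintf("  values: [%g, %g]\n", min(v), max(v)))
  invisible(x)
}

#' Map extent of a raster grid
#'
#' @param g a `raster_grid`.
#' @return `c(xmin, ymin, xmax, ymax)`.
#' @export
grid_extent <- function(g) {
  c(xmin = g$origin[1], ymin = g$origin[2] - nrow(g$values) * g$cell_size,
    xmax = g$origin[1] + ncol(g$values) * g$cell_size, ymax = g$origin[2])
}

#' Cell-center coordinates
#'
#' @param g a `raster_grid`.
#' @return list with `x` (length ncol) and `y` (length nrow) center vectors.
#' @export
cell_centers <- function(g) {
  list(x = g$origin[1] + (seq_len(ncol(g$values)) - 0.5) * g$cell_size,
       y = g$origin[2] - (seq_len(nrow(g$values)) - 0.5) * g$cell_size)
}

#' Row/column indices of map points (half-open cells)
#'
#' Points outside the grid get NA indices.
#' @param g a `raster_grid`.
#' @param x,y map coordinates.
#' @return data.frame with columns `row`, `col`.
#' @export
cell_index <- function(g, x, y) {
  col <- floor((x - g$origin[1]) / g$cell_size) + 1L
  row <- floor((g$origin[2] - y) / g$cell_size) + 1L
  # points exactly on the north/west origin edges belong to the first cell
  row[g$origin[2] - y == 0] <- 1L
  bad <- col < 1L | col > ncol(g$values) | row < 1L | row > nrow(g$values)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

grid_compatible <- function(a, b) {
  isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin)) &&
    all(dim(a$values) == dim(b$values))
}

#' Bilinear sampling of a raster at arbitrary map points
#'
#' Values are interpolated between cell centers; points beyond the outer
#' center ring are clamped to the edge. Nodata cells poison the interpolation
#' (result NA).
#'
#' @param g a `raster_grid`.
#' @param x,y map coordinates.
#' @return numeric vector of interpolated values.
#' @export
sample_bilinear <- function(g, x, y) {
  cc <- cell_centers(g)
  nx <- length(cc$x); ny <- length(cc$y)
  fx <- (x - cc$x[1]) / g$cell_size
  fy <- (cc$y[1] - y) / g$cell_size
  j0 <- pmin(pmax(floor(fx), 0), nx - 2); i0 <- pmin(pmax(floor(fy), 0), ny - 2)
  tx <- pmin(pmax(fx - j0, 0), 1); ty <- pmin(pmax(fy - i0, 0), 1)
  v <- g$values
  v[v == g$nodata] <- NA_real_
  idx <- function(i, j) v[cbind(i + 1L, j + 1L)]
  (1 - tx) * (1 - ty) * idx(i0, j0) + tx * (1 - ty) * idx(i0, j0 + 1L) +
    (1 - tx) * ty * idx(i0 + 1L, j0) + tx * ty * idx(i0 + 1L, j0 + 1L)
}

#' Resample a raster onto the grid of another (bilinear)
#'
#' @param src source `raster_grid`.
#' @param target `raster_grid` defining the output geometry.
#' @return a `raster_grid` on the target geometry.
#' @export
resample_to <- function(src, target) {
  cc <- cell_centers(target)
  xy <- expand.grid(y = cc$y, x = cc$x) # column-major to match matrix layout
  v <- sample_bilinear(src, xy$x, xy$y)
  m <- matrix(v, nrow = nrow(target$values), ncol = ncol(target$values))
  m[is.na(m)] <- target$nodata
  raster_grid(m, target$cell_size, target$origin, target$nodata)
}

#' Write a raster grid as an ESRI ASCII grid (.asc)
#'
#' Plain-text format: six header lines (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by rows north to south.
#'
#' @param g a `raster_grid`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(g, path) {
  e <- grid_extent(g)
  hdr <- c(
    sprintf("ncols %d", ncol(g$values)),
    sprintf("nrows %d", nrow(g$values)),
    sprintf("xllcorner %.10g", e["xmin"]),
    sprintf("yllcorner %.10g", e["ymin"]),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %.10g", g$nodata))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(g$values, digits = 9, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid (.asc)
#'
#' @param path file path.
#' @return a `raster_grid`.
#' @export
read_ascii_grid <- function(path) {
  hdr_lines <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr_lines), "\\s+")
  hdr <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]), 0),
                         tolower(vapply(kv, `[`, "", 1)))
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == hdr["nrows"], ncol(m) == hdr["ncols"])
  origin <- c(hdr[["xllcorner"]], hdr[["yllcorner"]] + hdr[["nrows"]] * hdr[["cellsize"]])
  raster_grid(m, hdr[["cellsize"]], origin, hdr[["nodata_value"]])
}
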