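#' Lightweight single-band georeferenced raster
#'
#' A `grid_raster` stores one band of gridded values on a regular planar
#' grid: a numeric matrix (row 1 = northernmost row, following the usual
#' raster convention) plus origin, cell size and a nodata value. Cells are
#' half-open intervals `[x0, x0 + res)` in x and `(y0 - res, y0]` read
#' top-down in y, so a point on a shared edge belongs to exactly one cell.
#'
#' @param values numeric matrix, row 1 = top (maximum y).
#' @param xmin,ymin coordinates of the lower-left corner of the grid (m).
#' @param cellsize cell edge length in metres (> 0).
#' @param nodata value used to mark missing cells (default `NA_real_`).
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, xmin = 0, ymin = 0, cellsize = 25,
                        nodata = NA_real_) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1 || ncol(values) < 1)
    stop("grid_raster: grid dimensions must be positive")
  if (cellsize <= 0) stop("grid_raster: cellsize must be > 0")
  structure(
    list(values = values, xmin = xmin, ymin = ymin,
         cellsize = cellsize, nodata = nodata),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("grid_raster: %d rows x %d cols, cell %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xmin, x$ymin))
  if (length(v))
    cat(sprintf("  values: min %.4g, max %.4g, NA cells %d\n",
                min(v), max(v), sum(!is.finite(x$values))))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Raster extent
#' @param r a `grid_raster`.
#' @return Named vector `c(xmin, xmax, ymin, ymax)`.
#' @export
raster_extent <- function(r) {
  c(xmin = r$xmin,
    xmax = r$xmin + ncol(r$values) * r$cellsize,
    ymin = r$ymin,
    ymax = r$ymin + nrow(r$values) * r$cellsize)
}

#' Do two rasters share the same grid geometry?
#' @param a,b `grid_raster` objects.
#' @param tol tolerance on origin/cell size comparison (m).
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

stopifnot_same_grid <- function(a, b, what = "rasters") {
  if (!same_grid(a, b)) stop(what, " are not co-registered")
}

#' Row/column of the cell containing a point
#'
#' Uses the half-open cell convention: cell columns span `[x0, x0 + res)`
#' and rows are counted top-down with the top row spanning `(ymax - res,
#' ymax]`; a point on a shared vertical edge falls in the cell to its east,
#' a point on a shared horizontal edge in the cell to its south.
#'
#' @param r a `grid_raster`.
#' @param x,y numeric vectors of planar coordinates (m).
#' @return data.frame with columns `row`, `col` (`NA` where outside).
#' @export
cell_index <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((x - r$xmin) / r$cellsize) + 1L
  ymax <- r$ymin + nr * r$cellsize
  # top-down rows; y on an edge belongs to the cell below it except at ymax
  row <- floor((ymax - y) / r$cellsize) + 1L
  row[y == ymax] <- 1L
  bad <- col < 1L | col > nc | row < 1L | row > nr | !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Sample raster values at point locations
#'
#' Nearest-cell (containing-cell) lookup under the half-open convention.
#'
#' @inheritParams cell_index
#' @param strict error (rather than return `NA`) for out-of-coverage points.
#' @return numeric vector of cell values (`NA` for nodata cells).
#' @export
raster_sample <- function(r, x, y, strict = FALSE) {
  idx <- cell_index(r, x, y)
  if (strict && anyNA(idx$row))
    stop("point(s) outside raster coverage")
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- r$values[cbind(idx$row[ok], idx$col[ok])]
  if (!is.na(r$nodata)) out[ok][out[ok] == r$nodata] <- NA_real_
  out
}

#' Centre coordinates of every cell
#' @param r a `grid_raster`.
#' @return list with matrices `x` and `y` shaped like the raster.
#' @export
cell_centres <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  xs <- r$xmin + (seq_len(nc) - 0.5) * r$cellsize
  ymax <- r$ymin + nr * r$cellsize
  ys <- ymax - (seq_len(nr) - 0.5) * r$cellsize
  list(x = matrix(xs, nr, nc, byrow = TRUE),
       y = matrix(ys, nr, nc))
}

#' Apply a function cellwise, preserving geometry
#' @param r a `grid_raster`.
#' @param f vectorised function of the value matrix.
#' @export
raster_map <- function(r, f) {
  grid_raster(f(r$values), r$xmin, r$ymin, r$cellsize, r$nodata)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by standard GIS software; one
#' header block (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value)
#' followed by rows of values, top row first.
#'
#' @param r a `grid_raster`.
#' @param path output file path (conventionally `.asc`).
#' @param digits significant digits written.
#' @export
write_ascii_grid <- function(r, path, digits = 10) {
  v <- r$values
  nodata <- -9999
  v[!is.finite(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", r$cellsize),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(v, 1, function(row)
    paste(formatC(row, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path file written by [write_ascii_grid()] or any GIS.
#' @return a `grid_raster` with nodata cells set to `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z_]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  grid_raster(m, xmin = hdr$xllcorner, ymin = hdr$yllcorner,
              cellsize = hdr$cellsize)
}
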