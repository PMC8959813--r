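#' Lightweight planar raster
#'
#' Internal container used for digital terrain models (DTM), canopy height
#' models (CHM) and crown segment label maps. Values are stored in a matrix
#' whose rows index x and columns index y; `origin` is the lower-left corner
#' of cell `[1, 1]` and cells are half-open intervals
#' `[x0 + (i-1) cell, x0 + i cell)` so every point belongs to exactly one
#' cell.
#'
#' @param values numeric or integer matrix, rows = x, columns = y.
#' @param origin numeric length-2, xy of the lower-left raster corner (m).
#' @param cell cell size (m), single positive number.
#' @return An object of class `ca_raster`.
#' @export
ca_raster <- function(values, origin, cell) {
  stopifnot(is.matrix(values), length(origin) == 2, is.finite(origin),
            length(cell) == 1, is.finite(cell), cell > 0)
  structure(
    list(values = values, origin = as.numeric(origin), cell = as.numeric(cell)),
    class = "ca_raster"
  )
}

#' @export
print.ca_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<ca_raster> %d x %d cells, cell %.3g m, origin (%.2f, %.2f)\n",
              nrow(v), ncol(v), x$cell, x$origin[1], x$origin[2]))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat(sprintf("  values: [%.3f, %.3f], %d NA\n", rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' @export
dim.ca_raster <- function(x) dim(x$values)

# cell index of xy coordinates (half-open convention); 0 when off-raster
raster_cell_index <- function(r, x, y) {
  ix <- floor((x - r$origin[1]) / r$cell) + 1L
  iy <- floor((y - r$origin[2]) / r$cell) + 1L
  d <- dim(r$values)
  bad <- ix < 1L | ix > d[1] | iy < 1L | iy > d[2]
  ix[bad] <- NA_integer_
  iy[bad] <- NA_integer_
  cbind(ix, iy)
}

raster_cell_centers <- function(r) {
  d <- dim(r$values)
  list(x = r$origin[1] + (seq_len(d[1]) - 0.5) * r$cell,
       y = r$origin[2] + (seq_len(d[2]) - 0.5) * r$cell)
}

# bilinear interpolation at (x, y) between cell centers; nearest-neighbour
# beyond the outermost centers (raster edge), NA off the raster entirely
raster_bilinear <- function(r, x, y) {
  d <- dim(r$values)
  x0 <- r$origin[1]; y0 <- r$origin[2]; cs <- r$cell
  off <- x < x0 | x > x0 + d[1] * cs | y < y0 | y > y0 + d[2] * cs
  # continuous index in center coordinates, clamped to the center lattice
  gx <- pmin(pmax((x - x0) / cs - 0.5, 0), d[1] - 1)
  gy <- pmin(pmax((y - y0) / cs - 0.5, 0), d[2] - 1)
  i0 <- pmin(floor(gx), d[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(gy), d[2] - 2); j0 <- pmax(j0, 0)
  if (d[1] == 1) i0 <- rep(0, length(x))
  if (d[2] == 1) j0 <- rep(0, length(y))
  fx <- gx - i0; fy <- gy - j0
  v <- r$values
  i1 <- pmin(i0 + 1, d[1] - 1); j1 <- pmin(j0 + 1, d[2] - 1)
  v00 <- v[cbind(i0 + 1, j0 + 1)]
  v10 <- v[cbind(i1 + 1, j0 + 1)]
  v01 <- v[cbind(i0 + 1, j1 + 1)]
  v11 <- v[cbind(i1 + 1, j1 + 1)]
  out <- v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
  out[off] <- NA_real_
  out
}

# 3x3 moving-window filter ignoring NAs; fn over the 9 shifted layers
filter3x3 <- function(m, stat = c("median", "mean"), na_keep = TRUE) {
  stat <- match.arg(stat)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(NA_real_, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  layers <- matrix(NA_real_, nr * nc, 9)
  k <- 0
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1
    layers[, k] <- as.vector(pad[(2 + dx):(nr + 1 + dx), (2 + dy):(nc + 1 + dy)])
  }
  out <- if (stat == "median") apply(layers, 1, median, na.rm = TRUE)
  else rowMeans(layers, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out <- matrix(out, nr, nc)
  if (na_keep) out[is.na(m)] <- NA_real_  # filter does not invent cells
  out
}

#' Convert a raster to a tibble of cell centers
#'
#' @param x a [ca_raster].
#' @param ... unused.
#' @return Tibble with columns `x`, `y`, `value`.
#' @export
as_tibble.ca_raster <- function(x, ...) {
  ctr <- raster_cell_centers(x)
  tibble::tibble(
    x = rep(ctr$x, times = length(ctr$y)),
    y = rep(ctr$y, each = length(ctr$x)),
    value = as.vector(x$values)
  )
}

#' Export a raster as an ESRI ASCII grid
#'
#' @param r a [ca_raster].
#' @param path output file path.
#' @param nodata value written for NA cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", nrow(v)),       # rows index x
    sprintf("nrows %d", ncol(v)),
    sprintf("xllcorner %.6f", r$origin[1]),
    sprintf("yllcorner %.6f", r$origin[2]),
    sprintf("cellsize %.6f", r$cell),
    sprintf("NODATA_value %g", nodata)
  )
  # ASCII grids run north to south: highest y row first
  rows <- vapply(rev(seq_len(ncol(v))), function(j)
    paste(format(v[, j], trim = TRUE), collapse = " "), character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
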