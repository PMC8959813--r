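#' Rasterize a canopy height model
#'
#' Each cell takes the maximum normalized point height of its points
#' (half-open cells, see [ca_raster()]); empty cells are nodata. A single
#' 3x3 median filter pass (on populated cells only) suppresses within-crown
#' pits; disable it with `pit_filter = FALSE` to inspect raw cell maxima.
#' Cells below `min_height` are masked to nodata so understorey and ground
#' artifacts never seed a crown.
#'
#' @param pc normalized point-cloud tibble.
#' @param cell CHM resolution (m); 0.2 m resolves individual conifer crowns.
#' @param min_height canopy mask threshold (m above ground).
#' @param pit_filter apply the single median-filter pass?
#' @return A [ca_raster] of canopy heights.
#' @export
rasterize_chm <- function(pc, cell = 0.2, min_height = 2, pit_filter = TRUE) {
  check_point_cloud(pc, require_points = TRUE)
  x0 <- min(pc$x); y0 <- min(pc$y)
  nx <- max(1L, ceiling((max(pc$x) - x0) / cell + 1e-9))
  ny <- max(1L, ceiling((max(pc$y) - y0) / cell + 1e-9))
  ix <- pmin(nx, floor((pc$x - x0) / cell) + 1L)
  iy <- pmin(ny, floor((pc$y - y0) / cell) + 1L)
  cid <- ix + (iy - 1L) * nx
  o <- order(cid, pc$z)
  last <- !duplicated(cid[o], fromLast = TRUE)   # max z per cell
  vals <- matrix(NA_real_, nx, ny)
  vals[cid[o][last]] <- pc$z[o][last]
  if (pit_filter) vals <- filter3x3(vals, "median", na_keep = TRUE)
  vals[!is.na(vals) & vals < min_height] <- NA_real_
  ca_raster(vals, c(x0, y0), cell)
}

#' Default variable-window radius function
#'
#' Search radius (m) as a function of canopy height (m):
#' `max(0.5, 0.04 h)`, a conservative window for dense boreal conifer
#' canopies (2 m window diameter at 25 m tree height).
#'
#' @param h canopy height (m).
#' @return Window radius (m).
#' @export
vwf_radius <- function(h) pmax(0.5, 0.04 * h)

#' Detect treetops with a variable window filter
#'
#' A cell is a treetop iff its height is at least `min_height` and it is the
#' maximum within a circular window whose radius is `window_radius_fn`
#' evaluated at the cell's height. Among equal-height cells in one window
#' the first in row-major order (lower row, then lower column) is kept, so
#' plateau tops yield exactly one treetop.
#'
#' @param chm canopy height model from [rasterize_chm()].
#' @param window_radius_fn function mapping height (m) to window radius (m);
#'   must return positive radii.
#' @param min_height minimum treetop height (m).
#' @return Tibble of treetops: `id`, `x`, `y`, `height`, `row`, `col`.
#' @export
detect_treetops <- function(chm, window_radius_fn = vwf_radius,
                            min_height = 2) {
  v <- chm$values
  d <- dim(v)
  cand <- which(!is.na(v) & v >= min_height, arr.ind = TRUE)
  out <- matrix(numeric(0), 0, 3)
  if (nrow(cand) > 0) {
    radii <- window_radius_fn(v[cand])
    if (any(!is.finite(radii) | radii <= 0))
      stop("window_radius_fn returned a non-positive radius", call. = FALSE)
    keep <- logical(nrow(cand))
    rcell <- radii / chm$cell
    for (i in seq_len(nrow(cand))) {
      r0 <- cand[i, 1]; c0 <- cand[i, 2]; h0 <- v[r0, c0]
      w <- ceiling(rcell[i])
      rows <- max(1, r0 - w):min(d[1], r0 + w)
      cols <- max(1, c0 - w):min(d[2], c0 + w)
      sub <- v[rows, cols, drop = FALSE]
      dx <- outer(rows - r0, rep(1, length(cols)))
      dy <- outer(rep(1, length(rows)), cols - c0)
      inwin <- (dx^2 + dy^2) <= rcell[i]^2
      vals <- sub[inwin]
      if (any(vals > h0, na.rm = TRUE)) next
      # tie rule: first cell in row-major order wins
      ties <- which(inwin & !is.na(sub) & sub == h0, arr.ind = TRUE)
      trow <- rows[ties[, 1]]; tcol <- cols[ties[, 2]]
      ord <- order(trow, tcol)   # lower row first, then lower column
      if (trow[ord[1]] == r0 && tcol[ord[1]] == c0) keep[i] <- TRUE
    }
    cand <- cand[keep, , drop = FALSE]
    out <- cand
  }
  ctr <- raster_cell_centers(chm)
  tibble::tibble(
    id = seq_len(nrow(out)),
    x = ctr$x[out[, 1]],
    y = ctr$y[out[, 2]],
    height = v[out],
    row = as.integer(out[, 1]),
    col = as.integer(out[, 2])
  )
}

#' Delineate crown segments by marker-controlled watershed
#'
#' Floods the inverted CHM from the treetop markers (Meyer priority-flood,
#' 8-connected); cells below `min_height` or without canopy stay unlabeled.
#' Every labeled region is connected to its marker by construction.
#'
#' @param chm canopy height model.
#' @param treetops treetop tibble from [detect_treetops()].
#' @param min_height canopy mask threshold (m).
#' @return A `crown_segments` object: list with `labels` (integer
#'   [ca_raster]) and `treetops`.
#' @export
watershed_crowns <- function(chm, treetops, min_height = 2) {
  if (nrow(treetops) == 0)
    stop("watershed segmentation needs at least one treetop", call. = FALSE)
  v <- chm$values
  d <- dim(v)
  if (any(treetops$row < 1 | treetops$row > d[1] |
            treetops$col < 1 | treetops$col > d[2]))
    stop("treetop outside the CHM raster", call. = FALSE)
  mask <- !is.na(v) & v >= min_height
  relief <- max(v, na.rm = TRUE) - v
  relief[!mask] <- Inf
  markers <- matrix(0L, d[1], d[2])
  markers[cbind(treetops$row, treetops$col)] <- treetops$id
  labels <- watershed_flood_cpp(relief, markers, mask)
  structure(list(labels = ca_raster(labels, chm$origin, chm$cell),
                 treetops = treetops),
            class = "crown_segments")
}

#' @export
print.crown_segments <- function(x, ...) {
  cat(sprintf("<crown_segments> %d segments on a %d x %d grid (cell %.2g m)\n",
              nrow(x$treetops), nrow(x$labels$values), ncol(x$labels$values),
              x$labels$cell))
  invisible(x)
}

#' Assign points to crown segments
#'
#' Raster point-in-polygon: each point inherits the segment label of the
#' cell containing its xy position (half-open cell intervals). Points over
#' unlabeled cells, or outside the raster, go to the unassigned bucket
#' `tree = 0`. The assignment is an exhaustive, disjoint partition.
#'
#' @param pc normalized point-cloud tibble.
#' @param segments `crown_segments` from [watershed_crowns()].
#' @return `pc` with an integer `tree` column.
#' @export
assign_points <- function(pc, segments) {
  check_point_cloud(pc)
  lab <- segments$labels
  idx <- raster_cell_index(lab, pc$x, pc$y)
  tree <- rep(0L, nrow(pc))
  ok <- !is.na(idx[, 1])
  tree[ok] <- lab$values[idx[ok, , drop = FALSE]]
  pc[["tree"]] <- as.integer(tree)
  pc
}
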