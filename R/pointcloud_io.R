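#' Point clouds as tibbles
#'
#' A point cloud is an ordinary tibble with numeric columns `x`, `y`, `z`
#' (metres, projected planar coordinates) and two optional integer columns:
#' `label`, the per-point class using LAS-style codes (`2` ground, `3` crown,
#' `4` stem, `0` unclassified), and `tree`, the tree id (`0` = unassigned).
#' Every pipeline stage takes such a tibble first and returns one, so stages
#' chain with the pipe.
#'
#' @param x,y,z numeric coordinate vectors of equal length (m).
#' @param label optional integer class codes.
#' @param tree optional integer tree ids.
#' @return A tibble with the supplied columns.
#' @export
point_cloud <- function(x = numeric(), y = numeric(), z = numeric(),
                        label = NULL, tree = NULL) {
  pc <- tibble::tibble(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (!is.null(label)) pc$label <- as.integer(label)
  if (!is.null(tree)) pc$tree <- as.integer(tree)
  check_point_cloud(pc)
  pc
}

check_point_cloud <- function(pc, require_points = FALSE) {
  if (!is.data.frame(pc) || !all(c("x", "y", "z") %in% names(pc)))
    stop("a point cloud needs numeric columns x, y, z", call. = FALSE)
  if (nrow(pc) > 0 &&
      !all(is.finite(pc$x) & is.finite(pc$y) & is.finite(pc$z)))
    stop("point cloud contains non-finite coordinates", call. = FALSE)
  if (require_points && nrow(pc) == 0)
    stop("point cloud is empty", call. = FALSE)
  invisible(pc)
}

# LAS class codes used throughout
LABEL_GROUND <- 2L
LABEL_CROWN <- 3L
LABEL_STEM <- 4L

#' Read a point cloud from disk
#'
#' Supports two on-disk formats: whitespace-delimited XYZ text
#' (`x y z [label [tree]]`, `#` comments ignored) and binary LAS 1.2/1.4
#' with point record formats 0-3. The LAS classification field maps to
#' `label` and the point source id to `tree`.
#'
#' @param path input file.
#' @param format `"las"`, `"xyz"`, or `"auto"` (by file extension).
#' @return A point-cloud tibble (see [point_cloud()]).
#' @export
read_point_cloud <- function(path, format = c("auto", "xyz", "las")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.la[sz]$", path, ignore.case = TRUE)) "las" else "xyz"
  }
  switch(format, xyz = read_xyz(path), las = read_las(path))
}

#' Write a point cloud to disk
#'
#' @param pc point-cloud tibble.
#' @param path output file.
#' @param format `"las"`, `"xyz"`, or `"auto"` (by file extension).
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(pc, path, format = c("auto", "xyz", "las")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.la[sz]$", path, ignore.case = TRUE)) "las" else "xyz"
  }
  switch(format, xyz = write_xyz(pc, path), las = write_las(pc, path))
}

read_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) return(point_cloud())
  parts <- strsplit(trimws(lines[rows]), "\\s+")
  nfld <- lengths(parts)
  if (any(nfld < 3)) {
    bad <- rows[which(nfld < 3)[1]]
    stop(sprintf("malformed XYZ record at line %d of %s: fewer than 3 columns",
                 bad, path), call. = FALSE)
  }
  ncol_use <- min(5L, min(nfld))
  m <- matrix(as.numeric(vapply(parts, function(p) p[seq_len(ncol_use)],
                                character(ncol_use))),
              ncol = ncol_use, byrow = TRUE)
  if (anyNA(m[, 1:3])) {
    bad <- rows[which(rowSums(is.na(m[, 1:3, drop = FALSE])) > 0)[1]]
    stop(sprintf("malformed XYZ record at line %d of %s: non-numeric value",
                 bad, path), call. = FALSE)
  }
  point_cloud(m[, 1], m[, 2], m[, 3],
              label = if (ncol_use >= 4) as.integer(m[, 4]) else NULL,
              tree = if (ncol_use >= 5) as.integer(m[, 5]) else NULL)
}

write_xyz <- function(pc, path, digits = 4) {
  check_point_cloud(pc)
  cols <- list(formatC(pc$x, format = "f", digits = digits),
               formatC(pc$y, format = "f", digits = digits),
               formatC(pc$z, format = "f", digits = digits))
  if (!is.null(pc[["label"]]))
    cols <- c(cols, list(as.character(pc[["label"]])))
  if (!is.null(pc[["label"]]) && !is.null(pc[["tree"]]))
    cols <- c(cols, list(as.character(pc[["tree"]])))
  writeLines(do.call(paste, cols), path)
  invisible(path)
}

# --- minimal LAS 1.2 binary reader/writer (point formats 0-3) ---------------
# No LAS library exists in the R dependency stack, so the fixed-layout binary
# format is read directly. Coordinates are stored as scaled 32-bit integers.

las_point_layout <- c(`0` = 20L, `1` = 28L, `2` = 26L, `3` = 34L)

read_las <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- rawToChar(readBin(con, "raw", 4))
  if (sig != "LASF") stop("not a LAS file (bad signature): ", path, call. = FALSE)
  hdr <- readBin(con, "raw", 96 - 4)
  ver_major <- as.integer(hdr[24 - 4 + 1])
  ver_minor <- as.integer(hdr[25 - 4 + 1])
  u16 <- function(raw, at) readBin(raw[(at + 1):(at + 2)], "integer",
                                   size = 2, signed = FALSE)
  u32 <- function(raw, at) readBin(raw[(at + 1):(at + 4)], "integer", size = 4)
  f64 <- function(raw, at) readBin(raw[(at + 1):(at + 8)], "double", size = 8)
  hdr_size <- u16(hdr, 94 - 4)
  rest <- readBin(con, "raw", hdr_size - 96)
  full <- c(charToRaw(sig), hdr, rest)
  data_offset <- u32(full, 96)
  pfmt <- as.integer(full[104 + 1])
  if (!(as.character(pfmt) %in% names(las_point_layout)))
    stop("unsupported LAS point format ", pfmt,
         " (formats 0-3 supported)", call. = FALSE)
  reclen <- u16(full, 105)
  npts <- u32(full, 107)
  if (npts == 0 && ver_major == 1 && ver_minor >= 4 && hdr_size >= 375) {
    npts <- u32(full, 247)  # legacy count zeroed; low word of 64-bit count
  }
  scale <- c(f64(full, 131), f64(full, 139), f64(full, 147))
  offs <- c(f64(full, 155), f64(full, 163), f64(full, 171))
  seek(con, data_offset)
  raw <- readBin(con, "raw", npts * reclen)
  if (length(raw) < npts * reclen)
    stop("truncated LAS point data in ", path, call. = FALSE)
  dim(raw) <- c(reclen, npts)
  geti32 <- function(at) readBin(as.vector(raw[at:(at + 3), ]), "integer",
                                 n = npts, size = 4)
  x <- geti32(1) * scale[1] + offs[1]
  y <- geti32(5) * scale[2] + offs[2]
  z <- geti32(9) * scale[3] + offs[3]
  label <- as.integer(raw[16, ])
  tree <- readBin(as.vector(raw[19:20, ]), "integer", n = npts, size = 2,
                  signed = FALSE)
  point_cloud(x, y, z, label = label, tree = tree)
}

write_las <- function(pc, path, scale = 0.001) {
  check_point_cloud(pc)
  n <- nrow(pc)
  offs <- if (n > 0) c(min(pc$x), min(pc$y), min(pc$z)) else c(0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  writeBin(charToRaw("LASF"), con)
  w(0L, 2)                                   # file source id
  w(0L, 2)                                   # global encoding
  writeBin(raw(16), con)                     # project GUID
  writeBin(as.raw(c(1, 2)), con)             # version 1.2
  writeBin(raw(32), con)                     # system identifier
  sw <- charToRaw("crownarch")
  writeBin(c(sw, raw(32 - length(sw))), con) # generating software
  w(1L, 2); w(2026L, 2)                      # day, year
  w(227L, 2)                                 # header size
  w(227L, 4)                                 # offset to point data
  w(0L, 4)                                   # number of VLRs
  writeBin(as.raw(0), con)                   # point data format 0
  w(20L, 2)                                  # record length
  w(n, 4)                                    # number of points
  for (i in 1:5) w(if (i == 1) n else 0L, 4) # points by return
  writeBin(rep(scale, 3), con)
  writeBin(offs, con)
  rng <- function(v) if (n > 0) c(max(v), min(v)) else c(0, 0)
  writeBin(c(rng(pc$x), rng(pc$y), rng(pc$z)), con)
  if (n > 0) {
    label <- if (is.null(pc[["label"]])) integer(n) else pc[["label"]]
    tree <- if (is.null(pc[["tree"]])) integer(n)
    else pmin(pc[["tree"]], 65535L)
    enc_i32 <- function(v) {
      m <- matrix(writeBin(as.integer(round((v))), raw(), size = 4), nrow = 4)
      m
    }
    rec <- matrix(as.raw(0), nrow = 20, ncol = n)
    rec[1:4, ] <- enc_i32((pc$x - offs[1]) / scale)
    rec[5:8, ] <- enc_i32((pc$y - offs[2]) / scale)
    rec[9:12, ] <- enc_i32((pc$z - offs[3]) / scale)
    rec[15, ] <- as.raw(9L)                  # return 1 of 1
    rec[16, ] <- as.raw(pmax(0L, pmin(255L, label)))
    psid <- matrix(writeBin(as.integer(tree), raw(), size = 4), nrow = 4)
    rec[19:20, ] <- psid[1:2, ]
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}

# --- terrain model and height normalization ---------------------------------

#' Build a digital terrain model from a point cloud
#'
#' Ground candidates are the per-cell minimum heights. Outlying minima are
#' rejected with a 2.5 x IQR rule computed over the distribution of cell
#' minima: minima below `Q1 - 2.5 IQR` are spurious sub-ground returns,
#' minima above `Q3 + 2.5 IQR` come from cells that only saw canopy (no
#' ground return) — both are discarded and treated as empty. Empty cells
#' are filled from the nearest populated cell and the surface is smoothed
#' once with a 3x3 mean filter. Applying the rejection to cell minima
#' rather than within each cell keeps the rule valid under canopy, where a
#' cell's height distribution is dominated by crown returns.
#'
#' @param pc point-cloud tibble (unnormalized, all returns).
#' @param cell DTM cell size in m. 0.5 m resolves the smooth terrain the
#'   generator produces; configurable for rougher ground.
#' @return A [ca_raster] of ground elevations with attribute `filled`
#'   (logical matrix marking cells that had no usable ground return).
#' @export
build_dtm <- function(pc, cell = 0.5) {
  check_point_cloud(pc, require_points = TRUE)
  x0 <- min(pc$x); y0 <- min(pc$y)
  nx <- max(1L, ceiling((max(pc$x) - x0) / cell + 1e-9))
  ny <- max(1L, ceiling((max(pc$y) - y0) / cell + 1e-9))
  ix <- pmin(nx, floor((pc$x - x0) / cell) + 1L)
  iy <- pmin(ny, floor((pc$y - y0) / cell) + 1L)
  cid <- ix + (iy - 1L) * nx
  ground <- vapply(split(pc$z, cid), min, numeric(1))
  if (length(ground) >= 4) {
    q <- quantile(ground, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    ok <- ground >= q[1] - 2.5 * iqr & ground <= q[2] + 2.5 * iqr
    if (any(ok)) ground <- ground[ok]
  }
  vals <- matrix(NA_real_, nx, ny)
  vals[as.integer(names(ground))] <- ground
  filled <- is.na(vals)
  if (all(filled)) stop("DTM has no populated cells", call. = FALSE)
  if (any(filled)) {
    ctr_x <- x0 + (seq_len(nx) - 0.5) * cell
    ctr_y <- y0 + (seq_len(ny) - 0.5) * cell
    full_idx <- which(!filled, arr.ind = TRUE)
    na_idx <- which(filled, arr.ind = TRUE)
    nn <- FNN::get.knnx(
      cbind(ctr_x[full_idx[, 1]], ctr_y[full_idx[, 2]]),
      cbind(ctr_x[na_idx[, 1]], ctr_y[na_idx[, 2]]), k = 1)$nn.index[, 1]
    vals[filled] <- vals[!filled][nn]
  }
  vals <- filter3x3(vals, "mean", na_keep = FALSE)
  r <- ca_raster(vals, c(x0, y0), cell)
  attr(r, "filled") <- filled
  r
}

#' Normalize point heights to height above ground
#'
#' Replaces `z` by `z` minus the bilinearly interpolated DTM elevation under
#' each point (nearest-neighbour at the raster edge). Point count and xy
#' coordinates are preserved exactly.
#'
#' @param pc point-cloud tibble.
#' @param dtm [ca_raster] from [build_dtm()]; must cover the xy extent of
#'   `pc`.
#' @return The point cloud with normalized `z`.
#' @export
normalize_heights <- function(pc, dtm) {
  check_point_cloud(pc)
  if (nrow(pc) == 0) return(pc)
  g <- raster_bilinear(dtm, pc$x, pc$y)
  n_out <- sum(is.na(g))
  if (n_out > 0)
    stop(sprintf("%d point(s) fall outside the DTM extent", n_out),
         call. = FALSE)
  dplyr::mutate(pc, z = .data$z - g)
}
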