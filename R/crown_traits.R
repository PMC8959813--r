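#' Crown projection area
#'
#' Area of the 2D convex hull of the crown points projected to the xy
#' plane.
#'
#' @param crown_pc crown point-cloud tibble (>= 3 non-collinear points).
#' @return Area (m^2).
#' @export
crown_projection_area <- function(crown_pc) {
  check_point_cloud(crown_pc)
  hull <- hull_2d(crown_pc$x, crown_pc$y)
  hull$area
}

#' Maximum crown diameter
#'
#' The largest pairwise xy distance, computed over the vertices of the 2D
#' convex hull (the diameter of a point set is attained at hull vertices).
#'
#' @param crown_pc crown point-cloud tibble (>= 2 points).
#' @return Diameter (m).
#' @export
max_crown_diameter <- function(crown_pc) {
  check_point_cloud(crown_pc)
  n <- nrow(crown_pc)
  if (n < 2) stop("crown diameter needs at least 2 points", call. = FALSE)
  max_pairwise_xy(crown_pc$x, crown_pc$y)
}

#' Crown volume and surface area from the 3D convex hull
#'
#' @param crown_pc crown point-cloud tibble (>= 4 non-coplanar points).
#' @return One-row tibble: `volume` (m^3), `surface_area` (m^2).
#' @export
crown_hull_3d <- function(crown_pc) {
  check_point_cloud(crown_pc)
  if (nrow(crown_pc) < 4)
    stop("3D hull needs at least 4 points", call. = FALSE)
  h <- convex_hull_3d_cpp(as.matrix(crown_pc[, c("x", "y", "z")]))
  tibble::tibble(volume = h$volume, surface_area = h$area)
}

# 2D convex hull with shoelace area; errors on degenerate input
hull_2d <- function(x, y) {
  if (length(x) < 3)
    stop("2D hull needs at least 3 points", call. = FALSE)
  idx <- grDevices::chull(x, y)
  hx <- x[idx]; hy <- y[idx]
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (length(idx) < 3 || area <= 0)
    stop("degenerate 2D hull: points are collinear", call. = FALSE)
  list(x = hx, y = hy, area = area)
}

# maximum pairwise distance; restricted to hull vertices when possible
max_pairwise_xy <- function(x, y) {
  n <- length(x)
  if (n > 3) {
    idx <- tryCatch(grDevices::chull(x, y), error = function(e) seq_len(n))
    if (length(idx) >= 2) { x <- x[idx]; y <- y[idx] }
  }
  max(stats::dist(cbind(x, y)))
}

#' Slice a crown into height percentiles
#'
#' Crown points are ordered by height and split into `n` equal-count
#' slices starting from the lowest points (the remainder when the count
#' does not divide evenly goes to the lowest slices). Per slice the 2D
#' hull diameter and area are computed as for the whole crown; degenerate
#' slices fall back to the maximum pairwise distance with zero area. The
#' representative height of a slice is the mean height of its points.
#' `method = "height"` slices into equal-height bands instead.
#'
#' @param crown_pc crown point-cloud tibble (>= 3 n points).
#' @param n number of slices (10 = height deciles).
#' @param method `"count"` (equal point counts, the default reading of
#'   height percentiles) or `"height"` (equal-height bands).
#' @return A `crown_slices` tibble: `slice`, `height`, `diameter`, `area`,
#'   `n`.
#' @export
slice_crown <- function(crown_pc, n = 10, method = c("count", "height")) {
  method <- match.arg(method)
  check_point_cloud(crown_pc)
  npts <- nrow(crown_pc)
  if (npts < 3 * n)
    stop(sprintf("crown slicing needs at least %d points (got %d)",
                 3 * n, npts), call. = FALSE)
  ord <- order(crown_pc$z)
  if (method == "count") {
    base <- npts %/% n
    rem <- npts %% n
    counts <- base + as.integer(seq_len(n) <= rem)
    slice_of <- rep(seq_len(n), counts)
  } else {
    zmin <- crown_pc$z[ord[1]]; zmax <- crown_pc$z[ord[npts]]
    edges <- seq(zmin, zmax, length.out = n + 1)
    slice_of <- findInterval(crown_pc$z[ord], edges,
                             rightmost.closed = TRUE, all.inside = TRUE)
  }
  x <- crown_pc$x[ord]; y <- crown_pc$y[ord]; z <- crown_pc$z[ord]
  out <- lapply(seq_len(n), function(s) {
    i <- which(slice_of == s)
    if (length(i) == 0)
      return(tibble::tibble(slice = s, height = NA_real_, diameter = 0,
                            area = 0, n = 0L))
    diam <- if (length(i) >= 2) max_pairwise_xy(x[i], y[i]) else 0
    area <- tryCatch(hull_2d(x[i], y[i])$area, error = function(e) 0)
    tibble::tibble(slice = s, height = mean(z[i]), diameter = diam,
                   area = area, n = length(i))
  })
  structure(dplyr::bind_rows(out),
            class = c("crown_slices", class(tibble::tibble())))
}

#' Summarise crown slices
#'
#' Mean, standard deviation (n-1 denominator), range (crown tapering) and
#' maximum of the slice diameters, plus the height of the maximum crown
#' diameter (HMC): the representative height of the widest slice. Slices
#' whose diameter is within `tie_tol` of the maximum are treated as tied
#' — a crown that is widest near a slice boundary yields two slices whose
#' diameters differ by less than any point measurement resolves — and
#' ties go to the lowest slice, making the derived crown length the
#' longest consistent with the slices.
#'
#' @param slices a `crown_slices` tibble from [slice_crown()].
#' @param tie_tol diameter tie tolerance (m).
#' @return One-row tibble: `mean_diameter`, `sd_diameter`, `tapering`,
#'   `max_diameter`, `hmc`.
#' @export
slice_summary <- function(slices, tie_tol = 0.01) {
  d <- slices$diameter
  tibble::tibble(
    mean_diameter = mean(d),
    sd_diameter = sd(d),
    tapering = max(d) - min(d),
    max_diameter = max(d),
    hmc = slices$height[which(d >= max(d) - tie_tol)[1]]
  )
}

#' Crown length and live-crown ratio
#'
#' Crown length is the distance from the height of the maximum crown
#' diameter (HMC, standing in for the crown base) to the tree top; the
#' live-crown ratio is its proportion of tree height.
#'
#' @param H tree height (m).
#' @param hmc height of the maximum crown diameter (m), `0 <= hmc < H`.
#' @return One-row tibble: `crown_length` (m), `live_crown_ratio`.
#' @export
crown_length_and_ratio <- function(H, hmc) {
  if (!is.finite(hmc) || hmc < 0 || hmc >= H)
    stop("hmc must satisfy 0 <= hmc < H", call. = FALSE)
  tibble::tibble(crown_length = H - hmc, live_crown_ratio = (H - hmc) / H)
}

#' Stem area at the height of the maximum crown diameter (SAHMC)
#'
#' The stem diameter at the HMC is read off the taper curve and converted
#' to a basal-area-style cross-section: `pi/4 d^2` with `d` in cm, giving
#' cm^2 — the pipe-model-motivated proxy for growth potential.
#'
#' @param taper a `taper_curve`.
#' @param hmc height of the maximum crown diameter (m).
#' @param H tree height (m), for taper extrapolation above the last knot.
#' @return SAHMC (cm^2) with attribute `extrapolated`.
#' @export
sahmc <- function(taper, hmc, H = NULL) {
  d <- taper_diameter(taper, hmc, H = H)
  out <- pi / 4 * (100 * as.numeric(d))^2
  attr(out, "extrapolated") <- attr(d, "extrapolated")
  out
}

#' All crown traits of one tree
#'
#' Computes the full crown trait set from a tree's crown points and its
#' taper curve: convex-hull size traits, the ten slice diameters, their
#' summary statistics, HMC, crown length, live-crown ratio, crown tapering
#' and SAHMC.
#'
#' @param crown_pc crown point-cloud tibble.
#' @param taper a `taper_curve` (for SAHMC); optional.
#' @param H tree height (m); defaults to the highest crown point.
#' @param n_slices number of crown slices.
#' @param slice_method `"count"` or `"height"`, see [slice_crown()].
#' @return One-row tibble with `projection_area`, `crown_volume`,
#'   `surface_area`, `max_crown_diameter`, `mean_crown_diameter`,
#'   `sd_crown_diameter`, `hmc`, `crown_length`, `crown_tapering`,
#'   `live_crown_ratio`, `sahmc` and slice diameters `d_p10` ... `d_p100`.
#' @export
crown_traits <- function(crown_pc, taper = NULL, H = NULL, n_slices = 10,
                         slice_method = "count") {
  check_point_cloud(crown_pc, require_points = TRUE)
  if (is.null(H)) H <- max(crown_pc$z)
  hull3 <- crown_hull_3d(crown_pc)
  slices <- slice_crown(crown_pc, n = n_slices, method = slice_method)
  smry <- slice_summary(slices)
  clr <- crown_length_and_ratio(H, smry$hmc)
  out <- tibble::tibble(
    projection_area = crown_projection_area(crown_pc),
    crown_volume = hull3$volume,
    surface_area = hull3$surface_area,
    max_crown_diameter = max_crown_diameter(crown_pc),
    mean_crown_diameter = smry$mean_diameter,
    sd_crown_diameter = smry$sd_diameter,
    hmc = smry$hmc,
    crown_length = clr$crown_length,
    crown_tapering = smry$tapering,
    live_crown_ratio = clr$live_crown_ratio,
    sahmc = if (is.null(taper)) NA_real_
    else as.numeric(sahmc(taper, smry$hmc, H = H))
  )
  for (s in seq_len(n_slices))
    out[[sprintf("d_p%d", round(100 * s / n_slices))]] <- slices$diameter[s]
  out
}

#' Crown and stem traits for every tree of a classified cloud
#'
#' Maps over the trees of a point cloud that carries `tree` ids and
#' stem/crown `label`s, computing [stem_traits()] and [crown_traits()] per
#' tree. Trees whose taper or crown geometry cannot be computed (too few
#' points, no stem found) are reported with `NA` traits and a note.
#'
#' @param pc classified, normalized point-cloud tibble with `tree` and
#'   `label` columns.
#' @param min_points minimum points per tree to attempt traits.
#' @return Tibble with one row per tree: `tree`, stem traits, crown traits,
#'   `note`.
#' @export
tree_traits <- function(pc, min_points = 100) {
  check_point_cloud(pc)
  if (is.null(pc[["tree"]]) || is.null(pc[["label"]]))
    stop("tree_traits needs `tree` and `label` columns", call. = FALSE)
  ids <- sort(setdiff(unique(pc$tree), 0L))
  rows <- lapply(ids, function(id) {
    tp <- dplyr::filter(pc, .data$tree == id)
    base <- tibble::tibble(tree = id, n_points = nrow(tp))
    if (nrow(tp) < min_points)
      return(dplyr::mutate(base, note = "too few points"))
    stem <- dplyr::filter(tp, .data$label == LABEL_STEM)
    crown <- dplyr::filter(tp, .data$label == LABEL_CROWN)
    H <- tree_height(tp)
    res <- tryCatch({
      taper <- fit_taper_curve(stem)
      st <- stem_traits(stem, tree_pc = tp)
      ct <- crown_traits(crown, taper = taper, H = H)
      dplyr::bind_cols(base, st, ct, tibble::tibble(note = NA_character_))
    }, error = function(e) {
      dplyr::mutate(base, height = H, note = conditionMessage(e))
    })
    res
  })
  dplyr::bind_rows(rows)
}
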