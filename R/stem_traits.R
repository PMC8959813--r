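#' Fit a circle to 2D points
#'
#' Taubin's algebraic fit (Newton iteration on the characteristic
#' polynomial of the scaled moment matrix) followed by one geometric
#' Gauss-Newton step minimising the orthogonal distances. Exact on
#' noise-free circles; essentially unbiased for full circles with small
#' isotropic noise.
#'
#' @param points_2d data frame or matrix with columns `x`, `y` (>= 5 rows).
#' @return One-row tibble: `center_x`, `center_y`, `diameter`, `residual`
#'   (RMS orthogonal distance, m), `n`.
#' @export
fit_circle <- function(points_2d) {
  m <- as.matrix(points_2d[, c("x", "y")])
  n <- nrow(m)
  if (n < 5) stop("circle fitting needs at least 5 points", call. = FALSE)
  mx <- mean(m[, 1]); my <- mean(m[, 2])
  u <- m[, 1] - mx; v <- m[, 2] - my
  # collinearity check on the centred second moments
  Sxx <- mean(u * u); Syy <- mean(v * v); Sxy <- mean(u * v)
  tr <- Sxx + Syy
  det2 <- Sxx * Syy - Sxy^2
  if (tr <= 0 || det2 <= 1e-12 * tr^2)
    stop("degenerate circle: points are collinear", call. = FALSE)
  z <- u * u + v * v
  Mz <- mean(z)
  Mxx <- Sxx; Myy <- Syy; Mxy <- Sxy
  Mxz <- mean(u * z); Myz <- mean(v * z); Mzz <- mean(z * z)
  Cov_xy <- Mxx * Myy - Mxy * Mxy
  Var_z <- Mzz - Mz * Mz
  A3 <- 4 * Mz
  A2 <- -3 * Mz * Mz - Mzz
  A1 <- Var_z * Mz + 4 * Cov_xy * Mz - Mxz * Mxz - Myz * Myz
  A0 <- Mxz * (Mxz * Myy - Myz * Mxy) + Myz * (Myz * Mxx - Mxz * Mxy) -
    Var_z * Cov_xy
  A22 <- A2 + A2; A33 <- 3 * A3
  xk <- 0
  yk <- 1e50
  for (iter in 1:25) {
    yold <- yk
    yk <- A0 + xk * (A1 + xk * (A2 + xk * A3))
    if (abs(yk) > abs(yold)) { xk <- 0; break }
    Dy <- A1 + xk * (A22 + xk * A33)
    xold <- xk
    xk <- xold - yk / Dy
    if (!is.finite(xk)) { xk <- 0; break }
    if (abs((xk - xold) / (abs(xk) + 1e-30)) < 1e-12) break
  }
  DET <- xk * xk - xk * Mz + Cov_xy
  if (abs(DET) < 1e-300)
    stop("degenerate circle fit", call. = FALSE)
  a <- (Mxz * (Myy - xk) - Myz * Mxy) / DET / 2
  b <- (Myz * (Mxx - xk) - Mxz * Mxy) / DET / 2
  r <- sqrt(a * a + b * b + Mz)
  # one geometric Gauss-Newton step on (a, b, r)
  di <- sqrt((u - a)^2 + (v - b)^2)
  if (all(di > 0)) {
    J <- cbind(-(u - a) / di, -(v - b) / di, rep(-1, n))
    res <- di - r
    step <- tryCatch(solve(crossprod(J), crossprod(J, -res)),
                     error = function(e) rep(0, 3))
    a <- a + step[1]; b <- b + step[2]; r <- r + step[3]
    di <- sqrt((u - a)^2 + (v - b)^2)
  }
  tibble::tibble(center_x = a + mx, center_y = b + my,
                 diameter = 2 * r,
                 residual = sqrt(mean((di - r)^2)),
                 n = n)
}

#' Reconstruct a stem taper curve
#'
#' Stem points are sliced into height bins; a circle is fitted per bin.
#' Bins are accepted when the fit residual is below `residual_max` and the
#' diameter does not exceed the previous accepted diameter by more than
#' `max_increase` (crown contamination guard). An interpolating natural
#' cubic spline through the accepted (height, diameter) knots is the taper
#' curve; knot heights are the mean point heights of the slices.
#'
#' @param stem_pc point-cloud tibble of stem points.
#' @param slice_h slice height (m).
#' @param residual_max maximum accepted RMS circle residual (m).
#' @param max_increase maximum relative diameter increase over the previous
#'   accepted slice.
#' @return A `taper_curve`: list with `knots` tibble, spline function, and
#'   valid range `h_lo`, `h_hi`.
#' @export
fit_taper_curve <- function(stem_pc, slice_h = 0.5, residual_max = 0.03,
                            max_increase = 0.10) {
  check_point_cloud(stem_pc, require_points = TRUE)
  z0 <- max(0, min(stem_pc$z))
  bins <- floor((stem_pc$z - z0) / slice_h)
  rows <- list()
  prev_d <- NULL
  for (b in sort(unique(bins))) {
    i <- which(bins == b)
    if (length(i) < 5) next
    fit <- tryCatch(fit_circle(stem_pc[i, c("x", "y")]),
                    error = function(e) NULL)
    if (is.null(fit) || fit$residual > residual_max) next
    if (!is.null(prev_d) && fit$diameter > (1 + max_increase) * prev_d) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      height = mean(stem_pc$z[i]),
      diameter = fit$diameter,
      residual = fit$residual,
      n = fit$n)
    prev_d <- fit$diameter
  }
  knots <- dplyr::bind_rows(rows)
  if (nrow(knots) < 2)
    stop("taper curve needs at least 2 accepted circle fits", call. = FALSE)
  fun <- splinefun(knots$height, knots$diameter, method = "natural")
  structure(list(knots = knots, fun = fun,
                 h_lo = min(knots$height), h_hi = max(knots$height),
                 h_top = max(stem_pc$z)),
            class = "taper_curve")
}

#' @export
print.taper_curve <- function(x, ...) {
  cat(sprintf(
    "<taper_curve> %d knots on [%.2f, %.2f] m, d(h_lo) = %.3f m\n",
    nrow(x$knots), x$h_lo, x$h_hi, x$fun(x$h_lo)))
  invisible(x)
}

#' Evaluate a taper curve
#'
#' Inside the knot range the interpolating spline is used. Below the lowest
#' knot the natural spline extrapolates linearly (flagged). Above the
#' highest knot — the part of the stem hidden inside the crown — the
#' diameter follows a power-law taper `d = c (H - h)^k` fitted to the
#' uppermost knots when the tree height `H` is supplied: the classical
#' stem-taper form, which reaches zero at the tip, is exact for conic and
#' parabolic stems and constant for cylinders. Without `H`, or when the
#' fit is degenerate, the spline's clamped linear extension is used.
#' Diameters never widen upward past the last knot and are clamped at
#' zero.
#'
#' @param taper a `taper_curve`.
#' @param h heights (m).
#' @param H total tree height (m), enabling the power-law tip model.
#' @return Diameters (m) with attribute `extrapolated` (logical vector).
#' @export
taper_diameter <- function(taper, h, H = NULL) {
  d <- taper$fun(h)
  extra <- h < taper$h_lo | h > taper$h_hi
  d_hi <- max(0, taper$fun(taper$h_hi))
  hi <- which(h > taper$h_hi)
  if (length(hi)) {
    d[hi] <- pmin(d[hi], d_hi)      # monotone: no widening above the knots
    if (!is.null(H)) {
      kn <- taper$knots
      sel <- utils::tail(order(kn$height), 8)
      hh <- kn$height[sel]
      dd <- kn$diameter[sel]
      if (H > max(hh) + 0.5 && all(dd > 0) && length(sel) >= 3) {
        # weight by inverse squared circle residual: a knot straddling the
        # crown base carries crown contamination and a visibly larger
        # residual, and should not steer the tip model
        res <- kn$residual[sel]
        w <- 1 / (res^2 + max(stats::median(res), 1e-4)^2)
        cf <- stats::lm.wfit(cbind(1, log(H - hh)), log(dd), w)$coefficients
        khat <- max(0, cf[2])
        d[hi] <- pmin(exp(cf[1]) * pmax(0, H - h[hi])^khat, d_hi)
      } else {
        top <- if (is.null(taper$h_top)) taper$h_hi else min(taper$h_top, H)
        d_top <- max(0, min(taper$fun(top), d_hi))
        far <- hi[h[hi] > top]
        if (H > top && length(far))
          d[far] <- pmin(d_top * pmax(0, (H - h[far]) / (H - top)), d_hi)
      }
    }
  }
  d <- pmax(d, 0)
  attr(d, "extrapolated") <- extra
  d
}

#' Tree height from the highest point
#'
#' @param tree_pc normalized point-cloud tibble of one tree.
#' @return Height (m) of the highest point.
#' @export
tree_height <- function(tree_pc) {
  check_point_cloud(tree_pc, require_points = TRUE)
  max(tree_pc$z)
}

#' Diameter at breast height from the taper curve
#'
#' @param taper a `taper_curve`.
#' @return DBH in cm, with attribute `extrapolated` set when 1.3 m lies
#'   outside the taper's knot range.
#' @export
dbh <- function(taper) {
  d <- taper_diameter(taper, 1.3)
  out <- 100 * as.numeric(d)
  attr(out, "extrapolated") <- attr(d, "extrapolated")
  out
}

#' Stem volume from 10-cm cylinder slices
#'
#' The stem is a stack of 10-cm vertical cylinders from the ground to the
#' tree top; each cylinder's diameter is the taper curve at the cylinder's
#' mid-height (midpoint evaluation halves the bias of end evaluation for
#' monotone tapers). Above the last taper knot the diameter falls linearly
#' to zero at the top.
#'
#' @param taper a `taper_curve`.
#' @param H tree height (m).
#' @param bin cylinder height (m).
#' @return Volume in dm^3.
#' @export
stem_volume <- function(taper, H, bin = 0.1) {
  if (!is.finite(H) || H <= 0) stop("tree height must be positive",
                                    call. = FALSE)
  edges <- seq(0, H, by = bin)
  if (tail(edges, 1) < H) edges <- c(edges, H)
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  widths <- diff(edges)
  d <- as.numeric(taper_diameter(taper, mids, H = H))
  1000 * sum(pi / 4 * d^2 * widths)
}

#' Height at a cumulative stem-volume fraction
#'
#' Smallest cylinder-top height at which the cumulative 10-cm cylinder
#' volume reaches `frac` of the total, linearly interpolated within the
#' crossing cylinder.
#'
#' @param taper a `taper_curve`.
#' @param H tree height (m).
#' @param frac volume fraction in (0, 1); 0.5 gives the median-volume
#'   height.
#' @param bin cylinder height (m).
#' @return Height (m).
#' @export
height_at_volume_fraction <- function(taper, H, frac = 0.5, bin = 0.1) {
  if (!is.finite(frac) || frac <= 0 || frac >= 1)
    stop("frac must lie strictly between 0 and 1", call. = FALSE)
  edges <- seq(0, H, by = bin)
  if (tail(edges, 1) < H) edges <- c(edges, H)
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  widths <- diff(edges)
  d <- as.numeric(taper_diameter(taper, mids, H = H))
  vol <- pi / 4 * d^2 * widths
  cum <- cumsum(vol)
  target <- frac * cum[length(cum)]
  i <- which(cum >= target)[1]
  lo <- edges[i]
  prev <- if (i > 1) cum[i - 1] else 0
  lo + widths[i] * (target - prev) / vol[i]
}

#' Height to DBH ratio
#'
#' @param H tree height (m).
#' @param dbh diameter at breast height (cm).
#' @return `H / dbh` (m per cm, the conventional slenderness measure).
#' @export
height_dbh_ratio <- function(H, dbh) {
  if (!is.finite(dbh) || dbh <= 0) stop("dbh must be positive", call. = FALSE)
  H / dbh
}

#' All stem traits of one tree
#'
#' Convenience wrapper: fits the taper curve from the stem points and
#' derives DBH, stem volume, the height at 50% cumulative volume and the
#' height/DBH ratio. Tree height comes from the full tree cloud (highest
#' point) when supplied, otherwise from the stem points.
#'
#' @param stem_pc stem point-cloud tibble.
#' @param tree_pc full tree cloud for the height (optional).
#' @param slice_h taper slice height (m).
#' @return One-row tibble: `height`, `dbh`, `stem_volume`,
#'   `height_at_half_volume`, `height_dbh_ratio`, `dbh_extrapolated`.
#' @export
stem_traits <- function(stem_pc, tree_pc = NULL, slice_h = 0.5) {
  taper <- fit_taper_curve(stem_pc, slice_h = slice_h)
  H <- tree_height(if (is.null(tree_pc)) stem_pc else tree_pc)
  d <- dbh(taper)
  tibble::tibble(
    height = H,
    dbh = as.numeric(d),
    stem_volume = stem_volume(taper, H),
    height_at_half_volume = height_at_volume_fraction(taper, H, 0.5),
    height_dbh_ratio = height_dbh_ratio(H, as.numeric(d)),
    dbh_extrapolated = isTRUE(attr(d, "extrapolated"))
  )
}
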