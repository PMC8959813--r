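#' Per-point neighbourhood geometry features
#'
#' For each point, the covariance of its `k` nearest neighbours (self
#' included) is eigen-decomposed; with eigenvalues `l1 >= l2 >= l3`, the
#' third eigenvector approximates the local surface normal. Features:
#' `verticality = 1 - |normal . up|` (1 on a vertical cylinder wall, 0 on
#' flat ground), `planarity = (l2 - l3)/l1` and `linearity = (l1 - l2)/l1`.
#' Eigenvalues of the symmetric 3x3 covariances are computed in closed form
#' so the whole cloud is vectorized.
#'
#' @param pc point-cloud tibble.
#' @param k neighbourhood size; k-NN rather than a fixed radius so the
#'   features are robust to point-density variation.
#' @return `pc` with `verticality`, `planarity`, `linearity` columns.
#' @export
point_features <- function(pc, k = 20) {
  check_point_cloud(pc, require_points = TRUE)
  X <- as.matrix(pc[, c("x", "y", "z")])
  n <- nrow(X)
  k <- min(k, n - 1)
  if (k < 2) stop("too few points for neighbourhood features", call. = FALSE)
  nn <- FNN::get.knn(X, k = k)$nn.index
  idx <- cbind(seq_len(n), nn)
  m <- ncol(idx)
  gx <- matrix(X[idx, 1], n, m)
  gy <- matrix(X[idx, 2], n, m)
  gz <- matrix(X[idx, 3], n, m)
  mx <- rowMeans(gx); my <- rowMeans(gy); mz <- rowMeans(gz)
  a11 <- rowMeans(gx * gx) - mx * mx
  a22 <- rowMeans(gy * gy) - my * my
  a33 <- rowMeans(gz * gz) - mz * mz
  a12 <- rowMeans(gx * gy) - mx * my
  a13 <- rowMeans(gx * gz) - mx * mz
  a23 <- rowMeans(gy * gz) - my * mz
  # closed-form eigenvalues of a symmetric 3x3 matrix
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  ok <- p > 0
  b11 <- (a11 - q) / p; b22 <- (a22 - q) / p; b33 <- (a33 - q) / p
  b12 <- a12 / p; b13 <- a13 / p; b23 <- a23 / p
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  # eigenvector of the smallest eigenvalue: cross product of two rows of
  # (A - l3 I); take the best-conditioned of the three row pairs
  c11 <- a11 - l3; c22 <- a22 - l3; c33 <- a33 - l3
  v1x <- a12 * a23 - a13 * c22; v1y <- a13 * a12 - c11 * a23
  v1z <- c11 * c22 - a12 * a12                       # row1 x row2
  w1x <- a12 * c33 - a13 * a23; w1y <- a13 * a13 - c11 * c33
  w1z <- c11 * a23 - a12 * a13                       # row1 x row3
  u1x <- c22 * c33 - a23 * a23; u1y <- a23 * a13 - a12 * c33
  u1z <- a12 * a23 - c22 * a13                       # row2 x row3
  n1 <- v1x^2 + v1y^2 + v1z^2
  n2 <- w1x^2 + w1y^2 + w1z^2
  n3 <- u1x^2 + u1y^2 + u1z^2
  nx <- v1x; ny <- v1y; nz <- v1z; nn2 <- n1
  pick <- n2 > nn2
  nx[pick] <- w1x[pick]; ny[pick] <- w1y[pick]; nz[pick] <- w1z[pick]
  nn2[pick] <- n2[pick]
  pick <- n3 > nn2
  nx[pick] <- u1x[pick]; ny[pick] <- u1y[pick]; nz[pick] <- u1z[pick]
  nn2[pick] <- n3[pick]
  vert <- ifelse(ok & nn2 > 0, 1 - abs(nz) / sqrt(nn2), 0)
  pc$verticality <- vert
  pc$planarity <- ifelse(ok & l1 > 0, (l2 - l3) / l1, 0)
  pc$linearity <- ifelse(ok & l1 > 0, (l1 - l2) / l1, 0)
  pc
}

#' Default stem classification parameters
#'
#' All thresholds of the iterative stem/crown separation: minimum
#' verticality of candidate points, slice height, fraction of candidates
#' that must fit the slice circle, circle inlier tolerance, maximum number
#' of consecutive rejected slices before stopping, maximum circle-centre
#' drift between accepted slices, and the feature neighbourhood size.
#'
#' @return Named list of parameters.
#' @export
stem_classify_params <- function() {
  list(verticality_min = 0.8, slice_h = 0.5, accept_frac = 0.6,
       inlier_tol = 0.03, max_reject = 3, max_drift = 0.25, k = 20,
       min_points = 200, min_circle_points = 5, basal_zone = 2)
}

#' Classify a tree's points into stem and crown
#'
#' An iterative geometric procedure working upward from the tree base:
#' (1) points whose local surface normal is near-horizontal
#' (`verticality >= 0.8`) are stem candidates; (2) candidates are sliced
#' into 0.5-m height bins and a circle is fitted per bin; a bin is accepted
#' when at least 60% of its candidates lie within 3 cm of the circle;
#' (3) each bin's circle search is seeded from the previous accepted centre
#' and may drift at most 25 cm; after 3 consecutive rejected bins the stem
#' is considered ended. Stem points are the accepted bins' circle inliers;
#' everything else is crown. If no bin in the lowest 2 m is acceptable the
#' tree is flagged and all points are returned as crown.
#'
#' @param tree_pc normalized point-cloud tibble of one tree (>= 200 points).
#' @param params parameter list, see [stem_classify_params()].
#' @return A `classified_tree`: list with `points` (input tibble with
#'   `label` set to stem/crown), `diagnostics` (per-slice tibble: height,
#'   circle fit, coverage, accepted), and `no_stem_found` flag. The
#'   stem/crown split is always an exhaustive disjoint partition of the
#'   input.
#' @export
classify_stem_points <- function(tree_pc, params = stem_classify_params()) {
  check_point_cloud(tree_pc, require_points = TRUE)
  p <- utils::modifyList(stem_classify_params(), params)
  if (nrow(tree_pc) < p$min_points)
    stop(sprintf("stem classification needs at least %d points (got %d)",
                 p$min_points, nrow(tree_pc)), call. = FALSE)
  feats <- point_features(tree_pc, k = p$k)
  cand <- which(feats$verticality >= p$verticality_min)
  z0 <- min(tree_pc$z)
  bins <- floor((tree_pc$z - z0) / p$slice_h)
  n_bins <- max(bins) + 1L
  stem_idx <- integer(0)
  diag_rows <- vector("list", n_bins)
  prev_center <- NULL
  prev_ok_bin <- -Inf
  rejects <- 0L
  for (b in seq_len(n_bins) - 1L) {
    bin_lo <- z0 + b * p$slice_h
    in_bin <- cand[bins[cand] == b]
    search <- in_bin
    if (!is.null(prev_center) && length(search) > 0) {
      dc <- sqrt((tree_pc$x[search] - prev_center[1])^2 +
                   (tree_pc$y[search] - prev_center[2])^2)
      search <- search[dc <= prev_radius + p$max_drift]
    }
    accepted <- FALSE
    fit <- NULL
    coverage <- NA_real_
    if (length(search) >= p$min_circle_points) {
      fit <- tryCatch(
        fit_circle(tree_pc[search, c("x", "y")]),
        error = function(e) NULL)
      if (!is.null(fit)) {
        dist_c <- sqrt((tree_pc$x[in_bin] - fit$center_x)^2 +
                         (tree_pc$y[in_bin] - fit$center_y)^2)
        inl <- abs(dist_c - fit$diameter / 2) <= p$inlier_tol
        coverage <- mean(inl)
        drift_ok <- is.null(prev_center) ||
          sqrt(sum((c(fit$center_x, fit$center_y) - prev_center)^2)) <=
          p$max_drift
        if (coverage >= p$accept_frac && drift_ok) {
          accepted <- TRUE
          # harvest inliers from ALL points of the slice, not only the
          # verticality candidates: every return on the accepted circle is
          # a stem return even when its neighbourhood features were diluted
          all_bin <- which(bins == b)
          dist_all <- sqrt((tree_pc$x[all_bin] - fit$center_x)^2 +
                             (tree_pc$y[all_bin] - fit$center_y)^2)
          stem_idx <- c(stem_idx,
                        all_bin[abs(dist_all - fit$diameter / 2) <=
                                  p$inlier_tol])
          prev_center <- c(fit$center_x, fit$center_y)
          prev_radius <- fit$diameter / 2
          prev_ok_bin <- b
          rejects <- 0L
        }
      }
    }
    if (!accepted && is.finite(prev_ok_bin)) {
      rejects <- rejects + 1L
      if (rejects >= p$max_reject) {
        diag_rows[[b + 1L]] <- slice_diag(bin_lo, p, fit, coverage, FALSE,
                                          length(in_bin))
        break
      }
    }
    if (!accepted && !is.finite(prev_ok_bin) && bin_lo + p$slice_h > z0 +
          p$basal_zone && b > 0) {
      # beyond the basal zone with no accepted slice: no stem
      diag_rows[[b + 1L]] <- slice_diag(bin_lo, p, fit, coverage, FALSE,
                                        length(in_bin))
      break
    }
    diag_rows[[b + 1L]] <- slice_diag(bin_lo, p, fit, coverage, accepted,
                                      length(in_bin))
  }
  no_stem <- !is.finite(prev_ok_bin)
  label <- rep(LABEL_CROWN, nrow(tree_pc))
  if (!no_stem) label[stem_idx] <- LABEL_STEM
  out <- tree_pc
  out$label <- as.integer(label)
  structure(list(points = out,
                 diagnostics = dplyr::bind_rows(diag_rows),
                 no_stem_found = no_stem),
            class = "classified_tree")
}

slice_diag <- function(bin_lo, p, fit, coverage, accepted, n_candidates) {
  tibble::tibble(
    height = bin_lo + p$slice_h / 2,
    n_candidates = n_candidates,
    diameter = if (is.null(fit)) NA_real_ else fit$diameter,
    residual = if (is.null(fit)) NA_real_ else fit$residual,
    coverage = coverage,
    accepted = accepted
  )
}

#' @export
print.classified_tree <- function(x, ...) {
  n <- nrow(x$points)
  ns <- sum(x$points$label == LABEL_STEM)
  cat(sprintf("<classified_tree> %d points: %d stem, %d crown%s\n",
              n, ns, n - ns,
              if (x$no_stem_found) " [no stem found]" else ""))
  invisible(x)
}
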