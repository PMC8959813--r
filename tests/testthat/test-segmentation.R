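test_that("CHM rasterization takes per-cell maxima on half-open cells", {
  pc <- point_cloud(0.1, 0.1, 17)
  chm <- rasterize_chm(pc, cell = 0.2)
  expect_identical(dim(chm$values), c(1L, 1L))
  expect_equal(chm$values[1, 1], 17)

  # two points in one cell: the higher wins; a third lands one cell over
  pc2 <- point_cloud(c(0.05, 0.15, 0.25), c(0.05, 0.05, 0.05), c(5, 9, 7))
  chm2 <- rasterize_chm(pc2, cell = 0.2, pit_filter = FALSE)
  expect_equal(chm2$values[1, 1], 9)
  expect_equal(chm2$values[2, 1], 7)
})

test_that("the CHM top of a synthetic tree is within 10 cm of true height", {
  tr <- reference_tree(height = 20, crown_density = 800)
  chm <- rasterize_chm(tr$cloud, pit_filter = FALSE)
  expect_lt(abs(max(chm$values, na.rm = TRUE) - 20), 0.1)
})

test_that("clouds entirely below the canopy mask give an all-nodata CHM", {
  set.seed(10)
  pc <- point_cloud(runif(500, 0, 10), runif(500, 0, 10),
                    runif(500, 0, 1.5))
  chm <- rasterize_chm(pc, min_height = 2)
  expect_true(all(is.na(chm$values)))
  expect_identical(nrow(detect_treetops(chm)), 0L)
})

test_that("VWF finds a single tree's apex and matches brute force", {
  tr <- reference_tree(height = 20, crown_density = 600, seed = 9)
  chm <- rasterize_chm(tr$cloud)
  tops <- detect_treetops(chm)
  expect_identical(nrow(tops), 1L)
  expect_lt(sqrt(tops$x^2 + tops$y^2), 0.3)  # model apex at the origin

  oracle <- vwf_brute_force(chm, vwf_radius, min_height = 2)
  expect_identical(cbind(tops$row, tops$col), unname(oracle))
})

test_that("two equal-height crowns 8 m apart give exactly two treetops", {
  # synthetic CHM: two identical radial bumps, peak 20 m, on a 0.5-m grid
  n <- 40
  ctr <- (seq_len(n) - 0.5) * 0.5
  bump <- function(x, y, cx) 20 - 2 * sqrt((x - cx)^2 + (y - 10)^2)
  v <- outer(ctr, ctr, function(x, y) pmax(bump(x, y, 6), bump(x, y, 14), 0))
  v[v < 2] <- NA
  chm <- ca_raster(v, c(0, 0), 0.5)
  wfn <- function(h) rep(2, length(h))
  tops <- detect_treetops(chm, window_radius_fn = wfn)
  expect_identical(nrow(tops), 2L)
  oracle <- vwf_brute_force(chm, wfn, min_height = 2)
  expect_identical(nrow(oracle), 2L)

  expect_error(detect_treetops(chm, window_radius_fn = function(h) 0 * h),
               "non-positive")
})

test_that("watershed floods one marker over the whole canopy", {
  tr <- reference_tree(crown_density = 300, seed = 4)
  chm <- rasterize_chm(tr$cloud)
  tops <- detect_treetops(chm)
  segs <- watershed_crowns(chm, tops)
  lab <- segs$labels$values
  canopy <- !is.na(chm$values) & chm$values >= 2
  expect_true(all(lab[canopy] == 1L))
  expect_true(all(lab[!canopy] == 0L))

  expect_error(watershed_crowns(chm, tops[0, ]), "at least one")
})

test_that("twin-crown watershed boundary tracks the equidistant line", {
  n <- 60
  ctr <- (seq_len(n) - 0.5) * 0.5
  bump <- function(x, y, cx) 20 - 1.5 * sqrt((x - cx)^2 + (y - 15)^2)
  v <- outer(ctr, ctr, function(x, y) pmax(bump(x, y, 9), bump(x, y, 21), 0))
  v[v < 2] <- NA
  chm <- ca_raster(v, c(0, 0), 0.5)
  tops <- detect_treetops(chm, window_radius_fn = function(h)
    rep(3, length(h)))
  segs <- watershed_crowns(chm, tops)
  lab <- segs$labels$values
  # all labeled cells more than one cell from the midline follow the
  # nearest marker (the symmetric crowns make the midline the watershed)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (lab[i, j] == 0) next
    d1 <- sqrt((ctr[i] - 9)^2 + (ctr[j] - 15)^2)
    d2 <- sqrt((ctr[i] - 21)^2 + (ctr[j] - 15)^2)
    if (abs(d1 - d2) > 2 * 0.5)
      expect_identical(lab[i, j], if (d1 < d2) tops$id[tops$x < 15]
                       else tops$id[tops$x > 15])
  }
})

test_that("point assignment is an exhaustive disjoint partition", {
  tr1 <- reference_tree(crown_density = 200, seed = 1)
  m2 <- tree_model(x = 10, y = 10, height = 18, crown_base = 9,
                   crown_radius = 2, crown_density = 200,
                   stem_density = 500, noise_sd = 0)
  pc <- dplyr::bind_rows(tr1$cloud,
                         generate_tree(m2, seed = 2,
                                       include_ground = FALSE))
  chm <- rasterize_chm(pc)
  segs <- watershed_crowns(chm, detect_treetops(chm))
  asg <- assign_points(pc, segs)
  counts <- table(asg$tree)
  expect_identical(sum(counts), nrow(pc))      # exhaustive
  expect_identical(length(asg$tree), nrow(pc)) # one label per point
})

test_that("points on cell edges follow the half-open cell convention", {
  lab <- ca_raster(matrix(c(1L, 2L, 3L, 4L), 2, 2), c(0, 0), 1)
  segs <- structure(list(labels = lab,
                         treetops = tibble::tibble(id = 1:4)),
                    class = "crown_segments")
  pts <- point_cloud(c(0, 1, 1.999, 0.5), c(0, 1, 0.5, 1), rep(10, 4))
  asg <- assign_points(pts, segs)
  # x in [1, 2) maps to column 2 of the x axis, exactly-on-edge included
  expect_identical(asg$tree, c(1L, 4L, 2L, 3L))
})

test_that("well-separated stands segment every tree with >= 95% accuracy", {
  spec <- stand_spec(treatment = "intensive_below", seed = 2,
                     min_spacing = 4.9,
                     tree_params = list(crown_shape = "cone",
                                        crown_radius_mean = 2.0,
                                        crown_radius_sd = 0.15,
                                        crown_density = 40,
                                        stem_density = 200))
  chk <- stand_segmentation_check(spec)
  expect_identical(chk$n_tops, chk$n_true)
  expect_gte(min(chk$accuracy), 0.95)
})
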