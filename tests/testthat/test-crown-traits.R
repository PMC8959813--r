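test_that("2D hull area and diameter are exact on the unit square", {
  sq <- point_cloud(c(0, 1, 1, 0), c(0, 0, 1, 1), rep(1, 4))
  expect_equal(crown_projection_area(sq), 1)
  expect_equal(max_crown_diameter(sq), sqrt(2))
  expect_error(crown_projection_area(point_cloud(c(0, 1), c(0, 1),
                                                 c(0, 0))),
               "at least 3")
  line <- point_cloud(1:5, 2 * (1:5), rep(0, 5))
  expect_error(crown_projection_area(line), "collinear")
  two <- point_cloud(c(1, 1), c(2, 2), c(0, 0))
  expect_equal(max_crown_diameter(two), 0)
})

test_that("projection area of a sampled disk approaches the analytic area", {
  set.seed(40)
  r <- 2 * sqrt(runif(1e4)); th <- runif(1e4, 0, 2 * pi)
  disk <- point_cloud(r * cos(th), r * sin(th), runif(1e4))
  expect_lt(abs(crown_projection_area(disk) - 4 * pi) / (4 * pi), 0.02)
})

test_that("max crown diameter equals the brute-force pairwise maximum", {
  set.seed(41)
  pc <- point_cloud(rnorm(500), rnorm(500), rnorm(500))
  brute <- max(stats::dist(cbind(pc$x, pc$y)))
  expect_equal(max_crown_diameter(pc), brute, tolerance = 1e-12)
})

test_that("3D hull volume and area are exact on cube and tetrahedron", {
  cube <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  h <- crown_hull_3d(point_cloud(cube$x, cube$y, cube$z))
  expect_equal(h$volume, 1, tolerance = 1e-12)
  expect_equal(h$surface_area, 6, tolerance = 1e-12)

  tet <- point_cloud(c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  expect_equal(crown_hull_3d(tet)$volume, 1 / 6, tolerance = 1e-12)

  flat <- point_cloud(runif(10), runif(10), rep(0, 10))
  expect_error(crown_hull_3d(flat), "coplanar")
})

test_that("hull of dense ellipsoid surface points matches the solid", {
  set.seed(42)
  n <- 1e5
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pc <- point_cloud(1.5 * u[, 1], 1.5 * u[, 2], 3 * u[, 3])
  h <- crown_hull_3d(pc)
  expect_lt(abs(h$volume - 4 / 3 * pi * 1.5^2 * 3) / (4 / 3 * pi * 6.75),
            0.01)
})

test_that("equal-count slices partition the points with balanced counts", {
  set.seed(43)
  pc <- point_cloud(rnorm(100), rnorm(100), runif(100, 5, 15))
  sl <- slice_crown(pc, n = 10)
  expect_identical(sl$n, rep(10L, 10))
  expect_identical(sum(sl$n), 100L)
  expect_true(all(diff(sl$height) > 0))

  # remainder spreads to the lowest slices
  pc2 <- point_cloud(rnorm(103), rnorm(103), runif(103, 5, 15))
  sl2 <- slice_crown(pc2, n = 10)
  expect_identical(sl2$n, c(rep(11L, 3), rep(10L, 7)))
  expect_error(slice_crown(pc[1:20, ]), "at least 30")
})

test_that("a spindle crown puts its widest slice at the generator's hm", {
  m <- tree_model(height = 20, crown_base = 8, crown_radius = 2,
                  crown_max_height = 12, crown_density = 800,
                  stem_density = 0.001, noise_sd = 0)
  pc <- generate_tree(m, seed = 44, include_ground = FALSE)
  crown <- pc[pc$label == 3L, ]
  sl <- slice_crown(crown)
  smry <- slice_summary(sl)
  slice_thickness <- (20 - 8) / 10
  expect_lt(abs(smry$hmc - 12), slice_thickness)
  expect_gt(which.max(sl$diameter), 1)
  expect_lt(which.max(sl$diameter), 10)
})

test_that("slice summary follows the tie and moment conventions", {
  sl <- tibble::tibble(slice = 1:10, height = seq(2, 20, by = 2),
                       diameter = rep(3, 10), area = 0, n = 10L)
  smry <- slice_summary(sl)
  expect_identical(smry$sd_diameter, 0)
  expect_identical(smry$tapering, 0)
  expect_identical(smry$hmc, 2)      # ties resolve to the lowest slice

  sl2 <- dplyr::mutate(sl, diameter = as.numeric(1:10))
  smry2 <- slice_summary(sl2)
  expect_identical(smry2$mean_diameter, 5.5)
  expect_identical(smry2$tapering, 9)
  expect_identical(smry2$sd_diameter, sd(1:10))
})

test_that("crown length and live-crown ratio derive from HMC", {
  clr <- crown_length_and_ratio(20, 8)
  expect_identical(clr$crown_length, 12)
  expect_identical(clr$live_crown_ratio, 0.6)
  clr0 <- crown_length_and_ratio(20, 0)
  expect_identical(clr0$crown_length, 20)
  expect_identical(clr0$live_crown_ratio, 1)
  expect_error(crown_length_and_ratio(20, 20), "hmc")
})

test_that("SAHMC applies pi/4 d^2 on the cm scale", {
  knots <- tibble::tibble(height = c(0, 20), diameter = c(0.13, 0.13),
                          residual = 0, n = 10L)
  tp <- structure(list(knots = knots,
                       fun = splinefun(knots$height, knots$diameter,
                                       method = "natural"),
                       h_lo = 0, h_hi = 20), class = "taper_curve")
  expect_equal(as.numeric(sahmc(tp, 10)), pi / 4 * 13^2, tolerance = 1e-9)

  cone <- reference_tree(taper_k = 1, dbh = 100 * 0.2 * 18.7 / 20,
                         crown_density = 0.001, stem_density = 1500)
  tpc <- fit_taper_curve(cone$cloud[cone$cloud$label == 4L, ])
  expect_equal(as.numeric(sahmc(tpc, 10, H = 20)), 78.54,
               tolerance = 0.01)
})

test_that("hull nesting and volume bounds hold on random crowns", {
  set.seed(45)
  for (i in 1:5) {
    n <- 400
    pc <- point_cloud(rnorm(n, sd = 1 + i / 5), rnorm(n, sd = 1),
                      runif(n, 5, 10 + i))
    proj <- crown_projection_area(pc)
    sl <- slice_crown(pc)
    expect_true(all(sl$area <= proj + 1e-9))
    expect_true(all(sl$diameter <= max_crown_diameter(pc) + 1e-9))
    h <- crown_hull_3d(pc)
    expect_lte(h$volume, proj * diff(range(pc$z)) + 1e-9)
  }
})

test_that("crown_traits assembles the full trait set consistently", {
  tr <- reference_tree(crown_density = 300)
  cl <- classify_stem_points(tr$cloud[, c("x", "y", "z")])
  stem <- cl$points[cl$points$label == 4L, ]
  crown <- cl$points[cl$points$label == 3L, ]
  tp <- fit_taper_curve(stem)
  ct <- crown_traits(crown, taper = tp, H = tree_height(tr$cloud))
  expect_true(all(c("projection_area", "sahmc", "d_p10", "d_p100") %in%
                    names(ct)))
  expect_gte(ct$max_crown_diameter, ct$mean_crown_diameter)
  expect_gte(ct$crown_tapering, 0)
  expect_true(ct$live_crown_ratio > 0 && ct$live_crown_ratio <= 1)
})
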