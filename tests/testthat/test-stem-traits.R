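test_that("circle fit is exact on noise-free circles and robust to noise", {
  f <- fit_circle(circle_points(36, r = 0.1, cx = 3, cy = -2))
  expect_equal(f$diameter, 0.2, tolerance = 1e-12)
  expect_equal(f$center_x, 3, tolerance = 1e-12)
  expect_equal(f$center_y, -2, tolerance = 1e-12)
  expect_lt(f$residual, 1e-12)

  set.seed(30)
  ds <- vapply(1:100, function(i) {
    p <- circle_points(36, r = 0.1)
    fit_circle(tibble::tibble(x = p$x + rnorm(36, 0, 0.002),
                              y = p$y + rnorm(36, 0, 0.002)))$diameter
  }, numeric(1))
  expect_lt(abs(median(ds) - 0.2), 0.002)
})

test_that("circle fit rejects undersized and collinear input", {
  expect_error(fit_circle(circle_points(4)), "at least 5")
  line <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
  expect_error(fit_circle(line), "collinear")
})

test_that("taper curve recovers a cone within 2 mm and a cylinder within 1 mm", {
  cone <- reference_tree(height = 20, dbh = 100 * 0.2 * 18.7 / 20,
                         taper_k = 1, crown_density = 0.001,
                         stem_density = 2000)
  stem <- cone$cloud[cone$cloud$label == 4L, ]
  tp <- fit_taper_curve(stem)
  h <- seq(0.25, 15, by = 0.25)
  d_true <- 0.2 * (20 - h) / 20
  d_est <- as.numeric(taper_diameter(tp, h, H = 20))
  expect_lt(max(abs(d_est - d_true)), 0.002)

  cyl <- tree_model(height = 10, dbh = 25, taper_k = 0, crown_base = 5,
                    crown_radius = 1, crown_density = 0.001,
                    stem_density = 2000, noise_sd = 0)
  stem2 <- generate_tree(cyl, seed = 2, include_ground = FALSE)
  tp2 <- fit_taper_curve(stem2[stem2$label == 4L, ])
  h2 <- seq(tp2$h_lo, tp2$h_hi, length.out = 50)
  expect_lt(max(abs(as.numeric(taper_diameter(tp2, h2)) - 0.25)), 0.001)
})

test_that("crown-contaminated slices are dropped but the curve survives", {
  cyl <- tree_model(height = 10, dbh = 20, taper_k = 0, crown_base = 5,
                    crown_radius = 1, crown_density = 0.001,
                    stem_density = 1500, noise_sd = 0)
  stem <- generate_tree(cyl, seed = 3, include_ground = FALSE)
  stem <- stem[stem$label == 4L & stem$z < 8, ]
  set.seed(31)
  blob <- point_cloud(runif(2000, -1.5, 1.5), runif(2000, -1.5, 1.5),
                      runif(2000, 8, 10))
  tp <- fit_taper_curve(dplyr::bind_rows(stem[, c("x", "y", "z")], blob))
  expect_lt(tp$h_hi, 8.5)                      # blob slices rejected
  expect_equal(tp$fun(5), 0.2, tolerance = 1e-3)
  # monotone sanity on the accepted knots
  expect_true(all(diff(tp$knots$diameter) <= 0.1 * head(tp$knots$diameter,
                                                        -1) + 1e-12))
  expect_error(fit_taper_curve(stem[1:8, ]), "at least 2")
})

test_that("tree height is the highest normalized return", {
  tr <- reference_tree(crown_density = 1200)
  expect_lt(abs(tree_height(tr$cloud) - 20), 0.05)
  expect_identical(tree_height(point_cloud(0, 0, 3)), 3)
  expect_error(tree_height(point_cloud()), "empty")
})

test_that("DBH comes from the taper at 1.3 m with an extrapolation flag", {
  cone <- reference_tree(taper_k = 1, dbh = 18.7, crown_density = 0.001,
                         stem_density = 1500)
  tp <- fit_taper_curve(cone$cloud[cone$cloud$label == 4L, ])
  d <- dbh(tp)
  expect_equal(as.numeric(d), 18.7, tolerance = 0.02 / 0.187)
  expect_false(attr(d, "extrapolated"))

  high <- cone$cloud[cone$cloud$label == 4L & cone$cloud$z > 2, ]
  tp2 <- fit_taper_curve(high)
  d2 <- dbh(tp2)
  expect_true(attr(d2, "extrapolated"))
  expect_equal(as.numeric(d2), 18.7, tolerance = 0.2 / 18.7)
})

test_that("cylinder and cone volumes match closed forms", {
  cyl <- tree_model(height = 10, dbh = 20, taper_k = 0, crown_base = 5,
                    crown_radius = 1, crown_density = 0.001,
                    stem_density = 1500, noise_sd = 0)
  tp <- fit_taper_curve(generate_tree(cyl, seed = 5,
                                      include_ground = FALSE))
  v <- stem_volume(tp, H = 10)
  expect_lt(abs(v - 1000 * pi / 4 * 0.04 * 10) / (1000 * pi / 4 * 0.4),
            0.001)

  cone <- reference_tree(taper_k = 1, dbh = 100 * 0.2 * 18.7 / 20,
                         crown_density = 0.001, stem_density = 2000)
  tpc <- fit_taper_curve(cone$cloud[cone$cloud$label == 4L, ])
  vc <- stem_volume(tpc, H = 20)
  expect_lt(abs(vc - 209.4395) / 209.4395, 0.005)

  # a single partial 5-cm bin
  v5 <- stem_volume(tp, H = 0.05)
  expect_equal(v5, 1000 * pi / 4 * 0.2^2 * 0.05, tolerance = 0.01)
  expect_error(stem_volume(tp, H = 0), "positive")
})

test_that("height at half volume matches cylinder and cone theory", {
  cyl <- tree_model(height = 10, dbh = 20, taper_k = 0, crown_base = 5,
                    crown_radius = 1, crown_density = 0.001,
                    stem_density = 1500, noise_sd = 0)
  tp <- fit_taper_curve(generate_tree(cyl, seed = 6,
                                      include_ground = FALSE))
  expect_equal(height_at_volume_fraction(tp, H = 10, frac = 0.5), 5,
               tolerance = 0.02)

  cone <- reference_tree(taper_k = 1, crown_density = 0.001,
                         stem_density = 2000)
  tpc <- fit_taper_curve(cone$cloud[cone$cloud$label == 4L, ])
  h50 <- height_at_volume_fraction(tpc, H = 20, frac = 0.5)
  expect_lt(abs(h50 - 20 * (1 - 0.5^(1 / 3))), 0.1)  # within one bin

  expect_error(height_at_volume_fraction(tpc, H = 20, frac = 1),
               "strictly between")
})

test_that("height/DBH ratio uses the conventional m-per-cm units", {
  expect_identical(height_dbh_ratio(20, 20), 1)
  expect_identical(height_dbh_ratio(18, 24), 0.75)
  expect_error(height_dbh_ratio(18, 0), "positive")
})
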