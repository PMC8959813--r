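test_that("tree model rejects invalid geometry", {
  expect_error(tree_model(height = 20, crown_base = 25), "hb < H")
  expect_error(tree_model(height = 20, crown_base = -1), "hb < H")
  expect_error(tree_model(crown_radius = 0), "positive")
  expect_error(tree_model(height = 20, crown_base = 10,
                          crown_max_height = 9.5), "hb < hm < H")
})

test_that("zero-noise cylinder stem points sit exactly on the surface", {
  m <- tree_model(height = 10, dbh = 20, taper_k = 0, crown_base = 5,
                  crown_radius = 1, crown_density = 0.001,
                  stem_density = 300, noise_sd = 0)
  pc <- generate_tree(m, seed = 1, include_ground = FALSE)
  stem <- pc[pc$label == 4L, ]
  r <- sqrt(stem$x^2 + stem$y^2)
  expect_gt(nrow(stem), 100)
  expect_true(all(abs(r - 0.1) < 1e-12))
})

test_that("generation is deterministic in the seed and sensitive to it", {
  m <- tree_model(height = 15, crown_base = 8, crown_radius = 1.5)
  expect_identical(generate_tree(m, seed = 7), generate_tree(m, seed = 7))
  expect_false(identical(generate_tree(m, seed = 7),
                         generate_tree(m, seed = 8)))
})

test_that("crown point counts follow Poisson sampling of the solid volume", {
  m <- tree_model(height = 20, crown_base = 17, crown_radius = 0.8,
                  crown_shape = "ellipsoid", crown_density = 500,
                  stem_density = 0.001, noise_sd = 0)
  V <- 2 * pi / 3 * 0.8^2 * 3     # analytic ellipsoid crown volume
  lambda <- 500 * V
  counts <- vapply(1:100, function(s)
    sum(generate_tree(m, seed = s, include_ground = FALSE)$label == 3L),
    numeric(1))
  # mean of 100 Poisson draws: within 4 standard errors of lambda
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / 100))
})

test_that("oracle traits match closed forms for the analytic solids", {
  # ellipsoid crown: semi-axes 1.5, 1.5, 3.0
  m <- tree_model(height = 20, crown_base = 14, crown_radius = 1.5,
                  crown_shape = "ellipsoid")
  tr <- oracle_traits(m)
  expect_equal(tr$crown$crown_volume, 4 / 3 * pi * 1.5^2 * 3,
               tolerance = 1e-6)
  expect_equal(tr$crown$projection_area, pi * 1.5^2, tolerance = 1e-9)
  expect_equal(tr$crown$max_crown_diameter, 3, tolerance = 1e-9)

  # cone stem d0 = 0.2, H = 20, k = 1: volume (1/3) pi 0.1^2 20
  mc <- tree_model(height = 20, dbh = 100 * 0.2 * (18.7 / 20), taper_k = 1,
                   crown_base = 10, crown_radius = 2)
  tr2 <- oracle_traits(mc)
  expect_equal(tr2$stem$stem_volume, 1000 * pi / 3 * 0.1^2 * 20,
               tolerance = 1e-6)
  expect_equal(tr2$stem$dbh, 18.7, tolerance = 1e-9)
  # taper d(h) = 0.2 (20-h)/20 evaluated at hm = 10 gives SAHMC 78.54 cm^2
  expect_equal(pi / 4 * (100 * 0.2 * 0.5)^2, 78.53982, tolerance = 1e-6)
})

test_that("oracle crown size traits increase strictly with crown radius", {
  vals <- lapply(c(1.5, 2, 2.5), function(rc) {
    oracle_traits(tree_model(height = 20, crown_base = 10,
                             crown_radius = rc))$crown
  })
  for (tr in c("projection_area", "max_crown_diameter", "crown_volume")) {
    v <- vapply(vals, function(x) x[[tr]], numeric(1))
    expect_true(all(diff(v) > 0))
  }
})

test_that("stands hit the target density and carry one truth row per tree", {
  spec <- stand_spec(treatment = "intensive_below", density = 290,
                     plot_width = 25, plot_height = 40, seed = 3,
                     tree_params = list(crown_density = 5,
                                        stem_density = 30))
  st <- generate_stand(spec)
  expect_true(abs(nrow(st$truth) - 29) <= 3)     # 290/ha on 1,000 m^2
  expect_identical(sort(unique(st$cloud$tree[st$cloud$tree > 0])),
                   st$truth$tree)
  expect_true(all(c("sahmc", "growth_dbh", "growth_volume") %in%
                    names(st$truth)))
  expect_true(all(is.finite(st$truth$sahmc) & st$truth$sahmc > 0))
})

test_that("zero-density stands are ground only; seeds move the trees", {
  spec0 <- stand_spec(treatment = "none", density = 0, seed = 1)
  st0 <- generate_stand(spec0)
  expect_identical(nrow(st0$truth), 0L)
  expect_true(all(st0$cloud$label == 2L))

  s1 <- generate_stand(stand_spec(treatment = "intensive_below", seed = 4,
                                  tree_params = list(crown_density = 2,
                                                     stem_density = 10)))
  s2 <- generate_stand(stand_spec(treatment = "intensive_below", seed = 5,
                                  tree_params = list(crown_density = 2,
                                                     stem_density = 10)))
  expect_false(isTRUE(all.equal(s1$truth$x, s2$truth$x)))
})

test_that("unreachable densities fail naming the spacing constraint", {
  expect_error(
    generate_stand(stand_spec(treatment = "none", density = 1250,
                              min_spacing = 4, seed = 1)),
    "minimum-spacing")
})

test_that("minimum spacing is honoured in placed stands", {
  spec <- stand_spec(treatment = "none", seed = 6, min_spacing = 2.6,
                     tree_params = list(crown_density = 1,
                                        stem_density = 5))
  st <- generate_stand(spec)
  d <- as.matrix(stats::dist(cbind(st$truth$x, st$truth$y)))
  diag(d) <- Inf
  expect_gte(min(d), 2.6)
})
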