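test_that("with zero variance components the LMM reduces to group means", {
  tab <- simulate_trait_table(var_site = 0, var_plot = 0, var_resid = 4,
                              seed = 50)
  fit <- fit_nested_lmm(tab, "sahmc")
  means <- tapply(tab$sahmc, tab$treatment, mean)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_lt(max(abs(est[names(means)] - means)), 1e-6)
})

test_that("a constant trait yields equal estimates and zero variances", {
  tab <- simulate_trait_table(seed = 51)
  tab$const <- 7.5
  fit <- fit_nested_lmm(tab, "const")
  expect_true(all(abs(tidy(fit)$estimate - 7.5) < 1e-9))
  g <- glance(fit)
  expect_lt(g$var_site, 1e-9)
  expect_lt(g$var_plot, 1e-9)
})

test_that("design degeneracies are reported, not silently fitted", {
  tab <- simulate_trait_table(seed = 52)
  one_site <- dplyr::filter(tab, .data$site == "S1")
  expect_error(fit_nested_lmm(one_site, "sahmc"), "2 sites")
  thin <- dplyr::filter(tab, .data$site != "S1" | .data$plot == "S1_P1")
  expect_error(fit_nested_lmm(thin, "sahmc"), "single plot")
  expect_error(fit_nested_lmm(tab, "missing_trait"), "lacks columns")
})

test_that("variance components recover the generating values", {
  tab <- simulate_trait_table(n_sites = 6, plots_per_site = 9,
                              trees_per_plot = 30, var_site = 4,
                              var_plot = 2, var_resid = 9, seed = 53)
  g <- glance(fit_nested_lmm(tab, "sahmc"))
  expect_lt(abs(g$var_residual - 9) / 9, 0.2)
  expect_lt(abs(g$var_plot - 2) / 2, 0.8)   # few plot replicates: noisy
})

test_that("Tukey contrasts are antisymmetric under level reversal", {
  tab <- simulate_trait_table(seed = 54)
  fit <- fit_nested_lmm(tab, "sahmc")
  tk <- tukey_contrasts(fit)
  expect_identical(nrow(tk), 21L)
  expect_true(all(tk$adj.p.value >= 0 & tk$adj.p.value <= 1))

  tab_rev <- tab
  tab_rev$treatment <- factor(tab_rev$treatment,
                              levels = rev(sort(unique(tab$treatment))))
  tk_rev <- tukey_contrasts(fit_nested_lmm(tab_rev, "sahmc"))
  key <- paste(tk$treatment_1, tk$treatment_2)
  key_rev <- paste(tk_rev$treatment_2, tk_rev$treatment_1)
  m <- match(key, key_rev)
  expect_true(all(!is.na(m)))
  expect_equal(tk$estimate, -tk_rev$estimate[m], tolerance = 1e-6)
})

test_that("trait screen is exact for linear and monotone transforms", {
  tab <- simulate_trait_table(seed = 55)
  tab$double_sahmc <- 2 * tab$sahmc
  tab$expo <- exp(tab$sahmc / 50)
  tab$flat <- 1
  sc <- trait_screen(tab, traits = c("double_sahmc", "expo", "flat"))
  lin <- sc[sc$trait == "double_sahmc", ]
  expect_equal(lin$pearson_r, 1, tolerance = 1e-9)
  expect_equal(lin$spearman_rho, 1, tolerance = 1e-9)
  expect_equal(lin$slope, 0.5, tolerance = 1e-6)
  mono <- sc[sc$trait == "expo", ]
  expect_equal(mono$spearman_rho, 1, tolerance = 1e-9)
  expect_lt(mono$pearson_r, 1)
  expect_identical(sc$note[sc$trait == "flat"],
                   "zero variance or too few complete pairs")
})

test_that("planted growth slopes are recovered with the right sign", {
  tab <- simulate_trait_table(
    var_site = 25, var_plot = 9, var_resid = 100,
    growth_model = default_growth_model(), seed = 56)
  sc <- trait_screen(tab, traits = "growth_dbh")
  expect_gt(sc$slope, 0)
  expect_lt(sc$slope_p, 0.05)
  expect_gt(sc$pearson_r, 0.5)
})

test_that("stand ground truth feeds the statistics layer end to end", {
  tabs <- list()
  k <- 0
  for (site in c("S1", "S2")) for (p in 1:2) {
    k <- k + 1
    trt <- c("intensive_below", "none")[p]
    spec <- stand_spec(treatment = trt, site = site,
                       plot = sprintf("%s_P%d", site, p), seed = 60 + k,
                       tree_params = list(crown_density = 1,
                                          stem_density = 5))
    tabs[[k]] <- generate_stand(spec)$truth
  }
  truth <- dplyr::bind_rows(tabs)
  fit <- fit_nested_lmm(truth, "sahmc")
  expect_s3_class(fit, "crownarch_lmm")
  sc <- trait_screen(truth, traits = c("crown_volume", "growth_dbh"))
  expect_true(all(is.finite(sc$pearson_r)))
})
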