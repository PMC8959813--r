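#' Parametric model of a single synthetic tree
#'
#' The stem is a power-law taper `d(h) = d0 ((H - h)/H)^k` (`k = 0` gives a
#' cylinder, `k = 1` a cone); the crown is a convex solid of revolution
#' around the stem axis. Crown shapes: `"spheroid"` (two half-spheroid caps
#' meeting at the height of maximum radius `hm`, so `hm` is a free
#' parameter), `"ellipsoid"` (`hm` fixed at mid-crown) and `"cone"` (widest
#' at the crown base, so `hm` equals the crown base height). All three are
#' convex, making their convex hulls and 2D projections analytic.
#'
#' @param x,y stem position (m).
#' @param height total tree height H (m).
#' @param dbh diameter at breast height, 1.3 m (cm). The basal diameter `d0`
#'   is derived so the taper passes through the DBH.
#' @param taper_k taper exponent `k >= 0`.
#' @param crown_shape `"spheroid"`, `"ellipsoid"` or `"cone"`.
#' @param crown_base crown base height hb (m), `0 < hb < H`.
#' @param crown_radius maximum crown radius rc (m).
#' @param crown_max_height height hm of the maximum crown radius (m).
#'   Defaults: 35% of the crown span for `"spheroid"` (the middle of the
#'   fourth height decile, so the widest slice is unambiguous), mid-crown
#'   for `"ellipsoid"`, the crown base for `"cone"`.
#' @param crown_density crown point density (points/m^3).
#' @param stem_density stem surface point density (points/m^2).
#' @param noise_sd Gaussian noise SD applied to stem radius and crown
#'   coordinates (m).
#' @return An object of class `tree_model`.
#' @export
tree_model <- function(x = 0, y = 0, height = 20, dbh = 20, taper_k = 0.7,
                       crown_shape = c("spheroid", "ellipsoid", "cone"),
                       crown_base = 0.5 * height,
                       crown_radius = 2,
                       crown_max_height = NULL,
                       crown_density = 60, stem_density = 500,
                       noise_sd = 0.005) {
  crown_shape <- match.arg(crown_shape)
  H <- height
  if (!is.finite(H) || H <= 1.3) stop("tree height must exceed 1.3 m")
  if (dbh <= 0) stop("dbh must be positive")
  if (taper_k < 0) stop("taper exponent k must be >= 0")
  hb <- crown_base
  if (!is.finite(hb) || hb <= 0 || hb >= H)
    stop("invalid geometry: crown base must satisfy 0 < hb < H (got hb = ",
         signif(hb, 4), ", H = ", signif(H, 4), ")")
  if (crown_radius <= 0) stop("crown radius must be positive")
  hm <- crown_max_height
  if (is.null(hm)) {
    hm <- switch(crown_shape,
                 spheroid = hb + 0.35 * (H - hb),
                 ellipsoid = (hb + H) / 2,
                 cone = hb)
  }
  if (crown_shape == "ellipsoid") hm <- (hb + H) / 2
  if (crown_shape == "cone") {
    if (hm != hb) stop("cone crowns are widest at the crown base: hm = hb")
  } else if (hm <= hb || hm >= H) {
    stop("invalid geometry: need hb < hm < H")
  }
  d0 <- (dbh / 100) / ((H - 1.3) / H)^taper_k
  structure(list(
    x = x, y = y, height = H, dbh = dbh, d0 = d0, taper_k = taper_k,
    crown_shape = crown_shape, crown_base = hb, crown_radius = crown_radius,
    crown_max_height = hm, crown_density = crown_density,
    stem_density = stem_density, noise_sd = noise_sd
  ), class = "tree_model")
}

#' @export
print.tree_model <- function(x, ...) {
  cat(sprintf(
    "<tree_model> H %.1f m, DBH %.1f cm (k = %.2f), %s crown [%.1f, %.1f] m, rc %.2f m at %.1f m\n",
    x$height, x$dbh, x$taper_k, x$crown_shape, x$crown_base, x$height,
    x$crown_radius, x$crown_max_height))
  invisible(x)
}

# taper diameter d(h) of the generative model (m)
model_taper <- function(model, h) {
  d <- model$d0 * pmax(0, (model$height - h) / model$height)^model$taper_k
  d[h < 0] <- NA_real_
  d
}

# crown radius profile r(h) of the generative model (m)
model_crown_radius <- function(model, h) {
  hb <- model$crown_base; hm <- model$crown_max_height
  H <- model$height; rc <- model$crown_radius
  r <- numeric(length(h))
  inside <- h >= hb & h <= H
  if (model$crown_shape == "cone") {
    r[inside] <- rc * (H - h[inside]) / (H - hb)
  } else {
    lo <- inside & h <= hm
    hi <- inside & h > hm
    r[lo] <- rc * sqrt(pmax(0, 1 - ((hm - h[lo]) / (hm - hb))^2))
    r[hi] <- rc * sqrt(pmax(0, 1 - ((h[hi] - hm) / (H - hm))^2))
  }
  r
}

# analytic crown solid volume (m^3)
model_crown_volume <- function(model) {
  span <- model$height - model$crown_base
  if (model$crown_shape == "cone") pi / 3 * model$crown_radius^2 * span
  else 2 * pi / 3 * model$crown_radius^2 * span
}

# analytic stem volume (m^3): integral of (pi/4) d(h)^2
model_stem_volume <- function(model) {
  pi / 4 * model$d0^2 * model$height / (2 * model$taper_k + 1)
}

#' Generate a labeled TLS-like point cloud for one tree
#'
#' Stem points sit on the taper surface (area-proportional sampling along
#' the stem) with radial Gaussian noise; crown points fill the crown solid
#' uniformly with coordinate noise; an optional flat circular ground patch
#' is added for standalone use. Point counts are Poisson in density times
#' surface area / volume. Deterministic for a given seed.
#'
#' @param model a [tree_model()].
#' @param seed integer seed (optional).
#' @param include_ground add a ground disk around the stem foot?
#' @param ground_radius,ground_density radius (m) and density (points/m^2)
#'   of the ground patch.
#' @param base_z terrain elevation at the stem foot; all tree points are
#'   shifted up by this amount.
#' @return A point-cloud tibble with `label` codes 2 (ground), 3 (crown),
#'   4 (stem).
#' @export
generate_tree <- function(model, seed = NULL, include_ground = TRUE,
                          ground_radius = 3, ground_density = 100,
                          base_z = 0) {
  stopifnot(inherits(model, "tree_model"))
  with_seed(seed, {
    H <- model$height; k <- model$taper_k
    # stem: heights with density proportional to circumference
    stem_area <- pi * model$d0 * H / (k + 1)
    n_stem <- rpois(1, model$stem_density * stem_area)
    hs <- H * (1 - runif(n_stem)^(1 / (k + 1)))
    th <- runif(n_stem, 0, 2 * pi)
    r <- model_taper(model, hs) / 2 + rnorm(n_stem, 0, model$noise_sd)
    stem <- tibble::tibble(x = model$x + r * cos(th),
                           y = model$y + r * sin(th),
                           z = hs, label = LABEL_STEM)
    # crown: uniform in the solid by rejection in h, then uniform in the disk
    vol <- model_crown_volume(model)
    n_crown <- rpois(1, model$crown_density * vol)
    hs_c <- numeric(0)
    while (length(hs_c) < n_crown) {
      prop <- runif(2 * (n_crown - length(hs_c)) + 16, model$crown_base, H)
      keep <- runif(length(prop)) <
        (model_crown_radius(model, prop) / model$crown_radius)^2
      hs_c <- c(hs_c, prop[keep])
    }
    hs_c <- hs_c[seq_len(n_crown)]
    rr <- model_crown_radius(model, hs_c) * sqrt(runif(n_crown))
    th_c <- runif(n_crown, 0, 2 * pi)
    crown <- tibble::tibble(
      x = model$x + rr * cos(th_c) + rnorm(n_crown, 0, model$noise_sd),
      y = model$y + rr * sin(th_c) + rnorm(n_crown, 0, model$noise_sd),
      z = hs_c + rnorm(n_crown, 0, model$noise_sd),
      label = LABEL_CROWN)
    out <- dplyr::bind_rows(stem, crown)
    out$z <- out$z + base_z
    if (include_ground) {
      n_g <- rpois(1, ground_density * pi * ground_radius^2)
      rg <- ground_radius * sqrt(runif(n_g))
      tg <- runif(n_g, 0, 2 * pi)
      ground <- tibble::tibble(x = model$x + rg * cos(tg),
                               y = model$y + rg * sin(tg),
                               z = base_z + rnorm(n_g, 0, model$noise_sd),
                               label = LABEL_GROUND)
      out <- dplyr::bind_rows(ground, out)
    }
    out
  })
}

# --- analytic / high-resolution oracle traits -------------------------------

#' Ground-truth traits of a tree model
#'
#' Computes every crown and stem trait directly from the generative solids:
#' closed forms where available (hull volume and projection of the convex
#' crown solids, power-law stem volume), otherwise numeric integration on a
#' 1-mm height grid. Crown slicing mirrors the pipeline definition: deciles
#' of the crown point height distribution (density proportional to the
#' squared radius profile), slice diameter twice the maximum profile radius
#' in the slice, representative height the density-weighted mean height.
#'
#' @param model a [tree_model()].
#' @param n_slices number of crown slices (10 = height deciles).
#' @param step integration step (m).
#' @return List with one-row tibbles `crown` and `stem` whose columns match
#'   [crown_traits()] and [stem_traits()] outputs.
#' @export
oracle_traits <- function(model, n_slices = 10, step = 0.001) {
  H <- model$height; hb <- model$crown_base; rc <- model$crown_radius
  h <- seq(hb, H, by = step)
  r <- model_crown_radius(model, h)
  dr <- c(diff(r), 0) / step
  lateral <- sum(2 * pi * r * sqrt(1 + dr^2) * step)
  surface <- lateral + if (model$crown_shape == "cone") pi * rc^2 else 0
  # slice the solid into equal-mass height bins, mass density ~ r(h)^2
  w <- r^2
  cw <- cumsum(w); cw <- cw / cw[length(cw)]
  edges <- vapply(seq_len(n_slices - 1) / n_slices,
                  function(q) h[which(cw >= q)[1]], numeric(1))
  edges <- c(hb, edges, H)
  slice <- findInterval(h, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
  diam <- vapply(seq_len(n_slices), function(s) 2 * max(r[slice == s]),
                 numeric(1))
  rep_h <- vapply(seq_len(n_slices), function(s) {
    i <- slice == s
    sum(h[i] * w[i]) / sum(w[i])
  }, numeric(1))
  # near-ties resolve to the lowest slice, mirroring slice_summary()
  hmc <- rep_h[which(diam >= max(diam) - 0.01)[1]]
  d_hmc_cm <- 100 * model_taper(model, hmc)
  crown <- tibble::tibble(
    projection_area = pi * rc^2,
    crown_volume = model_crown_volume(model),
    surface_area = surface,
    max_crown_diameter = 2 * rc,
    mean_crown_diameter = mean(diam),
    sd_crown_diameter = sd(diam),
    hmc = hmc,
    crown_length = H - hmc,
    crown_tapering = max(diam) - min(diam),
    live_crown_ratio = (H - hmc) / H,
    sahmc = pi / 4 * d_hmc_cm^2
  )
  for (s in seq_len(n_slices))
    crown[[sprintf("d_p%d", 10 * s)]] <- diam[s]
  dbh_cm <- 100 * model_taper(model, 1.3)
  stem <- tibble::tibble(
    height = H,
    dbh = dbh_cm,
    stem_volume = 1000 * model_stem_volume(model),
    height_at_half_volume = H * (1 - 0.5^(1 / (2 * model$taper_k + 1))),
    height_dbh_ratio = H / dbh_cm
  )
  list(crown = crown, stem = stem)
}

# --- stands -----------------------------------------------------------------

#' The seven thinning treatments and their stand conditions
#'
#' Per-treatment defaults used by the stand generator: residual stand
#' densities, and tree-size distributions emulating mature southern-boreal
#' Scots pine experiments roughly 13 years after treatment (DBH and height
#' means/SDs per treatment; crowns wider and deeper-reaching at lower
#' density). Crown-base heights are set so that, with the default taper
#' exponent and spheroid crowns, the treatment-mean stem cross-section at
#' the height of the maximum crown diameter lands on the scale reported
#' for such trials (roughly 70 cm^2 in unthinned stands up to 160 cm^2
#' under intensive thinning from below). Treatment levels are ordered
#' moderate below/above/systematic, intensive below/above/systematic,
#' then the untreated control.
#'
#' @return Tibble with one row per treatment.
#' @export
thinning_treatments <- function() {
  tibble::tibble(
    treatment = treatment_levels(),
    density = c(720, 910, 940, 290, 450, 470, 1250),
    dbh_mean = c(22.2, 19.3, 18.8, 26.4, 21.1, 20.8, 18.7),
    dbh_sd = c(3.7, 4.3, 4.2, 3.9, 3.5, 4.3, 5.0),
    height_mean = c(21.2, 20.4, 19.4, 21.2, 19.1, 19.6, 20.2),
    height_sd = c(2.1, 1.6, 2.2, 1.7, 1.5, 2.8, 3.0),
    crown_radius_mean = c(1.7, 1.6, 1.6, 2.2, 1.9, 1.9, 1.3),
    crown_radius_sd = c(0.2, 0.2, 0.2, 0.25, 0.2, 0.2, 0.15),
    crown_base_mean = c(10.0, 7.9, 7.1, 8.4, 6.3, 6.4, 9.0),
    crown_base_sd = c(1, 1, 1, 1, 1, 1, 1)
  )
}

#' The seven thinning treatment labels, in model order
#'
#' @return Character vector: moderate below/above/systematic, intensive
#'   below/above/systematic, `"none"` (untreated control).
#' @export
treatment_levels <- function() {
  c("moderate_below", "moderate_above", "moderate_systematic",
    "intensive_below", "intensive_above", "intensive_systematic", "none")
}

#' Specification of a synthetic sample plot
#'
#' @param treatment one of the seven thinning treatment labels (see
#'   [thinning_treatments()]).
#' @param density target stand density (stems/ha); defaults to the
#'   treatment's residual density.
#' @param plot_width,plot_height plot rectangle (m); the default 32 x 33 m
#'   gives 1,056 m^2, within the 1,000-1,200 m^2 plot sizes of thinning
#'   trials.
#' @param min_spacing minimum distance between stem positions (m).
#' @param tree_params named list overriding the treatment's tree-parameter
#'   distribution (`dbh_mean`, `dbh_sd`, `height_mean`, `height_sd`,
#'   `crown_radius_mean`, `crown_radius_sd`, `crown_base_mean`,
#'   `crown_base_sd`) or scalar [tree_model()] arguments (`taper_k`,
#'   `crown_shape`, `crown_density`, `stem_density`, `noise_sd`).
#' @param ground_amplitude,ground_wavelength amplitude (m, <= 0.5) and
#'   wavelength (m) of the smooth sinusoidal terrain.
#' @param ground_density ground return density (points/m^2).
#' @param growth_model per-trait coefficients `(a, b, sd)` of the synthetic
#'   growth generator `growth = a + b * SAHMC_true + N(0, sd^2)`.
#' @param site,plot site and plot identifiers carried into the ground-truth
#'   table.
#' @param seed integer seed driving all randomness of the stand.
#' @return An object of class `stand_spec`.
#' @export
stand_spec <- function(treatment = "none", density = NULL,
                       plot_width = 32, plot_height = 33,
                       min_spacing = 1.5,
                       tree_params = list(),
                       ground_amplitude = 0.2, ground_wavelength = 40,
                       ground_density = 80,
                       growth_model = default_growth_model(),
                       site = "S1", plot = "P1", seed = 1L) {
  treatment <- match.arg(treatment, treatment_levels())
  defaults <- as.list(dplyr::filter(thinning_treatments(),
                                    .data$treatment == !!treatment))
  if (is.null(density)) density <- defaults$density
  if (density < 0 || (density > 0 && (density < 250 || density > 1400)))
    stop("stand density must be 0 or within [250, 1400] stems/ha")
  if (ground_amplitude < 0 || ground_amplitude > 0.5)
    stop("ground amplitude must be within [0, 0.5] m")
  known <- c("dbh_mean", "dbh_sd", "height_mean", "height_sd",
             "crown_radius_mean", "crown_radius_sd", "crown_base_mean",
             "crown_base_sd", "taper_k", "crown_shape", "crown_density",
             "stem_density", "noise_sd")
  bad <- setdiff(names(tree_params), known)
  if (length(bad))
    stop("unknown tree_params: ", paste(bad, collapse = ", "))
  params <- utils::modifyList(
    c(defaults[setdiff(names(defaults), c("treatment", "density"))],
      list(taper_k = 0.7, crown_shape = "spheroid", crown_density = 60,
           stem_density = 500, noise_sd = 0.005)),
    tree_params)
  structure(list(
    treatment = treatment, density = density,
    plot_width = plot_width, plot_height = plot_height,
    min_spacing = min_spacing, tree_params = params,
    ground_amplitude = ground_amplitude,
    ground_wavelength = ground_wavelength,
    ground_density = ground_density, growth_model = growth_model,
    site = site, plot = plot, seed = as.integer(seed)
  ), class = "stand_spec")
}

#' Coefficients of the synthetic growth generator
#'
#' Each 13-year growth column of the ground-truth table is drawn as
#' `a + b * SAHMC_true + N(0, sd^2)` with a positive slope `b`, so
#' trait-screen statistics have a known planted sign. Magnitudes give
#' growth of a few cm DBH, a few m height and a few hundred dm^3 volume.
#'
#' @return Named list of `c(a, b, sd)` vectors.
#' @export
default_growth_model <- function() {
  list(growth_dbh = c(a = 1, b = 0.025, sd = 0.8),
       growth_height = c(a = 4, b = 0.012, sd = 0.7),
       growth_volume = c(a = 30, b = 1.6, sd = 35),
       growth_hd_ratio = c(a = 0.02, b = 0.0015, sd = 0.05))
}

#' @export
print.stand_spec <- function(x, ...) {
  cat(sprintf(
    "<stand_spec> %s, %g stems/ha on %.0f x %.0f m (site %s, plot %s, seed %d)\n",
    x$treatment, x$density, x$plot_width, x$plot_height, x$site, x$plot,
    x$seed))
  invisible(x)
}

#' Generate a synthetic TLS plot with analytic ground truth
#'
#' Trees are placed on a jittered grid that enforces the minimum stem
#' spacing (pure rejection sampling cannot reach 1,250 stems/ha under a
#' hard-core constraint), tree sizes are drawn from the treatment's
#' distributions, ground returns follow a smooth sinusoidal terrain, and
#' every tree's traits are computed analytically with [oracle_traits()].
#' Synthetic growth columns are linear in true SAHMC plus noise (see
#' [default_growth_model()]).
#'
#' @param spec a [stand_spec()].
#' @return List with `cloud` (point-cloud tibble with `label` and `tree`
#'   columns; `tree = 0` for ground) and `truth` (one row per tree: ids,
#'   model parameters, oracle traits, growth columns).
#' @export
generate_stand <- function(spec) {
  stopifnot(inherits(spec, "stand_spec"))
  area_ha <- spec$plot_width * spec$plot_height / 1e4
  n <- round(spec$density * area_ha)
  gfun <- function(x, y) {
    spec$ground_amplitude * sin(2 * pi * x / spec$ground_wavelength) *
      sin(2 * pi * y / spec$ground_wavelength)
  }
  with_seed(spec$seed, {
    # ground returns over the whole plot
    n_g <- rpois(1, spec$ground_density * spec$plot_width * spec$plot_height)
    gx <- runif(n_g, 0, spec$plot_width)
    gy <- runif(n_g, 0, spec$plot_height)
    noise <- spec$tree_params$noise_sd
    cloud <- tibble::tibble(x = gx, y = gy,
                            z = gfun(gx, gy) + rnorm(n_g, 0, noise),
                            label = LABEL_GROUND, tree = 0L)
    truth <- tibble::tibble()
    if (n > 0) {
      pos <- place_trees(n, spec$plot_width, spec$plot_height,
                         spec$min_spacing)
      p <- spec$tree_params
      models <- vector("list", n)
      for (i in seq_len(n)) {
        H <- max(5, rnorm(1, p$height_mean, p$height_sd))
        hb <- min(max(1, rnorm(1, p$crown_base_mean, p$crown_base_sd)),
                  0.75 * H)
        models[[i]] <- tree_model(
          x = pos[i, 1], y = pos[i, 2], height = H,
          dbh = max(5, rnorm(1, p$dbh_mean, p$dbh_sd)),
          taper_k = p$taper_k, crown_shape = p$crown_shape,
          crown_base = hb,
          crown_radius = max(0.4, rnorm(1, p$crown_radius_mean,
                                        p$crown_radius_sd)),
          crown_density = p$crown_density, stem_density = p$stem_density,
          noise_sd = p$noise_sd)
      }
      clouds <- vector("list", n)
      rows <- vector("list", n)
      for (i in seq_len(n)) {
        m <- models[[i]]
        pts <- generate_tree(m, include_ground = FALSE,
                             base_z = gfun(m$x, m$y))
        pts$tree <- i
        clouds[[i]] <- pts
        tr <- oracle_traits(m)
        rows[[i]] <- dplyr::bind_cols(
          tibble::tibble(tree = i, site = spec$site, plot = spec$plot,
                         treatment = spec$treatment,
                         x = m$x, y = m$y, height = m$height, dbh = m$dbh,
                         crown_base = m$crown_base,
                         crown_radius = m$crown_radius,
                         crown_max_height = m$crown_max_height),
          tr$crown,
          dplyr::rename(tr$stem, oracle_height = "height",
                        oracle_dbh = "dbh"))
      }
      truth <- dplyr::bind_rows(rows)
      for (gname in names(spec$growth_model)) {
        cf <- spec$growth_model[[gname]]
        truth[[gname]] <- cf[["a"]] + cf[["b"]] * truth$sahmc +
          rnorm(n, 0, cf[["sd"]])
      }
      cloud <- dplyr::bind_rows(cloud, dplyr::bind_rows(clouds))
    }
    realized <- n / area_ha
    if (spec$density > 0 && abs(realized - spec$density) > 0.1 * spec$density)
      stop("realized density deviates more than 10% from target")
    list(cloud = cloud, truth = truth)
  })
}

# jittered-grid placement honouring the minimum spacing; errors when the
# spacing constraint makes the target density unreachable on the plot
place_trees <- function(n, width, height, min_spacing) {
  nx <- max(1L, ceiling(sqrt(n * width / height)))
  ny <- ceiling(n / nx)
  px <- width / nx; py <- height / ny
  if (min(px, py) < min_spacing)
    stop(sprintf(paste0(
      "cannot place %d trees on a %.0f x %.0f m plot under the ",
      "minimum-spacing constraint (%.2f m): grid pitch would be %.2f m"),
      n, width, height, min_spacing, min(px, py)), call. = FALSE)
  jx <- (px - min_spacing) / 2
  jy <- (py - min_spacing) / 2
  cells <- sample(nx * ny, n)
  cx <- ((cells - 1) %% nx) + 0.5
  cy <- ((cells - 1) %/% nx) + 0.5
  cbind(x = cx * px + runif(n, -jx, jx),
        y = cy * py + runif(n, -jy, jy))
}
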