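#' Fit the nested two-level mixed model for a trait
#'
#' Fits, by REML, the treatment cell-means model
#' `trait ~ 0 + treatment + (1 | site) + (1 | site:plot)`: one fixed mean
#' per thinning treatment and random intercepts for the study site and the
#' plot within site, whose variances carry the between-site and
#' between-plot effects. Non-convergence is flagged on the returned object,
#' not raised; a site with a single plot is an error because the plot
#' variance is then unidentifiable.
#'
#' @param table trait table: one row per tree with columns `site`, `plot`,
#'   `treatment` and the trait.
#' @param trait name of the trait column to model.
#' @return A `crownarch_lmm` object: the `lmerTest` fit plus convergence
#'   and singularity flags. Methods: [tidy()], [glance()],
#'   [tukey_contrasts()].
#' @export
fit_nested_lmm <- function(table, trait) {
  stopifnot(is.data.frame(table))
  need <- c("site", "plot", "treatment", trait)
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("trait table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab <- dplyr::filter(table, !is.na(.data[[trait]]))
  tab$site <- factor(tab$site)
  tab$plot <- factor(tab$plot)
  tab$treatment <- factor(tab$treatment)
  if (nlevels(tab$site) < 2)
    stop("need at least 2 sites", call. = FALSE)
  plots_per_site <- tapply(tab$plot, tab$site,
                           function(p) length(unique(p)))
  if (any(plots_per_site < 2))
    stop("site(s) with a single plot: ",
         paste(names(plots_per_site)[plots_per_site < 2], collapse = ", "),
         call. = FALSE)
  fml <- stats::as.formula(
    sprintf("`%s` ~ 0 + treatment + (1 | site) + (1 | site:plot)", trait))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(fml, data = tab, REML = TRUE,
                   control = lme4::lmerControl(
                     optimizer = "bobyqa",
                     check.conv.singular = "ignore"))))
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  structure(list(
    model = fit,
    trait = trait,
    converged = length(msgs) == 0,
    singular = lme4::isSingular(fit),
    messages = msgs,
    data = tab
  ), class = "crownarch_lmm")
}

#' @export
print.crownarch_lmm <- function(x, ...) {
  cat(sprintf("<crownarch_lmm> trait `%s`, %d trees, %d treatments%s\n",
              x$trait, nrow(x$data), nlevels(x$data$treatment),
              if (!x$converged) " [convergence flagged]" else ""))
  print(tidy(x))
  invisible(x)
}

#' Tidy the fixed treatment effects of a nested LMM
#'
#' @param x a `crownarch_lmm`.
#' @param ... unused.
#' @return Tibble: `term`, `estimate`, `std.error`, `df` (Satterthwaite),
#'   `statistic`, `p.value`.
#' @export
tidy.crownarch_lmm <- function(x, ...) {
  co <- as.data.frame(summary(x$model)$coefficients)
  tibble::tibble(
    term = sub("^treatment", "", rownames(co)),
    estimate = co$Estimate,
    std.error = co$`Std. Error`,
    df = co$df,
    statistic = co$`t value`,
    p.value = co$`Pr(>|t|)`
  )
}

#' Variance components and fit summary of a nested LMM
#'
#' @param x a `crownarch_lmm`.
#' @param ... unused.
#' @return One-row tibble: `var_site`, `var_plot`, `var_residual`,
#'   `logLik`, `nobs`, `converged`, `singular`.
#' @export
glance.crownarch_lmm <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$model))
  pick <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  tibble::tibble(
    var_site = pick("site"),
    var_plot = pick("site:plot"),
    var_residual = pick("Residual"),
    logLik = as.numeric(logLik(x$model)),
    nobs = nrow(x$data),
    converged = x$converged,
    singular = x$singular
  )
}

#' Tukey all-pairwise treatment contrasts
#'
#' All pairwise differences between the fitted treatment means with
#' single-step (multivariate-t) family-wise adjustment computed from the
#' fixed-effect covariance of the mixed model — the honest-significant-
#' difference test carried out on the LMM rather than on raw group means.
#'
#' @param fit a `crownarch_lmm` from [fit_nested_lmm()].
#' @param alpha significance level for the `significant` flag.
#' @return Tibble with one row per unordered treatment pair:
#'   `treatment_1`, `treatment_2`, `estimate` (mean 1 minus mean 2),
#'   `std.error`, `statistic`, `adj.p.value`, `significant`.
#' @export
tukey_contrasts <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "crownarch_lmm"))
  if (!fit$converged)
    stop("Tukey contrasts need a converged fit", call. = FALSE)
  levs <- levels(fit$data$treatment)
  k <- length(levs)
  pairs <- utils::combn(k, 2)
  K <- matrix(0, ncol(pairs), k,
              dimnames = list(NULL, paste0("treatment", levs)))
  for (j in seq_len(ncol(pairs))) {
    K[j, pairs[1, j]] <- 1
    K[j, pairs[2, j]] <- -1
  }
  rownames(K) <- sprintf("%s - %s", levs[pairs[1, ]], levs[pairs[2, ]])
  # Satterthwaite denominator df for the contrasts (balanced designs give
  # essentially one shared value); the multivariate t with these df keeps
  # the family-wise error calibrated where the normal reference is
  # anticonservative at few plots
  probe <- unique(round(seq(1, nrow(K), length.out = 3)))
  dfs <- vapply(probe, function(j) {
    out <- tryCatch(lmerTest::contest1D(fit$model, K[j, ]),
                    error = function(e) NULL)
    if (is.null(out)) NA_real_ else out$df
  }, numeric(1))
  df_use <- stats::median(dfs, na.rm = TRUE)
  gl <- if (is.finite(df_use) && df_use > 1)
    multcomp::glht(fit$model, linfct = K, df = max(2L, round(df_use)))
  else multcomp::glht(fit$model, linfct = K)
  # single-step multivariate-t adjustment; mvtnorm occasionally reports
  # its integration tolerance, which is far below any decision threshold
  sm <- suppressWarnings(summary(gl))
  tibble::tibble(
    treatment_1 = levs[pairs[1, ]],
    treatment_2 = levs[pairs[2, ]],
    estimate = as.numeric(sm$test$coefficients),
    std.error = as.numeric(sm$test$sigma),
    statistic = as.numeric(sm$test$tstat),
    adj.p.value = as.numeric(sm$test$pvalues),
    significant = as.numeric(sm$test$pvalues) < alpha
  )
}

#' Screen traits against SAHMC
#'
#' For every trait column: Pearson and Spearman correlation with SAHMC
#' (two-sided tests), and the slope of the nested mixed model with the
#' trait as the single fixed predictor of SAHMC (random structure
#' unchanged; Satterthwaite p-value). When the random-effect and residual
#' variance collapse to zero (e.g. exactly collinear traits) the slope
#' falls back to ordinary least squares, noted in the output. Zero-variance
#' traits are reported with `NA` coefficients.
#'
#' @param table trait table with `site`, `plot`, `treatment`, a `sahmc`
#'   column (or `response`) and trait columns.
#' @param traits character vector of trait columns to screen; default all
#'   numeric columns except ids and the response.
#' @param response name of the response column.
#' @return Tibble: one row per trait with correlation coefficients,
#'   p-values, model slope, its standard error and p-value, `n`, `note`.
#' @export
trait_screen <- function(table, traits = NULL, response = "sahmc") {
  stopifnot(is.data.frame(table), response %in% names(table))
  if (is.null(traits)) {
    num <- names(table)[vapply(table, is.numeric, logical(1))]
    traits <- setdiff(num, c(response, "tree", "x", "y"))
  }
  y <- table[[response]]
  rows <- lapply(traits, function(tr) {
    v <- table[[tr]]
    ok <- complete.cases(v, y)
    n <- sum(ok)
    out <- tibble::tibble(trait = tr, pearson_r = NA_real_,
                          pearson_p = NA_real_, spearman_rho = NA_real_,
                          spearman_p = NA_real_, slope = NA_real_,
                          slope_se = NA_real_, slope_p = NA_real_,
                          n = n, note = NA_character_)
    if (n < 3 || sd(v[ok]) == 0 || sd(y[ok]) == 0) {
      out$note <- "zero variance or too few complete pairs"
      return(out)
    }
    pe <- cor.test(v[ok], y[ok], method = "pearson")
    sp <- suppressWarnings(cor.test(v[ok], y[ok], method = "spearman",
                                    exact = FALSE))
    out$pearson_r <- unname(pe$estimate)
    out$pearson_p <- pe$p.value
    out$spearman_rho <- unname(sp$estimate)
    out$spearman_p <- sp$p.value
    dat <- table[ok, c("site", "plot", response, tr)]
    names(dat) <- c("site", "plot", ".y", ".x")
    sl <- tryCatch(suppressWarnings({
      m <- suppressMessages(lmerTest::lmer(
        .y ~ .x + (1 | site) + (1 | site:plot), data = dat, REML = TRUE,
        control = lme4::lmerControl(check.conv.singular = "ignore",
                                    calc.derivs = FALSE)))
      co <- summary(m)$coefficients
      if (anyNA(co[".x", c("Estimate", "Std. Error")]))
        stop("degenerate mixed-model fit")
      list(est = co[".x", "Estimate"], se = co[".x", "Std. Error"],
           p = co[".x", "Pr(>|t|)"], note = NA_character_)
    }), error = function(e) {
      m <- stats::lm(.y ~ .x, data = dat)
      co <- suppressWarnings(summary(m)$coefficients)
      list(est = co[".x", "Estimate"], se = co[".x", "Std. Error"],
           p = co[".x", "Pr(>|t|)"], note = "ols fallback")
    })
    out$slope <- sl$est
    out$slope_se <- sl$se
    out$slope_p <- sl$p
    out$note <- sl$note
    out
  })
  dplyr::bind_rows(rows)
}

#' Simulate a trait table from the nested two-level model
#'
#' Draws a balanced nested design — sites, plots within sites (treatments
#' assigned to plots in rotation) and trees within plots — from the same
#' generative model the analysis fits: per-treatment fixed means plus
#' Gaussian site, plot-within-site and residual effects. Optionally adds a
#' SAHMC-linked set of growth columns (`growth = a + b sahmc + noise`,
#' see [default_growth_model()]) for screening experiments; the simulated
#' trait column is then named `sahmc`.
#'
#' @param n_sites,plots_per_site,trees_per_plot design dimensions; the
#'   default 3 x 9 x 25 mirrors a three-site thinning trial with nine
#'   plots per site.
#' @param treatment_means named vector of the 7 treatment means (any
#'   subset of treatments is allowed).
#' @param var_site,var_plot,var_resid variance components.
#' @param trait name of the simulated trait column.
#' @param growth_model `NULL`, or a growth coefficient list as in
#'   [default_growth_model()] to append growth columns.
#' @param seed integer seed.
#' @return Tibble: `site`, `plot`, `treatment`, the trait column (and any
#'   growth columns), plus attribute `effects` holding the drawn site and
#'   plot effects.
#' @export
simulate_trait_table <- function(n_sites = 3, plots_per_site = 9,
                                 trees_per_plot = 25,
                                 treatment_means = c(
                                   moderate_below = 90, moderate_above = 91,
                                   moderate_systematic = 91,
                                   intensive_below = 132,
                                   intensive_above = 130,
                                   intensive_systematic = 131, none = 88),
                                 var_site = 1, var_plot = 0.5,
                                 var_resid = 4,
                                 trait = "sahmc", growth_model = NULL,
                                 seed = NULL) {
  treatments <- names(treatment_means)
  with_seed(seed, {
    rows <- list()
    site_eff <- rnorm(n_sites, 0, sqrt(var_site))
    for (s in seq_len(n_sites)) {
      trt_of_plot <- rep(treatments, length.out = plots_per_site)
      plot_eff <- rnorm(plots_per_site, 0, sqrt(var_plot))
      for (p in seq_len(plots_per_site)) {
        mu <- treatment_means[[trt_of_plot[p]]] + site_eff[s] + plot_eff[p]
        rows[[length(rows) + 1]] <- tibble::tibble(
          site = sprintf("S%d", s),
          plot = sprintf("S%d_P%d", s, p),
          treatment = trt_of_plot[p],
          value = mu + rnorm(trees_per_plot, 0, sqrt(var_resid)))
      }
    }
    tab <- dplyr::bind_rows(rows)
    names(tab)[names(tab) == "value"] <- trait
    if (!is.null(growth_model)) {
      for (g in names(growth_model)) {
        cf <- growth_model[[g]]
        tab[[g]] <- cf[["a"]] + cf[["b"]] * tab[[trait]] +
          rnorm(nrow(tab), 0, cf[["sd"]])
      }
    }
    attr(tab, "effects") <- list(site = site_eff)
    tab
  })
}
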