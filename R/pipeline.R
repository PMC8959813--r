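#' Pipeline configuration
#'
#' All stage parameters in one nested list, serializable to YAML. Unknown
#' keys are rejected so typos never silently fall back to defaults.
#'
#' @param ... named overrides of the defaults, nested as in the returned
#'   list (e.g. `chm = list(cell = 0.25)`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    out_dir = "crownarch_run",
    input = list(paths = character()),       # existing clouds, or empty
    simulate = list(
      sites = c("S1", "S2", "S3"),
      treatments = treatment_levels(),
      density = NULL,                        # per-treatment default
      tree_params = list(),
      ground_amplitude = 0.2,
      ground_density = 80
    ),
    dtm = list(cell = 0.5),
    chm = list(cell = 0.2, min_height = 2, pit_filter = TRUE),
    vwf = list(min_height = 2),
    classify = stem_classify_params(),
    traits = list(n_slices = 10, slice_method = "count", min_points = 100),
    analyze = list(
      traits = c("sahmc", "crown_volume", "projection_area",
                 "max_crown_diameter", "live_crown_ratio", "dbh"),
      alpha = 0.05
    )
  )
  override <- list(...)
  check_config_keys(override, defaults, "config")
  cfg <- utils::modifyList(defaults, override)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

check_config_keys <- function(override, defaults, path) {
  bad <- setdiff(names(override), names(defaults))
  if (length(bad))
    stop(sprintf("unknown %s key(s): %s", path, paste(bad, collapse = ", ")),
         call. = FALSE)
  for (k in names(override)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
          is.list(override[[k]]) && k != "tree_params")
      check_config_keys(override[[k]], defaults[[k]],
                        paste(path, k, sep = "$"))
  }
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()].
#' @return A validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the TLS crown-architecture pipeline
#'
#' Orchestrates the stages end to end: `simulate` synthetic plots (or read
#' input clouds), `normalize` heights against a DTM, `segment` individual
#' trees via CHM + variable window filter + watershed, `classify` stem
#' vs crown points, compute per-tree `traits`, and `analyze` the study
#' with nested mixed models, Tukey contrasts and the SAHMC trait screen.
#' Each stage writes its artifacts under `config$out_dir` so stages are
#' independently inspectable; a run log records parameters and seed.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run, in pipeline order.
#' @param quiet suppress progress messages?
#' @return Invisibly, a list with the trait table and (when `analyze` ran)
#'   the model fits, contrasts and screen.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "normalize", "segment",
                                    "classify", "traits", "analyze"),
                         quiet = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "run.log")
  say <- function(...) {
    msg <- sprintf(...)
    cat(format(Sys.time(), "%H:%M:%S "), msg, "\n", sep = "", file = logf,
        append = TRUE)
    if (!quiet) message(msg)
  }
  say("crownarch %s | seed %d", as.character(utils::packageVersion("crownarch")),
      config$seed)
  say("config: %s", paste(deparse(config, control = NULL), collapse = ""))

  plots <- list()  # per-plot cloud paths
  truth_all <- list()
  if ("simulate" %in% stages) {
    sim <- config$simulate
    i <- 0
    for (s in sim$sites) for (trt in sim$treatments) {
      i <- i + 1
      spec <- stand_spec(
        treatment = trt, density = sim$density,
        tree_params = sim$tree_params,
        ground_amplitude = sim$ground_amplitude,
        ground_density = sim$ground_density,
        site = s, plot = sprintf("%s_%s", s, trt),
        seed = config$seed + i)
      st <- generate_stand(spec)
      id <- spec$plot
      cloud_path <- file.path(out, sprintf("%s_cloud.xyz", id))
      write_point_cloud(dplyr::select(st$cloud, -"tree"), cloud_path)
      truth_all[[id]] <- st$truth
      plots[[id]] <- list(path = cloud_path, site = s, plot = id,
                          treatment = trt)
      say("simulated %s: %d trees, %d points", id, nrow(st$truth),
          nrow(st$cloud))
    }
    if (length(truth_all))
      write_csv_file(dplyr::bind_rows(truth_all),
                     file.path(out, "ground_truth.csv"))
  } else {
    if (!length(config$input$paths))
      stop("no input clouds configured and `simulate` not requested",
           call. = FALSE)
    for (p in config$input$paths) {
      if (!file.exists(p)) stop("input cloud not found: ", p, call. = FALSE)
      id <- tools::file_path_sans_ext(basename(p))
      plots[[id]] <- list(path = p, site = "S1", plot = id,
                          treatment = "none")
    }
  }

  trait_rows <- list()
  for (id in names(plots)) {
    meta <- plots[[id]]
    pc <- read_point_cloud(meta$path)
    if ("normalize" %in% stages) {
      dtm <- build_dtm(pc, cell = config$dtm$cell)
      pc <- normalize_heights(pc, dtm)
      write_point_cloud(pc, file.path(out, sprintf("%s_norm.xyz", id)))
      say("%s: normalized %d points", id, nrow(pc))
    }
    if (!("segment" %in% stages)) next
    chm <- rasterize_chm(pc, cell = config$chm$cell,
                         min_height = config$chm$min_height,
                         pit_filter = config$chm$pit_filter)
    tops <- detect_treetops(chm, min_height = config$vwf$min_height)
    segs <- watershed_crowns(chm, tops, min_height = config$vwf$min_height)
    pc <- assign_points(pc, segs)
    write_ascii_grid(chm, file.path(out, sprintf("%s_chm.asc", id)))
    write_csv_file(tops, file.path(out, sprintf("%s_treetops.csv", id)))
    say("%s: %d treetops", id, nrow(tops))
    if (!("classify" %in% stages)) next
    for (tid in sort(setdiff(unique(pc$tree), 0L))) {
      sel <- which(pc$tree == tid & pc$label != LABEL_GROUND)
      if (length(sel) < config$classify$min_points) next
      cl <- classify_stem_points(pc[sel, ], params = config$classify)
      pc$label[sel] <- cl$points$label
    }
    write_point_cloud(pc, file.path(out, sprintf("%s_classified.xyz", id)))
    if (!("traits" %in% stages)) next
    tt <- tree_traits(dplyr::filter(pc, .data$label != LABEL_GROUND),
                      min_points = config$traits$min_points)
    tt <- dplyr::mutate(tt, site = meta$site, plot = meta$plot,
                        treatment = meta$treatment, .before = 1)
    trait_rows[[id]] <- tt
    say("%s: traits for %d trees", id, nrow(tt))
  }

  traits_tab <- dplyr::bind_rows(trait_rows)
  if (nrow(traits_tab))
    write_csv_file(traits_tab, file.path(out, "tree_traits.csv"))

  analysis <- NULL
  if ("analyze" %in% stages) {
    tab <- if (nrow(traits_tab)) traits_tab
    else read_csv_file(file.path(out, "tree_traits.csv"))
    analysis <- analyze_traits(tab, traits = config$analyze$traits,
                               alpha = config$analyze$alpha)
    for (tr in names(analysis$fits)) {
      write_csv_file(tidy(analysis$fits[[tr]]),
                     file.path(out, sprintf("lmm_%s.csv", tr)))
      write_csv_file(analysis$tukey[[tr]],
                     file.path(out, sprintf("tukey_%s.csv", tr)))
    }
    if (!is.null(analysis$screen))
      write_csv_file(analysis$screen, file.path(out, "trait_screen.csv"))
    writeLines(analysis$report, file.path(out, "report.txt"))
    say("analysis written for %d trait(s)", length(analysis$fits))
  }
  invisible(list(traits = traits_tab, analysis = analysis,
                 out_dir = out))
}

#' Mixed-model analysis of a trait table
#'
#' Fits the nested treatment model for each requested trait, computes the
#' Tukey contrasts and, when a `sahmc` column is present, the trait
#' screen. Traits that fail to fit are skipped with a note in the report.
#'
#' @param table trait table (`site`, `plot`, `treatment`, trait columns).
#' @param traits trait columns to model.
#' @param alpha significance level.
#' @return List: `fits`, `tukey`, `screen`, `report` (character lines).
#' @export
analyze_traits <- function(table,
                           traits = c("sahmc", "crown_volume"),
                           alpha = 0.05) {
  fits <- list(); tukey <- list(); report <- character()
  for (tr in intersect(traits, names(table))) {
    res <- tryCatch({
      fit <- fit_nested_lmm(table, tr)
      list(fit = fit, tk = tukey_contrasts(fit, alpha = alpha))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      report <- c(report, sprintf("%s: model skipped (%s)", tr, res))
      next
    }
    fits[[tr]] <- res$fit
    tukey[[tr]] <- res$tk
    g <- glance(res$fit)
    report <- c(report,
                sprintf("%s: var(site) %.3g, var(plot) %.3g, var(resid) %.3g; %d/%d Tukey pairs significant at %.2f",
                        tr, g$var_site, g$var_plot, g$var_residual,
                        sum(res$tk$significant), nrow(res$tk), alpha))
  }
  screen <- NULL
  if ("sahmc" %in% names(table)) {
    screen <- tryCatch(trait_screen(table), error = function(e) NULL)
    if (!is.null(screen))
      report <- c(report, sprintf(
        "trait screen: %d traits against SAHMC, %d with |Pearson r| >= 0.5",
        nrow(screen), sum(abs(screen$pearson_r) >= 0.5, na.rm = TRUE)))
  }
  list(fits = fits, tukey = tukey, screen = screen, report = report)
}

write_csv_file <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

read_csv_file <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
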