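#' Pipeline configuration with standard defaults
#'
#' One declarative object holding every constant of the analysis, at its
#' standard value: 25 km clustering cut, minimum of 8 individuals per
#' cluster, candidate nonhabitat resistances {5, 10, 20} then
#' {50, 100, 200} with a 0.7 correlation limit, 1.2 km analysis
#' resolution, and Monte Carlo cross-validation with 100 iterations, 80%
#' training fraction and 5 differentiation bins. All values can be
#' overridden; a YAML file with any subset of the fields can stand in for
#' the argument list.
#'
#' @param cluster_cut clustering cut distance (m).
#' @param min_individuals minimum individuals per retained cluster.
#' @param low_set,high_set candidate nonhabitat resistance values.
#' @param corr_limit decorrelation threshold for resistance-value search.
#' @param target_resolution analysis cell size (m).
#' @param cv_iterations,cv_train_fraction,cv_bins cross-validation
#'   settings.
#' @param neighborhood circuit graph stencil (4 or 8).
#' @param statistic differentiation statistic for the response.
#' @param seed seed for the stochastic stages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cluster_cut = 25000, min_individuals = 8,
                            low_set = c(5, 10, 20),
                            high_set = c(50, 100, 200), corr_limit = 0.7,
                            target_resolution = 1200,
                            cv_iterations = 100, cv_train_fraction = 0.8,
                            cv_bins = 5, neighborhood = 8,
                            statistic = "gst_prime", seed = 1) {
  structure(list(cluster_cut = cluster_cut,
                 min_individuals = min_individuals, low_set = low_set,
                 high_set = high_set, corr_limit = corr_limit,
                 target_resolution = target_resolution,
                 cv_iterations = cv_iterations,
                 cv_train_fraction = cv_train_fraction, cv_bins = cv_bins,
                 neighborhood = neighborhood, statistic = statistic,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; unknown keys are an error, missing keys take the
#'   defaults of [pipeline_config].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}

#' Run the landscape-genetics pipeline end to end
#'
#' Chains every stage on one management zone: lek clustering of sampling
#' locations and the minimum-sample filter; pairwise differentiation;
#' candidate resistance surfaces per variable with the resistance-value
#' decorrelation search; circuit-theory pairwise resistances and the
#' geographic null; within-variable selection with the two-model
#' significance rule; the between-variable AICc table including the
#' additive combined landscape surface; Monte Carlo cross-validation of
#' the top surface; and the all-to-one current-flow map.
#'
#' @param genotypes a [genotype_table] (or a path readable by
#'   [read_genotypes]).
#' @param variables named list, one entry per predictor variable:
#'   `list(raster =, thresholds =, direction =, threshold_mode =,
#'   kind = "landscape"|"habitat")`. Rasters must share one grid (the
#'   common mask defines the study extent).
#' @param config a [pipeline_config].
#' @param outdir optional output directory; when given, every artifact is
#'   written (CSV/ASCII grid) together with a JSON provenance sidecar
#'   carrying the configuration and seed.
#' @return list of stage artifacts: `clusters`, `genotypes`, `y`,
#'   `geo_null`, `resistance_values`, `within`, `between`, `cv`, `flow`,
#'   `log` (character vector narrating each decision).
#' @export
run_pipeline <- function(genotypes, variables, config = pipeline_config(),
                         outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message(msg)
  }
  if (is.character(genotypes)) genotypes <- read_genotypes(genotypes)
  stopifnot(inherits(genotypes, "genotype_table"))
  if (!length(variables) || is.null(names(variables)))
    stop("variables must be a named list", call. = FALSE)
  base <- variables[[1]]$raster
  for (v in names(variables)) {
    if (!inherits(variables[[v]]$raster, "lg_raster"))
      stop("unknown or malformed variable: ", v, call. = FALSE)
    if (!same_grid(base, variables[[v]]$raster))
      stop("variable rasters are not on one grid: ", v, call. = FALSE)
  }

  # --- QC + clustering ---------------------------------------------------
  gt <- qc_filter(genotypes)
  say("QC: %d of %d individuals retained", nrow(gt), nrow(genotypes))
  pts <- data.frame(id = gt$individual_id, x = gt$x, y = gt$y)
  cl <- cluster_locations(geographic_distances(pts),
                          cut = config$cluster_cut, points = pts)
  gt <- assign_clusters(gt, cl)
  gt <- filter_clusters(gt, config$min_individuals)
  cents <- cluster_centroids(gt)
  say("clustering: %d clusters of >= %d individuals at %g km cut",
      nrow(cents), config$min_individuals, config$cluster_cut / 1000)
  if (nrow(cents) < 3L)
    stop("pipeline needs at least three retained clusters", call. = FALSE)

  # --- differentiation ---------------------------------------------------
  freqs <- allele_frequencies(gt, "cluster")
  y <- pairwise_differentiation(freqs, config$statistic)

  # --- node sets from cluster member locations ---------------------------
  node_sets <- lapply(split(gt, gt$cluster_id), function(s)
    unique(raster_cell_of(base, s$x, s$y)))
  node_sets <- node_sets[rownames(y)]

  geo_null <- null_distance_matrix(base, node_sets,
                                   neighborhood = config$neighborhood)

  # --- resistance values + candidate matrices per variable ---------------
  within <- list(); best_mats <- list(); rvals <- list()
  for (v in names(variables)) {
    spec <- variables[[v]]
    sel <- select_resistance_values(
      rasters_by_zone = list(zone = spec$raster),
      nodes_by_zone = list(zone = node_sets),
      thresholds = spec$thresholds, direction = spec$direction,
      threshold_mode = spec$threshold_mode %||% "absolute",
      low_set = config$low_set, high_set = config$high_set,
      corr_limit = config$corr_limit,
      neighborhood = config$neighborhood)
    rvals[[v]] <- sel
    say("%s: nonhabitat resistances %g / %g", v, sel$r_low, sel$r_high)
    cands <- list()
    surfs <- list()
    for (th in spec$thresholds) for (r in c(sel$r_low, sel$r_high)) {
      thv <- if (identical(spec$threshold_mode, "percentile"))
        percentile_threshold(spec$raster, th) else th
      s <- threshold_surface(spec$raster, thv, spec$direction, r, v)
      g <- build_graph(s, neighborhood = config$neighborhood)
      nm <- sprintf("%s_t%g_r%g", v, th, r)
      cands[[nm]] <- effective_resistance_pairwise(g, node_sets)
      surfs[[nm]] <- s
    }
    w <- within_variable_selection(y, cands, geo_null)
    say("%s: best surface %s (dAIC vs distance %.2f, significant: %s)",
        v, w$best, w$delta_AIC_vs_distance,
        w$significance$significant)
    w$surface <- surfs[[w$best]]
    within[[v]] <- w
    best_mats[[v]] <- cands[[w$best]]
  }

  # --- combined additive landscape surface -------------------------------
  kind <- vapply(variables, function(s) s$kind %||% "landscape",
                 character(1))
  sig_land <- names(variables)[kind == "landscape" &
    vapply(within, function(w) isTRUE(w$significance$significant),
           logical(1))]
  between_cands <- best_mats
  if (length(sig_land) >= 2L) {
    landsum <- combine_surfaces(lapply(within[sig_land], `[[`, "surface"))
    g <- build_graph(landsum, neighborhood = config$neighborhood)
    between_cands$landsum <- effective_resistance_pairwise(g, node_sets)
    say("combined additive surface built from: %s",
        paste(sig_land, collapse = ", "))
  }
  between <- between_variable_selection(y, between_cands, geo_null)
  top <- between$model[1]
  say("between-variable top model: %s (weight %.3f)", top,
      between$weight[1])

  # --- validation + flow map ---------------------------------------------
  top_mat <- if (top == "distance") best_mats[[1]] else
    between_cands[[top]]
  cv <- monte_carlo_cv(y, top_mat, geo_null,
                       iterations = config$cv_iterations,
                       train_fraction = config$cv_train_fraction,
                       n_bins = config$cv_bins, seed = config$seed)
  top_surface <- if (top == "landsum") {
    combine_surfaces(lapply(within[sig_land], `[[`, "surface"))
  } else if (top %in% names(within)) {
    within[[top]]$surface
  } else {
    within[[1]]$surface
  }
  flow <- all_to_one_flow(build_graph(top_surface,
                                      neighborhood = config$neighborhood),
                          node_sets)

  res <- list(clusters = cents, genotypes = gt, y = y,
              geo_null = geo_null, resistance_values = rvals,
              within = within, between = between, cv = cv, flow = flow,
              node_sets = node_sets, config = config, log = log)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

raster_cell_of <- function(raster, x, y) {
  nr <- nrow(raster$values)
  col <- pmin(pmax(ceiling((x - raster$xll) / raster$cell_size), 1L),
              ncol(raster$values))
  row <- pmin(pmax(nr - ceiling((y - raster$yll) / raster$cell_size) + 1L,
                   1L), nr)
  as.integer(row + (col - 1L) * nr)
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- jsonlite::toJSON(unclass(res$config), auto_unbox = TRUE)
  writeLines(cfg_json, file.path(outdir, "config.json"))
  hash <- unname(tools::md5sum(file.path(outdir, "config.json")))
  prov <- list(config_hash = hash, seed = res$config$seed,
               package_version = as.character(
                 utils::packageVersion("lgflow")))
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE),
             file.path(outdir, "provenance.json"))
  utils::write.csv(res$clusters, file.path(outdir, "clusters.csv"),
                   row.names = FALSE)
  write_pairwise_csv(res$y, file.path(outdir, "differentiation.csv"))
  write_pairwise_csv(res$geo_null, file.path(outdir, "geo_null.csv"))
  utils::write.csv(res$between, file.path(outdir, "model_table.csv"),
                   row.names = FALSE)
  utils::write.csv(res$cv$summary, file.path(outdir, "cv_summary.csv"),
                   row.names = FALSE)
  write_ascii_grid(res$flow, file.path(outdir, "flow_map.asc"))
  writeLines(res$log, file.path(outdir, "pipeline.log"))
  invisible(outdir)
}
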