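# End-to-end pipeline: simulate -> classify -> fit/select -> evaluate.
# Each stage reads and writes conventional file names under the run
# directory, logs one structured line with counts, and is idempotent
# given fixed inputs and seeds.

#' Pipeline run configuration
#'
#' @param out_dir run directory (created if missing).
#' @param species `"speckled_hind"` or `"warsaw_grouper"`.
#' @param seed integer seed driving every stochastic stage.
#' @param sim named list of overrides for [sim_config()].
#' @param k,n_repeats,stratified cross-validation settings.
#' @param specs candidate list; default [candidate_specs()].
#' @param gear standardization gear for prediction surfaces.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(out_dir, species = c("speckled_hind",
                                            "warsaw_grouper"),
                       seed = 1, sim = list(), k = 10, n_repeats = 10,
                       stratified = FALSE, specs = candidate_specs(),
                       gear = REFERENCE_GEAR) {
  species <- match.arg(species)
  cfg <- list(out_dir = out_dir, species = species, seed = seed, sim = sim,
              k = k, n_repeats = n_repeats, stratified = stratified,
              specs = specs, gear = gear)
  class(cfg) <- "run_config"
  cfg
}

run_path <- function(config, file) file.path(config$out_dir, file)

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Simulate a full synthetic input set
#'
#' Writes `grid.csv`, `observations.csv`, `reserves.geojson`,
#' `ground_truth.json` and a `manifest.json` (seed and configuration
#' hash) to the run directory.
#'
#' @param config a [run_config()].
#' @return the list from [synthetic_dataset()], invisibly.
#' @export
run_simulate <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_args <- c(list(seed = config$seed, species = config$species),
                config$sim)
  ds <- do.call(synthetic_dataset, sim_args)
  write_grid_csv(ds$grid, run_path(config, "grid.csv"))
  write_observations(ds$observations, run_path(config, "observations.csv"))
  write_reserves_geojson(ds$reserves, run_path(config, "reserves.geojson"))
  writeLines(jsonlite::toJSON(ds$truth, auto_unbox = TRUE, digits = NA),
             run_path(config, "ground_truth.json"))
  manifest <- list(seed = config$seed, species = config$species,
                   config_hash = config_hash(config$sim),
                   n_cells = nrow(ds$grid),
                   n_events = nrow(ds$observations),
                   n_reserves = length(ds$reserves))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE),
             run_path(config, "manifest.json"))
  log_stage("simulate", "%d cells, %d events, %d reserves -> %s",
            nrow(ds$grid), nrow(ds$observations), length(ds$reserves),
            config$out_dir)
  invisible(ds)
}

#' Classify the grid and summarize habitat class areas
#'
#' Reads `grid.csv` and `observations.csv`, applies the four-way habitat
#' classification over the 25-100 fathom analysis band, and writes
#' `classification.csv` plus `class_summary.json`.
#'
#' @param config a [run_config()].
#' @return the classified cell data frame, invisibly.
#' @export
run_classify <- function(config) {
  grid <- read_grid_csv(run_path(config, "grid.csv"))
  obs <- read_observations(run_path(config, "observations.csv"))
  cells <- filter_analysis_domain(grid)
  cells <- classify_grid(cells, obs)
  write_grid_csv(cells, run_path(config, "classification.csv"))
  summary <- summarize_area_by_class(cells)
  writeLines(jsonlite::toJSON(summary, dataframe = "columns",
                              digits = NA),
             run_path(config, "class_summary.json"))
  for (i in seq_len(nrow(summary)))
    log_stage("classify", "%-12s %9.1f km2 (%5.1f%%)", summary$class[i],
              summary$area_km2[i], 100 * summary$fraction[i])
  invisible(cells)
}

#' Fit and rank the candidate models; predict surfaces
#'
#' Reads the observations and classified grid, fits and cross-validates
#' the candidate set, and writes `candidate_ranking.csv`,
#' `best_xval.json` / `best_aic.json`, and per-cell probability surfaces
#' `surface_xval.csv` / `surface_aic.csv` over the species' restricted
#' domain.
#'
#' @param config a [run_config()].
#' @return the [rank_candidates()] result, invisibly.
#' @export
run_fit_select <- function(config) {
  obs <- read_observations(run_path(config, "observations.csv"))
  cells <- read_grid_csv(run_path(config, "classification.csv"))
  if (config$species == "warsaw_grouper")
    obs <- obs[obs$lat > 28, , drop = FALSE]
  ranking <- rank_candidates(obs, specs = config$specs, k = config$k,
                             n_repeats = config$n_repeats,
                             seed = config$seed,
                             stratified = config$stratified)
  utils::write.csv(ranking$table,
                   run_path(config, "candidate_ranking.csv"),
                   row.names = FALSE)
  domain_cells <- restrict_domain(cells, config$species)
  for (which in c("xval", "aic")) {
    idx <- if (which == "xval") ranking$best$best_by_cv
           else ranking$best$best_by_aic
    fit <- ranking$fits[[idx]]
    write_fitted_json(fit, run_path(config, paste0("best_", which, ".json")))
    surf <- predict_surface(fit, domain_cells, gear = config$gear,
                            check_domain = FALSE)
    utils::write.csv(surf, run_path(config,
                                    paste0("surface_", which, ".csv")),
                     row.names = FALSE)
  }
  log_stage("fit-select",
            "%d candidates on %d events; best by CV: %s; best by AIC: %s",
            length(config$specs), nrow(obs),
            format(ranking$best$spec_cv), format(ranking$best$spec_aic))
  invisible(ranking)
}

#' Score reserves against the classification and surfaces
#'
#' Reads the classified grid, the two probability surfaces and the
#' reserve polygons; writes `protection_report.csv` (one row per reserve:
#' area, percent Known, percent Known & Probable, percent stock under the
#' CV-best and AIC-best models, and per-unit-area efficiencies) and
#' `protection_aggregates.json` (existing / proposed / all totals with
#' cell-level union so overlapping reserves never double-count).
#'
#' @param config a [run_config()].
#' @return the report data frame, invisibly.
#' @export
run_evaluate <- function(config) {
  cells <- read_grid_csv(run_path(config, "classification.csv"))
  reserves <- read_reserves_geojson(run_path(config, "reserves.geojson"))
  surfaces <- list(
    xval = utils::read.csv(run_path(config, "surface_xval.csv"),
                           stringsAsFactors = FALSE),
    aic = utils::read.csv(run_path(config, "surface_aic.csv"),
                          stringsAsFactors = FALSE))
  domain_cells <- restrict_domain(cells, config$species)
  report <- protection_report(reserves, cells, surfaces,
                              surface_cells = domain_cells)
  utils::write.csv(report, run_path(config, "protection_report.csv"),
                   row.names = FALSE)
  aggregates <- lapply(c(all = "all", existing = "existing",
                         proposed = "proposed"), function(m)
    aggregate_reserves(reserves, domain_cells, surfaces$xval, mode = m))
  writeLines(jsonlite::toJSON(aggregates, auto_unbox = TRUE, digits = NA,
                              na = "null"),
             run_path(config, "protection_aggregates.json"))
  log_stage("evaluate", "%d reserves scored against %d domain cells",
            length(reserves), nrow(domain_cells))
  invisible(report)
}

#' Run the whole pipeline
#'
#' Chains [run_simulate()], [run_classify()], [run_fit_select()] and
#' [run_evaluate()].
#'
#' @param config a [run_config()].
#' @return the protection report, invisibly.
#' @export
run_all <- function(config) {
  run_simulate(config)
  run_classify(config)
  run_fit_select(config)
  run_evaluate(config)
}
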