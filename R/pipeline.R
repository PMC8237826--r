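#' Full-run configuration
#'
#' Bundles a synthetic scenario with every analysis threshold. All
#' thresholds default to the study constants: >50 records and >0.7
#' completeness for well-sampled cells, 3-decimal coordinate precision,
#' 1000 m centroid radius, 180 m functional-connectivity gap, 1 km habitat
#' window, 100 x 100 environmental-space bins, 1000 null iterations. Every
#' randomized stage draws its own seed deterministically from `seed`.
#'
#' @param scenario a [scenario_config()] (or list of arguments for one).
#' @param seed master analysis seed (default: the scenario seed).
#' @param n_bins,n_iter environmental-space bins and null iterations.
#' @param n_orders accumulation-curve permutations.
#' @param min_records,min_completeness well-sampled thresholds.
#' @param min_decimals,centroid_radius_m cleaning thresholds.
#' @param gap_m,window_m landscape-metric parameters.
#' @param trusted_cells cell ids treated as hosting trusted inventories.
#' @param K ANN maximum neighbour order (NULL = `min(30, n - 1)`).
#' @return list of class `run_config`.
#' @export
run_config <- function(scenario = scenario_config(), seed = NULL,
                       n_bins = 100, n_iter = 1000, n_orders = 100,
                       min_records = 50, min_completeness = 0.7,
                       min_decimals = 3, centroid_radius_m = 1000,
                       gap_m = 180, window_m = NULL,
                       trusted_cells = integer(0), K = NULL) {
  if (!inherits(scenario, "scenario_config"))
    scenario <- do.call(scenario_config, as.list(scenario))
  structure(list(scenario = scenario, seed = seed %||% scenario$seed,
                 n_bins = n_bins, n_iter = n_iter, n_orders = n_orders,
                 min_records = min_records,
                 min_completeness = min_completeness,
                 min_decimals = min_decimals,
                 centroid_radius_m = centroid_radius_m,
                 gap_m = gap_m, window_m = window_m,
                 trusted_cells = trusted_cells, K = K),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file holding `run_config` fields (`scenario` as a
#'   nested object).
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the complete coverage/bias workflow on a synthetic scenario
#'
#' Executes generate -> clean -> grid -> completeness -> landscape ->
#' environmental spaces -> coverage null tests (climate and landscape) ->
#' ANN -> bias tables, persisting every stage's intermediates under
#' `out_dir` and consolidating headline statistics in `report.json`.
#' Reruns with an identical config produce byte-identical `report.json`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing); NULL to skip all
#'   file output.
#' @return the report, invisibly a list (also written as JSON), with the
#'   full stage objects attached in attribute `"stages"`.
#' @export
run_all <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  sc <- config$scenario
  persist <- !is.null(out_dir)
  if (persist && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  pth <- function(...) file.path(out_dir, ...)

  ## stage 1: synthetic inputs
  scen <- simulate_scenario(sc, gap_m = config$gap_m,
                            window_m = config$window_m)
  polygon <- polygon_rect(0, 0, sc$width * sc$cell_size,
                          sc$height * sc$cell_size)
  grid <- grid_from_raster(scen$habitat)
  if (persist) {
    write_occurrences(scen$records, pth("records_raw.csv"))
    write_polygon_geojson(polygon, pth("polygon.geojson"))
    write_ascii_grid(scen$habitat, pth("habitat.asc"))
    write_ascii_grid(scen$roads, pth("roads.asc"))
    write_ascii_grid(scen$urban, pth("urban.asc"))
    write_ascii_grid(scen$veg, pth("veg.asc"))
    utils::write.csv(data.frame(name = sprintf("city_%02d",
                                               seq_len(nrow(scen$urban_centers))),
                                x = scen$urban_centers[, 1],
                                y = scen$urban_centers[, 2]),
                     pth("centroids.csv"), row.names = FALSE)
    utils::write.csv(data.frame(name = scen$names), pth("names.csv"),
                     row.names = FALSE)
    utils::write.csv(scen$synonyms, pth("synonyms.csv"), row.names = FALSE)
    write_json_stable(list(bias_fragment = scen$truth$bias_fragment,
                           bias_access = scen$truth$bias_access,
                           sites = scen$truth$sites,
                           true_richness = scen$truth$true_richness,
                           site_probabilities =
                             as.numeric(scen$truth$site_probabilities)),
                      pth("truth.json"))
  }

  ## stage 2: cleaning
  cl <- clean_records(scen$records, polygon,
                      valid_names = scen$names, synonym_map = scen$synonyms,
                      centroids = scen$urban_centers[, 1:2, drop = FALSE],
                      min_decimals = config$min_decimals,
                      radius_m = config$centroid_radius_m)
  if (persist) {
    write_occurrences(cl$records, pth("records_clean.csv"))
    write_json_stable(unclass(cl$report), pth("cleaning_report.json"))
  }

  ## stage 3: gridding + completeness
  recs <- assign_to_grid(cl$records, grid)
  comp <- completeness_by_cell(records_by_cell(recs),
                               trusted_cells = config$trusted_cells,
                               n_orders = config$n_orders,
                               seed = derive_seed(config$seed, 11L),
                               min_records = config$min_records,
                               min_completeness = config$min_completeness)
  ws_cells <- comp$cell[comp$well_sampled]
  if (persist) utils::write.csv(comp, pth("completeness.csv"),
                                row.names = FALSE)

  ## stage 4: environmental spaces
  clim_mat <- vapply(scen$climate, function(r) as.vector(unclass(r)),
                     numeric(grid$nrow * grid$ncol))
  clim_pca <- pca_varimax(clim_mat, 2)
  mt <- metrics_table(scen$metrics)
  land_ok <- stats::complete.cases(mt[, -1])
  land_cells <- mt$cell[land_ok]
  land_pca <- pca_varimax(as.matrix(mt[land_ok, -1]), 2)
  if (persist) {
    utils::write.csv(cbind(variable = rownames(clim_pca$loadings),
                           as.data.frame(clim_pca$loadings)),
                     pth("climate_loadings.csv"), row.names = FALSE)
    utils::write.csv(data.frame(cell = seq_len(nrow(clim_pca$scores)),
                                clim_pca$scores),
                     pth("climate_scores.csv"), row.names = FALSE)
    utils::write.csv(cbind(variable = rownames(land_pca$loadings),
                           as.data.frame(land_pca$loadings)),
                     pth("landscape_loadings.csv"), row.names = FALSE)
    utils::write.csv(data.frame(cell = land_cells, land_pca$scores),
                     pth("landscape_scores.csv"), row.names = FALSE)
    for (nm in names(scen$metrics))
      write_ascii_grid(scen$metrics[[nm]], pth(paste0("metric_", nm, ".asc")))
  }

  ## stage 5: coverage null tests + rarity + bias tables
  run_space <- function(scores, universe_cells, label, offset) {
    smp <- match(ws_cells, universe_cells)
    smp <- smp[!is.na(smp)]
    if (length(smp) < 2) {
      message(sprintf("%s space: <2 well-sampled cells in universe; skipped",
                      label))
      return(NULL)
    }
    ov <- coverage_null_test(scores, smp, n_iter = config$n_iter,
                             seed = derive_seed(config$seed, offset),
                             n_bins = config$n_bins)
    space_all <- build_env_space(scores, n_bins = config$n_bins)
    rar <- rarity_scores(space_all)
    list(overlap = ov,
         pc1 = axis_bias_test(scores, smp, 1),
         pc2 = axis_bias_test(scores, smp, 2),
         rarity = rarity_bias_test(rar, smp),
         rarity_values = rar, sampled = smp)
  }
  clim_res <- run_space(clim_pca$scores, seq_len(nrow(clim_pca$scores)),
                        "climate", 21L)
  land_res <- run_space(land_pca$scores, land_cells, "landscape", 22L)
  if (persist && !is.null(clim_res))
    utils::write.csv(data.frame(iter = seq_along(clim_res$overlap$null_d),
                                d = clim_res$overlap$null_d),
                     pth("climate_null_d.csv"), row.names = FALSE)
  if (persist && !is.null(land_res))
    utils::write.csv(data.frame(iter = seq_along(land_res$overlap$null_d),
                                d = land_res$overlap$null_d),
                     pth("landscape_null_d.csv"), row.names = FALSE)

  ## stage 6: ANN
  ann <- NULL
  if (length(ws_cells) >= 2) {
    pts <- cell_centers(grid, ws_cells)
    K <- config$K %||% min(30L, nrow(pts) - 1L)
    ann <- ann_analysis(pts, polygon, K = K, n_iter = config$n_iter,
                        seed = derive_seed(config$seed, 31L))
    if (persist)
      utils::write.csv(data.frame(k = seq_along(ann$observed),
                                  observed = ann$observed,
                                  null_lo = ann$null$quantiles[1, ],
                                  null_med = ann$null$quantiles[2, ],
                                  null_hi = ann$null$quantiles[3, ]),
                       pth("ann_curves.csv"), row.names = FALSE)
  }

  space_row <- function(res) {
    if (is.null(res)) return(NULL)
    list(n_well_sampled = res$overlap$n_sampled_cells,
         schoener_d = res$overlap$d_observed,
         d_p_value = res$overlap$p_value,
         coverage_fraction = res$overlap$coverage_fraction,
         pc1_h = res$pc1$h, pc1_p = res$pc1$p_value,
         pc2_h = res$pc2$h, pc2_p = res$pc2$p_value,
         rarity_h = res$rarity$h, rarity_p = res$rarity$p_value)
  }
  report <- list(
    config = list(seed = config$seed, scenario_seed = sc$seed,
                  extent = c(sc$width, sc$height),
                  n_sites = sc$n_sites,
                  bias_fragment = sc$bias_fragment,
                  bias_access = sc$bias_access),
    cleaning = unclass(cl$report),
    n_cells_with_records = nrow(comp),
    n_well_sampled = length(ws_cells),
    climate = space_row(clim_res),
    landscape = space_row(land_res),
    ann = if (!is.null(ann))
      list(aggregated_fraction = ann$aggregated_fraction,
           expected_nn = ann$null$expected_nn,
           n_sites = ann$n_sites) else NULL)
  if (persist) write_json_stable(report, pth("report.json"))
  attr(report, "stages") <- list(scenario = scen, cleaned = cl,
                                 completeness = comp,
                                 climate_pca = clim_pca,
                                 landscape_pca = land_pca,
                                 climate = clim_res, landscape = land_res,
                                 ann = ann, well_sampled_cells = ws_cells)
  invisible(report)
}
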