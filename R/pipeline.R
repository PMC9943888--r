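#' Default pipeline configuration
#'
#' Scalar settings for the full analysis. The defaults reproduce the
#' standard study settings: queen's-case adjacency, thresholds from the
#' 50th to 95th percentile by 5 plus the 99th, pathway delineation at the
#' 99/99.5/99.75th percentiles, the 95th percentile ("top 5%") as the
#' top-connectivity level for impedance intersection, a 6.44 km focal
#' window, and 200 bootstrap replicates.
#'
#' @param ... overrides for any default entry.
#' @return a named list of settings.
#' @export
pipeline_config <- function(...) {
  cfg <- list(neighborhood = "queen-8",
              threshold_levels = default_threshold_levels(),
              pathway_levels = c(99, 99.5, 99.75),
              top_level = 95,
              focal_radius_m = 6440,
              rules_variant = "default",
              top_k_pathways = 4,
              n_bootstrap = 200,
              seed = 1,
              include_zero = TRUE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop(sprintf("unknown config entries: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  utils::modifyList(cfg, over)
}

#' Generate a complete synthetic study scene
#'
#' One call producing every input class the analysis consumes: an
#' autocorrelated resistance raster with a planted corridor, preferentially
#' placed nodes, a connected genetic network with resistance-decaying
#' weights, PAC and MZ polygon sets, and cultivation/canopy land-cover
#' layers — all driven from a single seed.
#'
#' @param n_rows,n_cols scene dimensions (default 50 x 50).
#' @param n_nodes number of network nodes.
#' @param seed master seed; per-generator seeds are derived from it.
#' @param n_corridors corridors planted in the resistance surface.
#' @param edge_rule network edge rule.
#' @param pac_coverage target PAC coverage fraction.
#' @param n_mz number of management zones.
#' @return named list: raster, graph, nodes, network, pac_polygons,
#'   mz_polygons, cultivation, canopy, seed.
#' @export
synthetic_scene <- function(n_rows = 50, n_cols = 50, n_nodes = 15,
                            seed = 1, n_corridors = 1,
                            edge_rule = "gabriel", pac_coverage = 0.30,
                            n_mz = 5) {
  sd <- function(k) (seed * 101L + k) %% 2147483647L
  spec <- landscape_spec(n_rows, n_cols, resistance_range = c(1, 161),
                         autocorrelation_scale = 5,
                         n_corridors = n_corridors,
                         corridor_resistance = 1, seed = sd(1L))
  raster <- generate_resistance_raster(spec)
  graph <- build_resistance_graph(raster)
  nodes <- generate_nodes(raster, n_nodes, seed = sd(2L))
  network <- generate_network(nodes, raster,
                              network_spec(edge_rule = edge_rule,
                                           weight_decay = 0.05,
                                           noise_sd = 0.01, seed = sd(3L)),
                              graph = graph)
  pac <- generate_polygons(nodes, raster$georef, "pac",
                           coverage = pac_coverage, seed = sd(4L))
  mz <- generate_polygons(nodes, raster$georef, "mz", k = n_mz,
                          seed = sd(5L))
  cultivation <- generate_landcover(raster$georef, "cultivation",
                                    patch_density = 0.15, seed = sd(6L))
  canopy <- generate_landcover(raster$georef, "canopy",
                               patch_density = 0.25, seed = sd(7L))
  list(raster = raster, graph = graph, nodes = nodes, network = network,
       pac_polygons = pac, mz_polygons = mz, cultivation = cultivation,
       canopy = canopy, seed = seed)
}

#' Run the full connectivity-prioritization pipeline
#'
#' Executes the analysis end to end on an input scene: pairwise circuit
#' solves over the genetic network, cumulative-map accumulation, percentile
#' thresholding, spanning-tree edge ranking and pathway delineation,
#' PAC overlay statistics with the random-placement baseline, and
#' impedance action maps. Optionally writes all tabular and raster outputs
#' under \code{out_dir} (plain-text formats) and returns a manifest.
#'
#' @param scene input list as from \code{synthetic_scene} (fields raster,
#'   network, pac_polygons, mz_polygons, cultivation, canopy; graph
#'   optional).
#' @param config settings from \code{pipeline_config}.
#' @param out_dir output directory, or NULL (default) for no file output.
#' @return list of stage results plus a \code{manifest} of written files.
#' @export
run_pipeline <- function(scene, config = pipeline_config(), out_dir = NULL) {
  t0 <- Sys.time()
  graph <- scene$graph
  if (is.null(graph))
    graph <- build_resistance_graph(scene$raster, config$neighborhood)

  res <- solve_all_pairs(graph, scene$network, keep_maps = FALSE)
  cumulative <- res$cumulative

  masks <- threshold_series(cumulative, config$threshold_levels,
                            include_zero = config$include_zero)
  top_mask <- masks[[which(vapply(masks, `[[`, numeric(1),
                                  "percentile_level") == config$top_level)]]

  ranking <- rank_mst_edges(scene$network, use_provided = TRUE,
                            top_k = config$top_k_pathways)
  solver <- laplacian_solver(graph)
  pathways <- lapply(seq_len(nrow(ranking)), function(i) {
    eid <- ranking$edge_id[i]
    e <- scene$network$edges[scene$network$edges$edge_id == eid, ]
    na <- scene$nodes[scene$nodes$id == e$node_a, ]
    nb <- scene$nodes[scene$nodes$id == e$node_b, ]
    rc_a <- snap_to_cell(graph$georef, na$x, na$y)
    rc_b <- snap_to_cell(graph$georef, nb$x, nb$y)
    sol <- solve_pair(graph, c(rc_a$row, rc_a$col), c(rc_b$row, rc_b$col),
                      edge_id = eid, solver = solver)
    delineate_pathway(sol, config$pathway_levels, rank = ranking$rank[i])
  })

  pac <- rasterize_polygons(scene$pac_polygons, graph$georef)
  mz_labelled <- rasterize_polygons(scene$mz_polygons, graph$georef,
                                    labelled = TRUE)
  mz_masks <- lapply(stats::setNames(scene$mz_polygons$labels,
                                     scene$mz_polygons$labels),
                     function(l) zone_mask(!is.na(mz_labelled$zone_of) &
                                             mz_labelled$zone_of == l,
                                           graph$georef, label = l))

  within <- connectivity_within(cumulative, pac)
  deciles <- decile_partition(cumulative, pac)
  area_tab <- threshold_area_table(masks, pac)
  overlaps <- lapply(pathways, pathway_overlap, zone = pac)
  boot <- bootstrap_random_overlap(cumulative, scene$pac_polygons,
                                   n_reps = config$n_bootstrap,
                                   seed = config$seed)

  rules <- impedance_rules(config$rules_variant)
  impede <- lapply(stats::setNames(c("cultivation", "canopy"),
                                   c("cultivation", "canopy")), function(kind) {
    layer <- scene[[kind]]
    frac <- focal_fraction(layer, config$focal_radius_m)
    frac <- resample_to_grid(frac, graph$georef)
    exc <- exceedance_mask(frac, mz_masks, rules, kind)
    list(fraction = frac, exceedance = exc,
         summary = action_map_summary(exc, top_mask, pac),
         map = action_map(exc, top_mask))
  })

  manifest <- list(config = config, started = t0,
                   elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                   n_pairs = nrow(res$resistance_table),
                   n_infinite = sum(!is.finite(res$resistance_table$effective_resistance)),
                   files = character())
  out <- list(resistance_table = res$resistance_table,
              cumulative = cumulative, threshold_masks = masks,
              top_mask = top_mask, ranking = ranking, pathways = pathways,
              pac = pac, mz_masks = mz_masks,
              connectivity_within = within, deciles = deciles,
              threshold_area_table = area_tab,
              pathway_overlaps = overlaps, bootstrap = boot,
              impedance = impede, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wf <- function(fn, writer) { writer(file.path(out_dir, fn)); fn }
    files <- c(
      wf("pairwise_resistance.csv", function(p)
        utils::write.csv(res$resistance_table, p, row.names = FALSE)),
      wf("cumulative_connectivity.asc", function(p)
        write_ascii_grid(cumulative, p)),
      wf("threshold_table.csv", function(p) write_threshold_table(masks, p)),
      wf("edge_ranking.csv", function(p)
        utils::write.csv(ranking, p, row.names = FALSE)),
      wf("decile_partition.csv", function(p)
        utils::write.csv(deciles, p, row.names = FALSE)),
      wf("threshold_area_table.csv", function(p)
        utils::write.csv(area_tab, p, row.names = FALSE)),
      wf("bootstrap_replicates.csv", function(p)
        utils::write.csv(data.frame(replicate = seq_along(boot$replicates),
                                    proportion = boot$replicates),
                         p, row.names = FALSE)),
      wf("impedance_summary.csv", function(p) {
        tab <- do.call(rbind, lapply(names(impede), function(k)
          cbind(kind = k, impede[[k]]$summary)))
        utils::write.csv(tab, p, row.names = FALSE)
      }),
      wf("action_map_cultivation.asc", function(p)
        write_ascii_grid(impede$cultivation$map, p))
    )
    out$manifest$files <- files
    jsonlite::write_json(
      list(config = config, n_pairs = manifest$n_pairs,
           n_infinite = manifest$n_infinite, files = files),
      file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE)
  }
  out
}
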