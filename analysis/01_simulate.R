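#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study scene — an autocorrelated resistance
# landscape with a planted corridor, lek-cluster nodes placed preferentially
# in permeable habitat, a connected genetic network whose edge weights decay
# with landscape effective resistance, PAC and management-zone polygons, and
# cultivation/canopy land-cover layers — and write every input to disk.

library(connscape)

seed <- 1
out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

scene <- synthetic_scene(n_rows = 50, n_cols = 50, n_nodes = 15, seed = seed)

write_ascii_grid(scene$raster, file.path(out, "resistance.asc"))
write_network_csv(scene$network, file.path(out, "nodes.csv"),
                  file.path(out, "edges.csv"))
write_geojson(scene$pac_polygons, file.path(out, "pac.geojson"))
write_geojson(scene$mz_polygons, file.path(out, "mz.geojson"))
write_ascii_grid(scene$cultivation, file.path(out, "cultivation.asc"))
write_ascii_grid(scene$canopy, file.path(out, "canopy.asc"))

cat(sprintf("scene: %d x %d cells at %g m, resistance %.1f-%.1f\n",
            scene$raster$georef$n_rows, scene$raster$georef$n_cols,
            scene$raster$georef$cell_size,
            min(scene$raster$values), max(scene$raster$values)))
cat(sprintf("network: %d nodes, %d edges (gabriel rule, connected)\n",
            nrow(scene$nodes), nrow(scene$network$edges)))
cat(sprintf("PACs cover %.1f%% of the grid\n",
            100 * sum(rasterize_polygons(scene$pac_polygons,
                                         scene$raster$georef)$mask) / 2500))
cat(sprintf("inputs written to %s\n", out))
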