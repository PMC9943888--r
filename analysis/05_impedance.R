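#!/usr/bin/env Rscript
# Stage 5: impedances to connectivity. Screen cultivation and woodland
# canopy with a 6.44 km circular focal window, flag cells exceeding the
# per-management-zone thresholds, intersect exceedance with the top 5% of
# cumulative connectivity, and partition the result inside/outside PACs.

library(connscape)

inp <- "results/inputs"; out <- "results"
cum <- read_ascii_grid(file.path(out, "cumulative_connectivity.asc"))
cum <- cumulative_map(cum$values, cum$georef)
pac <- rasterize_polygons(read_geojson(file.path(inp, "pac.geojson")),
                          cum$georef)
mz_poly <- read_geojson(file.path(inp, "mz.geojson"))
mzl <- rasterize_polygons(mz_poly, cum$georef, labelled = TRUE)
mz <- lapply(stats::setNames(mz_poly$labels, mz_poly$labels), function(l)
  zone_mask(!is.na(mzl$zone_of) & mzl$zone_of == l, cum$georef, label = l))

top <- percentile_threshold(cum, 95)
rules <- impedance_rules("default")

summaries <- lapply(c(cultivation = "cultivation", canopy = "canopy"),
                    function(kind) {
  lay <- read_ascii_grid(file.path(inp, paste0(kind, ".asc")))
  lay <- landcover_raster(lay$values, lay$georef, kind)
  frac <- resample_to_grid(focal_fraction(lay, 6440), cum$georef)
  exc <- exceedance_mask(frac, mz, rules, kind)
  write_ascii_grid(action_map(exc, top),
                   file.path(out, paste0("action_map_", kind, ".asc")))
  action_map_summary(exc, top, pac)
})

tab <- do.call(rbind, lapply(names(summaries), function(k)
  cbind(kind = k, summaries[[k]])))
utils::write.csv(tab, file.path(out, "impedance_summary.csv"),
                 row.names = FALSE)

for (k in names(summaries)) {
  s <- summaries[[k]]
  above <- sum(s$area_km2[s$class == "above"])
  inp_share <- if (above > 0)
    100 * s$area_km2[s$class == "above" & s$location == "in_pac"] / above
    else 0
  cat(sprintf("%s: %.1f km2 of top-5%% connectivity exceeds its threshold (%.0f%% inside PACs)\n",
              k, above, inp_share))
}
cat(sprintf("top-5%% footprint screened: %.1f km2\n", top$area_km2))
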