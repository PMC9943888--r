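#!/usr/bin/env Rscript
# Stage 2: pairwise circuit analysis. Rebuild the resistance graph from the
# stored landscape (queen's-case adjacency), solve one circuit problem per
# genetic-network edge, and sum the per-pair current maps into the
# cumulative connectivity map.

library(connscape)

inp <- "results/inputs"; out <- "results"
ras <- read_ascii_grid(file.path(inp, "resistance.asc"))
ras <- resistance_raster(ras$values, ras$georef)
net <- read_network_csv(file.path(inp, "nodes.csv"), file.path(inp, "edges.csv"))

graph <- build_resistance_graph(ras, "queen-8")
res <- solve_all_pairs(graph, net, keep_maps = FALSE)

utils::write.csv(res$resistance_table,
                 file.path(out, "pairwise_resistance.csv"), row.names = FALSE)
write_ascii_grid(res$cumulative, file.path(out, "cumulative_connectivity.asc"))

r <- res$resistance_table$effective_resistance
cat(sprintf("solved %d pairwise circuits (%d disconnected)\n",
            nrow(res$resistance_table), sum(!is.finite(r))))
cat(sprintf("pairwise resistance: range %.2f-%.2f, median %.2f\n",
            min(r[is.finite(r)]), max(r[is.finite(r)]),
            stats::median(r[is.finite(r)])))
v <- res$cumulative$values[!is.na(res$cumulative$values)]
cat(sprintf("cumulative connectivity: range %.4f-%.2f, median %.2f\n",
            min(v), max(v), stats::median(v)))
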