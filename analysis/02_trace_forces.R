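#!/usr/bin/env Rscript
# Step 2: stopping forces from force traces (plateau route).
#
# For every geometry measured by direct plateau averaging, each trace is
# processed through binding detection, automatic plateau detection,
# baseline offset estimation and the vector-magnitude stopping force.
# Writes one row per trace to results/stopping_forces_traces.tsv.

suppressPackageStartupMessages(library(slideforce))

dir.create("results", showWarnings = FALSE)
geoms <- c("gliding", "non_aligned", "mt_anchored")

rows <- lapply(geoms, function(geom) {
  res <- analyze_traces(file.path("scratch/assays", geom))
  message(sprintf("%-12s %d/%d traces analysed, median F_stop = %.2f pN",
                  geom, nrow(res), nrow(res) + attr(res, "n_failed"),
                  median(res$stopping_force)))
  res
})
tab <- do.call(rbind, rows)
write.table(tab, "results/stopping_forces_traces.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# sanity: recovered plateaus vs the configured truths
presets <- geometry_presets(seed = 20260926L)
for (geom in geoms) {
  truth <- presets[[geom]]$team_friction * presets[[geom]]$unloaded_velocity
  got <- median(tab$stopping_force[tab$geometry == geom])
  message(sprintf("%-12s truth %.2f pN, recovered median %.2f pN (%+.1f%%)",
                  geom, truth, got, 100 * (got / truth - 1)))
}
message("wrote results/stopping_forces_traces.tsv")
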