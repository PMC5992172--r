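#!/usr/bin/env Rscript
# Step 1: generate the synthetic assay data for the whole workflow.
#
# Four batches, one per anchorage geometry, with force scales matching the
# measured regimes: gliding on surface-anchored motor domains (tens of pN),
# sliding between aligned microtubules driven by diffusively anchored
# full-length motors (sub-pN; measured by force-velocity scans, not
# plateaus), non-aligned crosslinked microtubules (several pN), and motor
# domains statically anchored on a microtubule. Raw traces go to
# scratch/assays/ (they are bulky and fully reproducible from the config
# files); everything downstream reads from there.

suppressPackageStartupMessages(library(slideforce))

seed <- 20260926L
out_root <- "scratch/assays"
n_traces <- 8L    # per plateau-measurable geometry
n_scans <- 12L    # sliding pairs, force-velocity route

presets <- geometry_presets(seed = seed)
for (geom in names(presets)) {
  cfg <- presets[[geom]]
  dir <- file.path(out_root, geom)
  if (geom == "sliding") {
    run_simulation(cfg, dir, n = n_scans, scans = TRUE)
    message(sprintf("%-12s %2d force-velocity scans -> %s", geom, n_scans, dir))
  } else {
    run_simulation(cfg, dir, n = n_traces)
    message(sprintf("%-12s %2d force traces        -> %s", geom, n_traces, dir))
  }
}

message("true plateau forces (team_friction * v0, pN):")
for (geom in names(presets)) {
  cfg <- presets[[geom]]
  message(sprintf("  %-12s %.2f", geom,
                  cfg$team_friction * cfg$unloaded_velocity))
}
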