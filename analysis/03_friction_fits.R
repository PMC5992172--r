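#!/usr/bin/env Rscript
# Step 3: stopping forces of sliding microtubule pairs (force-velocity
# route).
#
# The forces transmitted between aligned crosslinked microtubules are too
# small for a visible plateau, so each pair's scan is fitted by weighted
# least squares (force on velocity) and the stopping force read off as
# |slope| * v0. Writes one row per pair to results/stopping_forces_fits.tsv.

suppressPackageStartupMessages(library(slideforce))

dir.create("results", showWarnings = FALSE)
paths <- list.files("scratch/assays/sliding", pattern = "^scan_.*tsv$",
                    full.names = TRUE)
fits <- lapply(paths, function(p) {
  fit <- fit_force_velocity(read_fv_scan(p))
  data.frame(pair_id = fit$pair_id, slope = fit$slope,
             slope_se = fit$slope_se, intercept = fit$intercept,
             r_squared = fit$r_squared,
             unloaded_velocity = fit$unloaded_velocity,
             stopping_force = fit$stopping_force,
             stopping_force_se = fit$stopping_force_se)
})
tab <- do.call(rbind, fits)
write.table(tab, "results/stopping_forces_fits.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

truth <- 0.0123 * 57   # the sliding preset's team friction times v0
message(sprintf("%d sliding pairs fitted", nrow(tab)))
message(sprintf("median stopping force %.3f pN (truth %.3f pN); all sub-pN: %s",
                median(tab$stopping_force), truth,
                all(tab$stopping_force < 1)))
message(sprintf("median fit R^2 = %.3f", median(tab$r_squared)))
message("wrote results/stopping_forces_fits.tsv")
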