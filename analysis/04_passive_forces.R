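#!/usr/bin/env Rscript
# Step 4: the two passive-force corroborations of the sub-pN sliding force.
#
# (a) Buckling: the two observed buckled microtubule segments (8.3 um and
#     10 um) with the standard microtubule flexural rigidity EI = 6e-24
#     N m^2 bound the motor-team force at ~1.1 pN and ~0.75 pN.
# (b) Entropic balance: motors slide overlaps shut against confined
#     diffusible crosslinkers until N kB T / L balances the sliding force;
#     simulating the shortening and inverting the stalled state recovers
#     the motor force, here over a (N, force) grid.
# Writes results/buckling_forces.tsv and results/entropic_balance.tsv.

suppressPackageStartupMessages(library(slideforce))
dir.create("results", showWarnings = FALSE)

buck <- data.frame(segment_length_um = c(8.3, 10))
buck$force_pN <- sapply(buck$segment_length_um, buckling_force)
buck$force_euler_pN <- sapply(buck$segment_length_um, buckling_force,
                              prefactor = 4 * pi^2)
write.table(buck, "results/buckling_forces.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("buckling: %.2f um -> %.3f pN; %.2f um -> %.3f pN",
                buck$segment_length_um[1], buck$force_pN[1],
                buck$segment_length_um[2], buck$force_pN[2]))

grid <- expand.grid(n_crosslinkers = c(5, 20, 50),
                    motor_force = c(0.2, 0.5, 1.0))
grid$L_stall_nm <- grid$n_crosslinkers * kbt(298) / grid$motor_force
grid$recovered <- mapply(function(N, f, Ls) {
  s <- simulate_overlap_series(N, motor_force = f, L_start = 5 * Ls)
  stall_overlap_inversion(s)
}, grid$n_crosslinkers, grid$motor_force, grid$L_stall_nm)
grid$rel_error <- grid$recovered / grid$motor_force - 1
write.table(grid, "results/entropic_balance.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf(
  "entropic balance: %d (N, F) cells, max |relative error| = %.2f%%",
  nrow(grid), 100 * max(abs(grid$rel_error))))
message("wrote results/buckling_forces.tsv, results/entropic_balance.tsv")
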