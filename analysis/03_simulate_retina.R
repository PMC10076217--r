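#!/usr/bin/env Rscript
# Simulate the synthetic retina: a 500-cell RGC population with imposed
# dorsoventral gradients of surround strength, centre size and surround
# offset, responding to 420 s of the shifting white-noise checkerboard.
# Writes the ground-truth cell table; the recording itself is regenerated
# from the same seed by 04_map_and_fit.R (deterministic simulator).

library(panorf)

dir.create("results", showWarnings = FALSE)
seed <- 1
stim <- make_stimulus(420, field_um = c(1000, 1000), seed = seed * 7 + 1)
cells <- make_population(500, extent_um = c(700, 700), seed = seed * 7 + 2)
truth <- true_population_metrics(cells)
write.csv(truth, "results/ground_truth_cells.csv", row.names = FALSE)

cat(sprintf("Cells: %d over %d x %d um, stimulus %d frames (%d x %d px)\n",
            length(cells), 700, 700, stim$n_frames, stim$h_px, stim$w_px))
cat(sprintf("True relative surround range: %.2f - %.2f\n",
            min(truth$true_relative_surround), max(truth$true_relative_surround)))
cat("Wrote results/ground_truth_cells.csv\n")
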