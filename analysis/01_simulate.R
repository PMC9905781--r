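#!/usr/bin/env Rscript

# Step 1 -- simulate the study dataset.
#
# Generates the default synthetic multi-scorer dataset: 10 PSGs, each a
# ~7.5 h night of 900 thirty-second epochs, staged by a panel of 12
# scorers with mild individual bias, plus a probability-emitting
# auto-scorer. Writes one example PSG's artifacts (per-scorer hypnogram
# CSVs + manifest, truth and auto-scorer hypnodensity CSVs) so later steps
# and outside tools can inspect the file formats; the full dataset is
# re-derived deterministically from the seed by every later step.

suppressPackageStartupMessages(library(hypnoagree))

seed <- 20260923L
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ds <- simulate_dataset(10, sim_config(), seed = seed)

ex <- ds[["psg01"]]
write_scoring_set(ex$scorings, file.path(out, "psg01_scorings"))
write_hypnodensity(ex$truth, file.path(out, "psg01_truth.csv"))
write_hypnodensity(ex$auto, file.path(out, "psg01_autoscorer.csv"))

occ <- table(factor(ex$latent$stages, levels = sleep_stages()))
cat("Simulated", length(ds), "PSGs x", length(ex$scorings$hypnograms),
    "scorers x", length(ex$latent), "epochs (seed", seed, ")\n")
cat("Example night stage minutes (latent):",
    paste(sprintf("%s=%.0f", names(occ), as.integer(occ) * 0.5),
          collapse = " "), "\n")
cat("Example-PSG artifacts written under", out, "\n")
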