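#!/usr/bin/env Rscript

# Step 4 -- do auto-scored probabilities agree with the scorer panel?
#
# Builds the scorer-derived hypnodensity of each PSG and compares it with
# the auto-scored hypnodensity using ICC(2,1) absolute agreement, per
# stage and overall (per-stage series stacked). Stages with under 3.5
# minutes of reference time are flagged: their ICCs are not statistically
# meaningful.

suppressPackageStartupMessages(library(hypnoagree))

seed <- 20260923L
dir.create("results", showWarnings = FALSE)

ds <- simulate_dataset(10, sim_config(), seed = seed)

per_psg <- do.call(rbind, lapply(ds, function(psg) {
  manual <- hypnodensity_from_scorings(psg$scorings)
  r <- compare_hypnodensities(manual, psg$auto)
  rbind(data.frame(psg_id = psg$scorings$psg_id, stage = "all",
                   icc = r$all_stage$icc, ci_low = r$all_stage$ci_low,
                   ci_high = r$all_stage$ci_high),
        data.frame(psg_id = psg$scorings$psg_id,
                   stage = r$per_stage$stage, icc = r$per_stage$icc,
                   ci_low = r$per_stage$ci_low,
                   ci_high = r$per_stage$ci_high))
}))
rownames(per_psg) <- NULL

summ <- aggregate(cbind(icc, ci_low, ci_high) ~ stage, data = per_psg,
                  FUN = mean)
summ <- summ[match(c("all", sleep_stages()), summ$stage), ]
cat("ICC(2,1) manual- vs auto-scored probabilities (mean across PSGs):\n")
print(summ, row.names = FALSE, digits = 3)
cat(sprintf("\nPSGs with overall ICC > 0.9: %d of %d\n",
            sum(per_psg$icc[per_psg$stage == "all"] > 0.9), length(ds)))

write.csv(per_psg, "results/icc_per_psg.csv", row.names = FALSE)
write.csv(summ, "results/icc_summary.csv", row.names = FALSE)
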