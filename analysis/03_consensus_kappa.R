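#!/usr/bin/env Rscript

# Step 3 -- scorers and auto-scoring against the three comparators.
#
# For every PSG, each scorer (and the auto-scored staging collapsed from
# its hypnodensity) is evaluated with Cohen's kappa against (1) each
# remaining scorer, (2) the leave-one-out reliability-weighted consensus,
# and (3) "any scorer" credit. Per-PSG kappas are aggregated to
# mean +/- SD, and auto is compared to manual consensus performance with a
# paired t-test.

suppressPackageStartupMessages(library(hypnoagree))

seed <- 20260923L
dir.create("results", showWarnings = FALSE)

ds <- simulate_dataset(10, sim_config(), seed = seed)

tbl <- do.call(rbind, lapply(ds, function(psg)
  kappa_vs_comparators(psg$scorings,
                       auto = hypnodensity_to_hypnogram(psg$auto,
                                                        scorer_id = "auto"))))
summ <- kappa_summary(tbl)
cat("Kappa (mean +/- SD across PSGs), five-stage comparison:\n")
print(summ[summ$stage == "all", ], row.names = FALSE, digits = 3)
cat("\nPer-stage kappa vs the unbiased consensus:\n")
print(summ[summ$comparator == "unbiased_consensus" & summ$stage != "all", ],
      row.names = FALSE, digits = 3)

cons <- tbl[tbl$comparator == "unbiased_consensus" & tbl$stage == "all", ]
manual_k <- tapply(cons$kappa[cons$scorer != "auto"],
                   cons$psg_id[cons$scorer != "auto"], mean)
auto_rows <- cons[cons$scorer == "auto", ]
auto_k <- auto_rows$kappa[match(names(manual_k), auto_rows$psg_id)]
pt <- paired_kappa_test(as.numeric(manual_k), auto_k)
cat(sprintf("\nAuto vs manual consensus kappa: %.3f vs %.3f (t = %.2f, p = %.2g)\n",
            mean(auto_k), mean(manual_k), pt$statistic, pt$p_value))

write.csv(tbl, "results/kappa_per_psg.csv", row.names = FALSE)
write.csv(summ, "results/kappa_summary.csv", row.names = FALSE)
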