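#!/usr/bin/env Rscript
# Resting-foot group comparison: run the full pipeline (QC -> region
# kinetics -> one-way ANOVA with Bonferroni post hoc tests) on the
# calibrated synthetic cohort and write the comparison table.

suppressPackageStartupMessages(library(icgdyn))
seed <- 20260923L
dir.create("results/stats", recursive = TRUE, showWarnings = FALSE)

profile <- group_profiles()
cohort <- generate_cohort(profile, seed = seed)
res <- run_pipeline(cohort)
write_results_bundle(res, "results/stats")

st <- res$stats$table
st$mean <- signif(st$mean, 5)
st$sd <- signif(st$sd, 4)
cat(sprintf("Analyzed %d of %d limb acquisitions (%d excluded by motion QC).\n",
            res$report$n_analyzed, res$report$n_items, res$report$n_excluded))
cat("\nToe (digit) comparison:\n")
print(st[st$region == "digit", ], row.names = FALSE)
cat("\nDorsum comparison:\n")
print(st[st$region == "dorsum", ], row.names = FALSE)
cat("\nExpected pattern: C > M > D for toe I_max and AUC, the D group\n")
cat("slowest (largest MTT) and lowest BFI, with D-vs-C significant after\n")
cat("Bonferroni adjustment. Tables under results/stats/.\n")
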