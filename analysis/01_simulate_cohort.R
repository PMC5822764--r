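#!/usr/bin/env Rscript
# Build the synthetic study cohorts: resting feet for the three groups
# (control C, diabetes D, diabetes with microvascular complications M) and
# rest/post-stimulus hands. Stacks regenerate deterministically from the
# per-item seeds in the manifest, so only the manifests, ground truth and a
# few example image stacks are materialized here.

suppressPackageStartupMessages(library(icgdyn))
seed <- 20260923L
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

profile <- group_profiles()
cat("Group profiles calibrated; foot digit targets (I_max / BFI):\n")
for (g in c("C", "D", "M")) {
  cell <- profile$foot[[g]]$digit
  cat(sprintf("  %s: %7.1f A.U. / %6.1f A.U./s (model rise %.1f s, tau %.0f s)\n",
              g, cell$imax, cell$bfi, cell$tr_model, cell$tau))
}

foot <- generate_cohort(profile, seed = seed)
write.csv(foot$manifest, "results/sim/foot_manifest.csv", row.names = FALSE)
write.csv(foot$truth, "results/sim/foot_ground_truth.csv", row.names = FALSE)

hand <- generate_cohort(profile, limb = "hand",
                        conditions = c("rest", "post"), seed = seed + 1L)
write.csv(hand$manifest, "results/sim/hand_manifest.csv", row.names = FALSE)
write.csv(hand$truth, "results/sim/hand_ground_truth.csv", row.names = FALSE)

# one example stack per group, written as TIFF + YAML sidecar
write_region_labels(limb_label_image(), "results/sim/labels.png")
for (g in c("C", "D", "M")) {
  i <- which(foot$manifest$group == g)[1]
  write_stack(cohort_stack(foot, i)$stack,
              sprintf("results/sim/example_%s.tif", g))
}

cat(sprintf("Foot cohort: %d stacks (%d subjects); hand cohort: %d stacks.\n",
            nrow(foot$manifest), length(unique(foot$manifest$subject)),
            nrow(hand$manifest)))
cat("Manifests, ground truth and example stacks under results/sim/.\n")
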