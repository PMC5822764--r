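#!/usr/bin/env Rscript
# Motion-artifact QC demonstration: drift estimation on a clean stack and
# on stacks with injected rigid drift inside and outside the decision
# window (> 1 cm within the initial 3 min excludes).

suppressPackageStartupMessages(library(icgdyn))
seed <- 20260923L
dir.create("results/qc", recursive = TRUE, showWarnings = FALSE)

profile <- group_profiles()
gs <- generate_stack(profile, "C", "foot", seed = seed)
n <- length(gs$stack$times)

cases <- list(
  clean = matrix(0L, n, 2),
  early_drift = { d <- matrix(0L, n, 2); d[gs$stack$times >= 90, 1] <- 25L; d },
  small_drift = { d <- matrix(0L, n, 2); d[, 2] <- rep(c(0L, 10L), length.out = n); d },
  late_drift = { d <- matrix(0L, n, 2); d[gs$stack$times > 180, 1] <- 25L; d })

report <- list()
drift_tab <- NULL
for (nm in names(cases)) {
  st <- inject_motion(gs$stack, cases[[nm]])
  prof <- estimate_displacement(st)
  qc <- movement_exclusion(prof)
  report[[nm]] <- list(decision = qc$decision, max_drift_cm = qc$max_drift_cm,
                       at_time_s = qc$max_drift_time_s)
  drift_tab <- rbind(drift_tab, data.frame(case = nm, frame = prof$frame,
                                           time_s = prof$time_s,
                                           drift_cm = prof$magnitude_cm))
  cat(sprintf("%-12s -> %-7s (max drift %.2f cm at t = %g s)\n",
              nm, qc$decision, qc$max_drift_cm, qc$max_drift_time_s))
}
jsonlite::write_json(report, "results/qc/qc_report.json", auto_unbox = TRUE,
                     digits = NA)
write.csv(drift_tab, "results/qc/drift_vs_time.csv", row.names = FALSE)
cat("Only the early 1.25 cm drift is excluded: the rule is windowed to the\n")
cat("initial 180 s and thresholded strictly at 1 cm.\n")
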