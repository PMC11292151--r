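#!/usr/bin/env Rscript
# Step 1 — simulate a pharmacovigilance extract.
#
# Draws a 50,000-report synthetic spontaneous-reporting background with three
# planted drug-event associations of graded strength (odds multipliers 2, 5
# and 10) plus one null drug of special interest, and writes the long-format
# report table for the downstream steps. The raw table is bulky and
# regenerable, so it goes under scratch/; results/ gets the generator's
# ground truth for later comparison.

suppressPackageStartupMessages(library(akdsignal))

dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

signals <- list(
  planted_signal("emtricitabine + tenofovir disoproxil", "acute kidney injury",
                 lambda = 10, expect_detect = TRUE),
  planted_signal("vancomycin", c("blood creatinine increased", "acute kidney injury"),
                 lambda = 5, expect_detect = TRUE),
  planted_signal("furosemide", "acute kidney injury",
                 lambda = 2, expect_detect = TRUE)
)

cfg <- default_synthetic_config(n_reports = 50000, signals = signals,
                                seed = 20260928)
rs <- generate_reports(cfg)
write_reports(rs, "scratch/synthetic_reports.csv")

truth <- true_tables(cfg)
readr::write_tsv(truth, "results/planted_signal_truth.tsv")

cat("Simulated", n_reports(rs), "reports with",
    length(signals), "planted signals (odds multipliers 10, 5, 2).\n")
cat("Ground-truth 2x2 cell probabilities (results/planted_signal_truth.tsv):\n")
print(as.data.frame(truth), digits = 4)
cat("\nFor an isolated signal the implied odds ratio equals the configured\n",
    "multiplier almost exactly (nonemptiness conditioning is a <1% effect).\n",
    "Here the three signals share the 'acute kidney injury' term, so each\n",
    "inflates the others' comparator arm and the exact odds ratios sit below\n",
    "their multipliers; true_tables() accounts for this by enumerating the\n",
    "joint presence states of all signal drugs.\n", sep = "")
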