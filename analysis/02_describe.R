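#!/usr/bin/env Rscript
# Step 2 — ingest, deduplicate, define cases, describe them.
#
# Reads the simulated extract, removes exact-content duplicates, splits the
# set against the ten-term acute kidney disease case definition, and writes
# the descriptive tables: term frequencies, ATC classes, top ingredients,
# demographics, seriousness and the fatal-outcome breakdowns.

suppressPackageStartupMessages(library(akdsignal))

rs <- read_reports("scratch/synthetic_reports.csv")
rs <- deduplicate(rs)
cd <- akd_case_definition()
parts <- split_cases(rs, cd)
cases <- parts$cases

cat("Ingested", n_reports(rs) + rs$n_removed, "rows ->", n_reports(rs),
    "unique reports (", rs$n_removed, "exact duplicates removed).\n")
cat(n_reports(cases), "reports (",
    pct(n_reports(cases), n_reports(rs)), "% ) meet the AKD case definition.\n")

tf <- term_freq(cases, cd)
readr::write_tsv(tf$main, "results/terms_main.tsv")
readr::write_tsv(tf$concomitant, "results/terms_concomitant.tsv")
readr::write_tsv(atc_freq(cases), "results/atc_classes.tsv")
readr::write_tsv(ingredient_freq(cases, top_n = 10), "results/top_ingredients.tsv")

dem <- demographics(cases)
readr::write_tsv(dem$sex, "results/sex.tsv")
readr::write_tsv(dem$age_group, "results/age_groups.tsv")

st <- seriousness_table(cases)
readr::write_tsv(st$criteria, "results/seriousness.tsv")
cat(st$n_serious, "cases (", st$serious_pct, "% ) carry at least one seriousness criterion.\n")

fb <- fatal_breakdowns(cases)
readr::write_tsv(fb$atc, "results/fatal_atc_classes.tsv")
readr::write_tsv(fb$ingredients, "results/fatal_ingredients.tsv")
cat(fb$n_fatal, "cases (", fb$fatal_pct, "% ) had a fatal outcome.\n")

cat("\nMost reported case terms:\n")
print(as.data.frame(head(tf$main, 5)))
cat("\nMost reported ingredients among cases:\n")
print(as.data.frame(head(ingredient_freq(cases, top_n = 5))))
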