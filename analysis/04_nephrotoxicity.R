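#!/usr/bin/env Rscript
# Step 4 — bibliographic nephrotoxicity scoring.
#
# Classifies the 24 published reference drugs by their bibliographic score
# (0 = no evidence in any of five predetermined sources, 5 = evidence in
# all) into non-/potentially-/known-nephrotoxic, and annotates this run's
# screened synthetic signals with those scores where the drug appears in the
# reference list.

suppressPackageStartupMessages(library(akdsignal))

ref <- akd_reference_signals()
cp <- class_proportions(ref)
readr::write_tsv(cp, "results/nephrotoxicity_classes.tsv")

cat("Reference list:", nrow(ref), "drugs.\n")
cat("Class split (% of reference drugs):\n")
print(as.data.frame(cp))

res <- readr::read_tsv("results/signal_table.tsv", show_col_types = FALSE)
annotated <- merge(res, ref[, c("ingredient", "bs")], by = "ingredient",
                   all.x = TRUE, sort = FALSE)
annotated$category <- NA_character_
known <- !is.na(annotated$bs)
annotated$category[known] <- as.character(bs_category(annotated$bs[known]))
annotated <- annotated[order(-annotated$ic025), ]
readr::write_tsv(annotated, "results/signal_table_annotated.tsv")

flagged <- annotated[annotated$screened_in, ]
cat("\nScreened-in synthetic signals with reference scores:\n")
print(as.data.frame(flagged[, c("ingredient", "ror", "ic025", "bs", "category")]),
      digits = 3)
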