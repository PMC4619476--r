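#!/usr/bin/env Rscript
# Recurrence of the validated sites across the discovery (n = 2) and
# validation cohorts (24 FFPE samples pyrosequenced at five positions; 8
# fresh-tissue samples Sanger-screened for SMYD1 exons and the NOTCH2 PEST
# domain), with exact binomial intervals.
#
# Writes: results/recurrence.tsv

suppressPackageStartupMessages(library(somaticmz))
dir.create("results", showWarnings = FALSE)

rec <- load_recurrence_counts(system.file(
  "extdata", "smzl_recurrence_counts.tsv", package = "somaticmz"))
tab <- recurrence_table(rec)
print(as.data.frame(tab[, c("site", "n_mutated_validation", "n_validation",
                            "validation_pct", "pooled_pct", "pooled_ci_lo",
                            "pooled_ci_hi")]), digits = 3)
cat(sprintf(
  "\nMYD88 T794C: %s%% of validation cases, %s%% pooled over %d screened\n",
  tab$validation_pct[tab$site == "MYD88_T794C"],
  tab$pooled_pct[tab$site == "MYD88_T794C"],
  tab$n_discovery[tab$site == "MYD88_T794C"] +
    tab$n_validation[tab$site == "MYD88_T794C"]))
cat(sprintf("SMYD1 coding screen: %s%% pooled; NOTCH2 PEST: %s%% pooled\n",
            tab$pooled_pct[tab$site == "SMYD1_coding"],
            tab$pooled_pct[tab$site == "NOTCH2_PEST"]))
write.table(tab, "results/recurrence.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote results/recurrence.tsv\n")
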