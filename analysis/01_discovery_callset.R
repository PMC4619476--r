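#!/usr/bin/env Rscript
# Discovery call set: push the 25 published somatic SNVs back through the
# filtering cascade and summarize mutation classes, transitions/transversions
# and in-silico predictions.
#
# Writes: results/discovery_callset.tsv, results/discovery_summary.tsv

suppressPackageStartupMessages(library(somaticmz))
dir.create("results", showWarnings = FALSE)

snvs <- load_discovery_snvs()
cat("Discovery call set:", nrow(snvs), "somatic SNVs from two microdissected",
    "SMZL exomes\n")

# The cascade should be a no-op on an already-filtered somatic call set:
# every record clears its case's quality threshold and the paired rules.
res <- run_cascade(as_paired_table(snvs))
cat("Cascade re-run keeps", res$report$n_after_polymorphism, "of",
    res$report$n_input, "records; per-case quality thresholds:",
    paste(names(res$report$quality_thresholds),
          round(res$report$quality_thresholds, 2), sep = " = ",
          collapse = ", "), "\n\n")

summ <- summarize_callset(snvs)
print(summ)

out <- data.frame(
  quantity = c("n_total", "case1", "case2", "missense", "nonsense",
               "splice_site", "transitions", "transversions",
               "transitions_pct", "transversions_pct", "sift_damaging",
               "polyphen_possibly_or_probably_damaging"),
  value = c(summ$n_total, summ$per_case[["case1"]], summ$per_case[["case2"]],
            summ$class_counts[["missense"]], summ$class_counts[["nonsense"]],
            summ$class_counts[["splice_site"]], summ$ti_count, summ$tv_count,
            summ$ti_pct_display, summ$tv_pct_display,
            summ$sift_counts[["damaging"]],
            summ$polyphen_counts[["possibly_damaging"]] +
              summ$polyphen_counts[["probably_damaging"]])
)
write.table(out, "results/discovery_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(snvs, "results/discovery_callset.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nWrote results/discovery_summary.tsv and results/discovery_callset.tsv\n")
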