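#!/usr/bin/env Rscript
# Synthetic-cohort validation of the pipeline at the study conditions
# (depth 47x, purity 0.88): cascade recovery by cancer-cell fraction,
# germline rejection, and purity re-estimation from recovered clonal VAFs.
#
# Usage: Rscript analysis/04_synthetic_validation.R [seed]
# Writes: results/synthetic_recovery.tsv, results/purity_recovery.tsv

suppressPackageStartupMessages(library(somaticmz))
dir.create("results", showWarnings = FALSE)
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 17L

key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")

cfg <- simulation_config(n_germline_het = 6000, n_somatic = 4000,
                         n_polymorphisms = 500, seed = seed)
sim <- simulate_pair(cfg)
res <- run_cascade(sim$variants, blacklist = sim$blacklist)
som <- key(res$somatic)
truth <- sim$truth
recovered <- key(truth) %in% som

by_ccf <- tapply(recovered[truth$origin == "somatic"],
                 truth$ccf[truth$origin == "somatic"], mean)
germ_rej <- 1 - mean(recovered[truth$origin == "germline"])
cat(sprintf("Simulated %d loci at depth 47x, purity 0.88 (seed %d):\n",
            nrow(truth), seed))
cat(sprintf("  germline rejection: %.2f%%\n", 100 * germ_rej))
for (ccf in rev(names(by_ccf))) {
  cat(sprintf("  somatic recovery at CCF %s: %.1f%%\n", ccf,
              100 * by_ccf[[ccf]]))
}
cat("  (subclonal mutations evade the VAF floor; clonal ones do not)\n\n")
write.table(
  data.frame(metric = c("germline_rejection_pct",
                        paste0("recovery_pct_ccf_", names(by_ccf))),
             value = 100 * c(germ_rej, unname(by_ccf))),
  "results/synthetic_recovery.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

# Purity re-estimation: twice the median VAF of recovered clonal variants.
estimates <- vapply(seq_len(20), function(i) {
  cfg_i <- simulation_config(n_somatic = 50, n_germline_het = 100,
                             seed = (seed * 1000 + i) %% 2147483647)
  sim_i <- simulate_pair(cfg_i)
  res_i <- run_cascade(sim_i$variants)
  clonal_keys <- key(sim_i$truth[sim_i$truth$origin == "somatic" &
                                   sim_i$truth$ccf == 1, ])
  rec_i <- res_i$somatic[key(res_i$somatic) %in% clonal_keys, ]
  2 * median(rec_i$tumor_vaf)
}, numeric(1))
cat(sprintf(
  "Purity recovery over 20 replicates (true 0.88, n_somatic = 50):\n"))
cat(sprintf("  median estimate %.3f, range %.3f-%.3f\n",
            median(estimates), min(estimates), max(estimates)))
write.table(data.frame(replicate = seq_along(estimates),
                       purity_estimate = estimates),
            "results/purity_recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote results/synthetic_recovery.tsv and results/purity_recovery.tsv\n")
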