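# Shared helpers: a random paired-table generator and an independent
# brute-force re-statement of the filtering cascade (one boolean expression
# per variant, loops only) used as the oracle for run_cascade.

variant_key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")

random_paired_table <- function(n, seed) {
  set.seed(seed)
  chrom <- as.character(sample(1:22, n, replace = TRUE))
  pos <- sample.int(1e7L, n)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  t_depth <- sample(5:90, n, replace = TRUE)
  n_depth <- sample(5:90, n, replace = TRUE)
  t_alt <- rbinom(n, t_depth, runif(n, 0, 0.6))
  n_alt <- rbinom(n, n_depth, runif(n, 0, 0.4))
  tibble::tibble(
    case_id = sample(c("caseA", "caseB"), n, replace = TRUE),
    chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
    gene = NA_character_,
    tumor_depth = t_depth, tumor_alt_reads = t_alt,
    tumor_vaf = t_alt / t_depth,
    normal_depth = n_depth, normal_alt_reads = n_alt,
    normal_vaf = n_alt / n_depth,
    quality = round(runif(n, 10, 40), 2),
    consequence = sample(c("missense", "nonsense", "splice_site", "synonymous",
                           "intronic", "utr"), n, replace = TRUE),
    cdna_change = NA_character_, protein_change = NA_character_,
    sift = NA_character_, polyphen = NA_character_
  )
}

# Independent cascade oracle: recomputes every rule from scratch with loops.
brute_force_cascade <- function(variants, cfg, blacklist = NULL) {
  drop_csq <- cfg$drop_consequences
  pass_csq <- !(variants$consequence %in% drop_csq)
  # per-case quality threshold over the consequence survivors
  thr <- list()
  for (cs in unique(variants$case_id)) {
    q <- variants$quality[pass_csq & variants$case_id == cs]
    if (length(q) > 0) {
      s <- if (length(q) == 1) 0 else sd(q)
      thr[[cs]] <- mean(q) - cfg$quality_sd_multiplier * s
    }
  }
  bl_keys <- if (is.null(blacklist)) character(0) else variant_key(blacklist)
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    nvaf <- ifelse(is.na(v$normal_vaf), 0, v$normal_vaf)
    keep[i] <- pass_csq[i] &&
      v$quality >= thr[[v$case_id]] &&
      v$tumor_depth >= cfg$min_coverage &&
      v$tumor_vaf >= cfg$min_tumor_vaf &&
      nvaf < cfg$max_normal_vaf &&
      (v$tumor_vaf - nvaf) >= cfg$min_delta &&
      !(variant_key(v) %in% bl_keys)
  }
  variants[keep, , drop = FALSE]
}
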