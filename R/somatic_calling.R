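# The filtering cascade: consequence -> call quality -> paired somatic rules
# -> known polymorphisms.

#' Filtering-cascade configuration
#'
#' Thresholds of the somatic-calling cascade, defaulting to the study's
#' settings: tumor coverage at least 20, tumor novel-allele frequency at least
#' 0.1, normal allele frequency strictly below 0.2, tumor-minus-normal
#' frequency delta at least 0.1, call quality at least the per-case mean minus
#' two sample standard deviations, and removal of synonymous, intronic and UTR
#' calls.
#'
#' @param min_coverage Minimum tumor depth (inclusive).
#' @param min_tumor_vaf Minimum tumor variant allele fraction (inclusive).
#' @param max_normal_vaf Normal allele-fraction ceiling (exclusive: the normal
#'   VAF must be strictly smaller).
#' @param min_delta Minimum tumor-minus-normal VAF difference (inclusive).
#' @param quality_sd_multiplier Number of sample standard deviations below the
#'   mean at which calls are discarded.
#' @param drop_consequences Consequence classes removed outright.
#' @param quality_threshold Optional fixed quality cutoff (single value, or a
#'   named vector keyed by `case_id`). When supplied it replaces the adaptive
#'   mean-minus-k-sd threshold; freezing the threshold makes reprocessing of a
#'   filtered call set exactly idempotent.
#' @return A list of class `filter_config`.
#' @examples
#' cfg <- filter_config()
#' cfg$min_coverage
#' @export
filter_config <- function(min_coverage = 20L,
                          min_tumor_vaf = 0.1,
                          max_normal_vaf = 0.2,
                          min_delta = 0.1,
                          quality_sd_multiplier = 2,
                          drop_consequences = c("synonymous", "intronic", "utr"),
                          quality_threshold = NULL) {
  stopifnot(min_coverage >= 0,
            min_tumor_vaf >= 0, min_tumor_vaf <= 1,
            max_normal_vaf >= 0, max_normal_vaf <= 1,
            min_delta >= 0, min_delta <= 1,
            quality_sd_multiplier >= 0,
            all(drop_consequences %in% CONSEQUENCE_LEVELS))
  structure(list(min_coverage = as.integer(min_coverage),
                 min_tumor_vaf = min_tumor_vaf,
                 max_normal_vaf = max_normal_vaf,
                 min_delta = min_delta,
                 quality_sd_multiplier = quality_sd_multiplier,
                 drop_consequences = drop_consequences,
                 quality_threshold = quality_threshold),
            class = "filter_config")
}

#' Adaptive call-quality threshold
#'
#' The quality floor below which calls are discarded: the mean of the supplied
#' qualities minus `multiplier` sample standard deviations (n - 1 denominator).
#' A single quality has standard deviation 0, so the threshold is that value.
#'
#' @param qualities Non-empty numeric vector of novel-allele call qualities.
#' @param multiplier Number of standard deviations (default 2).
#' @return The threshold, a single number.
#' @examples
#' quality_threshold(c(10, 20, 30)) # 20 - 2 * 10 = 0
#' @export
quality_threshold <- function(qualities, multiplier = 2) {
  if (length(qualities) == 0 || any(is.na(qualities))) {
    stop("qualities must be a non-empty vector without NA", call. = FALSE)
  }
  s <- if (length(qualities) == 1L) 0 else stats::sd(qualities)
  mean(qualities) - multiplier * s
}

# Resolve per-case thresholds: fixed from cfg when given, else adaptive
# mean - k*sd within each case ("per calling").
case_quality_thresholds <- function(variants, cfg) {
  cases <- unique(variants$case_id)
  fixed <- cfg$quality_threshold
  if (!is.null(fixed)) {
    if (is.null(names(fixed))) {
      stats::setNames(rep(as.numeric(fixed), length(cases)), cases)
    } else {
      if (!all(cases %in% names(fixed))) {
        stop("fixed quality_threshold lacks case(s): ",
             paste(setdiff(cases, names(fixed)), collapse = ", "),
             call. = FALSE)
      }
      fixed[cases]
    }
  } else {
    vapply(cases, function(cs) {
      quality_threshold(variants$quality[variants$case_id == cs],
                        cfg$quality_sd_multiplier)
    }, numeric(1))
  }
}

#' Filter calls by novel-allele quality
#'
#' Removes calls whose quality lies below the threshold of
#' [quality_threshold()], computed separately within each case (each
#' sequencing run has its own quality distribution), unless
#' `cfg$quality_threshold` fixes the cutoff.
#'
#' @param variants A paired variant table.
#' @param cfg A [filter_config()].
#' @return A list with `kept` and `removed` tables and the named
#'   `thresholds` used per case.
#' @export
filter_by_quality <- function(variants, cfg = filter_config()) {
  if (nrow(variants) == 0) {
    return(list(kept = variants, removed = variants, thresholds = numeric(0)))
  }
  thr <- case_quality_thresholds(variants, cfg)
  keep <- variants$quality >= thr[variants$case_id]
  list(kept = variants[keep, , drop = FALSE],
       removed = variants[!keep, , drop = FALSE],
       thresholds = thr)
}

#' Remove protein-silent consequence classes
#'
#' Drops calls whose consequence is in `cfg$drop_consequences` (by default
#' synonymous, intronic and UTR). Splice-site calls are retained even when the
#' codon is unchanged: `splice_site` is its own class, never folded into
#' `synonymous`.
#'
#' @inheritParams filter_by_quality
#' @return A list with `kept` and `removed` tables.
#' @export
filter_consequence <- function(variants, cfg = filter_config()) {
  drop <- variants$consequence %in% cfg$drop_consequences
  list(kept = variants[!drop, , drop = FALSE],
       removed = variants[drop, , drop = FALSE])
}

#' Paired tumor/normal somatic decision
#'
#' Applies the somatic rule block to each row of a paired variant table:
#' tumor depth at least `min_coverage`, tumor VAF at least `min_tumor_vaf`,
#' normal VAF strictly below `max_normal_vaf`, and tumor-minus-normal VAF at
#' least `min_delta`. Rules are evaluated in that order and the first failing
#' rule is reported. A missing normal observation (`NA` normal VAF) is treated
#' as normal VAF 0 — an assumption, flagged with a message.
#'
#' @inheritParams filter_by_quality
#' @return A character vector, one element per row: `"somatic"` or the name of
#'   the first failing rule (`"coverage"`, `"tumor_vaf"`, `"normal_vaf"`,
#'   `"delta"`).
#' @examples
#' tbl <- as_paired_table(load_discovery_snvs())
#' table(call_somatic(tbl))
#' @export
call_somatic <- function(variants, cfg = filter_config()) {
  n <- nrow(variants)
  nvaf <- variants$normal_vaf
  if (anyNA(nvaf)) {
    message(sum(is.na(nvaf)),
            " variant(s) lack a normal observation; assuming normal VAF 0")
    nvaf[is.na(nvaf)] <- 0
  }
  decision <- rep("somatic", n)
  delta_fail <- (variants$tumor_vaf - nvaf) < cfg$min_delta
  decision[delta_fail] <- "delta"
  decision[nvaf >= cfg$max_normal_vaf] <- "normal_vaf"
  decision[variants$tumor_vaf < cfg$min_tumor_vaf] <- "tumor_vaf"
  decision[variants$tumor_depth < cfg$min_coverage] <- "coverage"
  decision
}

#' Remove previously described polymorphisms
#'
#' Exact-match removal on `(chrom, pos, ref, alt)` against a blacklist of
#' known polymorphic loci (see [load_polymorphism_blacklist()]).
#'
#' @inheritParams filter_by_quality
#' @param blacklist A data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   or `NULL` for no removal.
#' @return A list with `kept` and `removed` tables.
#' @export
filter_polymorphisms <- function(variants, blacklist = NULL) {
  if (is.null(blacklist) || nrow(blacklist) == 0 || nrow(variants) == 0) {
    return(list(kept = variants, removed = variants[0, , drop = FALSE]))
  }
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  hit <- key(variants) %in% key(blacklist)
  list(kept = variants[!hit, , drop = FALSE],
       removed = variants[hit, , drop = FALSE])
}

#' Run the full somatic-calling cascade
#'
#' Applies the four stages in order — consequence removal, per-case quality
#' threshold, paired somatic rules, known-polymorphism removal — and reports
#' per-stage attrition. Deterministic for a fixed input order; row order is
#' preserved throughout.
#'
#' @inheritParams filter_polymorphisms
#' @param cfg A [filter_config()].
#' @return A list with:
#'   * `somatic`: the surviving call set;
#'   * `report`: a list with `n_input`, `n_after_consequence`,
#'     `n_after_quality`, `n_after_somatic_rules`, `n_after_polymorphism`,
#'     the named per-case `quality_thresholds` actually used, and `removed`,
#'     a tibble of removed variants with `stage` and `reason` columns.
#' @examples
#' res <- run_cascade(as_paired_table(load_discovery_snvs()))
#' res$report$n_after_polymorphism
#' @export
run_cascade <- function(variants, cfg = filter_config(), blacklist = NULL) {
  variants <- validate_variant_table(variants)
  removed_with <- function(d, stage, reason) {
    if (nrow(d) == 0) {
      return(tibble::tibble(d, stage = character(0), reason = character(0)))
    }
    tibble::tibble(d, stage = stage, reason = reason)
  }

  s1 <- filter_consequence(variants, cfg)
  rem1 <- removed_with(s1$removed, "consequence", s1$removed$consequence)

  s2 <- filter_by_quality(s1$kept, cfg)
  rem2 <- removed_with(s2$removed, "quality", "low_quality")

  decision <- call_somatic(s2$kept, cfg)
  s3_kept <- s2$kept[decision == "somatic", , drop = FALSE]
  s3_removed <- s2$kept[decision != "somatic", , drop = FALSE]
  rem3 <- removed_with(s3_removed, "somatic_rules",
                       decision[decision != "somatic"])

  s4 <- filter_polymorphisms(s3_kept, blacklist)
  rem4 <- removed_with(s4$removed, "polymorphism", "known_polymorphism")

  removed <- rbind(rem1, rem2, rem3, rem4)
  report <- list(
    n_input = nrow(variants),
    n_after_consequence = nrow(s1$kept),
    n_after_quality = nrow(s2$kept),
    n_after_somatic_rules = nrow(s3_kept),
    n_after_polymorphism = nrow(s4$kept),
    quality_thresholds = s2$thresholds,
    removed = removed
  )
  stopifnot(report$n_input == nrow(s4$kept) + nrow(removed))
  list(somatic = s4$kept, report = report)
}
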