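# Recurrence statistics across the discovery and targeted-validation arms.

#' Per-site recurrence record
#'
#' One screened site with mutated/screened counts in the discovery and
#' validation arms.
#'
#' @param site Site label (gene + change).
#' @param n_mutated_discovery,n_discovery Mutated and screened counts in the
#'   discovery arm.
#' @param n_mutated_validation,n_validation Mutated and screened counts in the
#'   validation arm.
#' @return A one-row tibble.
#' @export
recurrence_record <- function(site, n_mutated_discovery, n_discovery,
                              n_mutated_validation, n_validation) {
  stopifnot(n_mutated_discovery >= 0, n_mutated_discovery <= n_discovery,
            n_mutated_validation >= 0, n_mutated_validation <= n_validation)
  tibble::tibble(site = site,
                 n_mutated_discovery = as.integer(n_mutated_discovery),
                 n_discovery = as.integer(n_discovery),
                 n_mutated_validation = as.integer(n_mutated_validation),
                 n_validation = as.integer(n_validation))
}

#' Mutation frequency within one cohort arm
#'
#' `100 * mutated / screened`, rounded half-up to `digits` decimals
#' (`digits = NULL` returns the exact percentage). The published per-arm
#' numbers use one decimal (e.g. 3/24 = 12.5 %, 1/24 = 4.2 %).
#'
#' @param mutated,screened Non-negative counts, `screened > 0`.
#' @param digits Decimals for half-up rounding, or `NULL` for no rounding.
#' @return Percentage(s).
#' @examples
#' arm_frequency(3, 24)
#' @export
arm_frequency <- function(mutated, screened, digits = 1) {
  if (any(screened <= 0)) stop("screened must be positive", call. = FALSE)
  if (any(mutated < 0 | mutated > screened)) {
    stop("mutated must lie in [0, screened]", call. = FALSE)
  }
  pct <- 100 * mutated / screened
  if (is.null(digits)) pct else round_half_up(pct, digits)
}

#' Pooled mutation frequency across both arms
#'
#' `100 * (mutated_discovery + mutated_validation) / (screened_discovery +
#' screened_validation)`, rounded half-up to whole percent by default (the
#' convention of the published headline frequencies, e.g. 4/26 -> 15 %).
#'
#' @param rec A recurrence record (or table) as from [recurrence_record()].
#' @param digits Decimals for half-up rounding, or `NULL` for no rounding.
#' @return Percentage(s), one per row of `rec`.
#' @examples
#' pooled_frequency(recurrence_record("MYD88_T794C", 1, 2, 3, 24))
#' @export
pooled_frequency <- function(rec, digits = 0) {
  screened <- rec$n_discovery + rec$n_validation
  if (any(screened <= 0)) {
    stop("at least one arm must have screened samples", call. = FALSE)
  }
  pct <- 100 * (rec$n_mutated_discovery + rec$n_mutated_validation) / screened
  if (is.null(digits)) pct else round_half_up(pct, digits)
}

#' Exact (Clopper-Pearson) confidence interval for a mutation frequency
#'
#' The exact binomial interval for `mutated` out of `screened`, on the
#' percentage scale. Computed with [stats::binom.test()].
#'
#' @param mutated,screened Counts, `screened > 0`.
#' @param level Confidence level in `(0, 1)`.
#' @return Named numeric vector `c(lo, hi)` in percent.
#' @examples
#' exact_ci(3, 24)
#' @export
exact_ci <- function(mutated, screened, level = 0.95) {
  if (screened <= 0) stop("screened must be positive", call. = FALSE)
  if (level <= 0 || level >= 1) stop("invalid confidence level", call. = FALSE)
  ci <- stats::binom.test(mutated, screened, conf.level = level)$conf.int
  c(lo = 100 * ci[1], hi = 100 * ci[2])
}

#' Read a per-sample genotyping cohort table
#'
#' TSV with columns `site`, `sample_id`, `arm` (`discovery`/`validation`) and
#' `status` (`mutated`/`wildtype`/`failed`). Assays that failed are excluded
#' from denominators, with a message stating how many were dropped.
#'
#' @param path Path to the TSV.
#' @return A tibble of the retained (non-failed) rows.
#' @export
load_cohort_table <- function(path) {
  x <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                           stringsAsFactors = FALSE))
  need <- c("site", "sample_id", "arm", "status")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("cohort table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- !(x$status %in% c("mutated", "wildtype", "failed")) |
    !(x$arm %in% c("discovery", "validation"))
  if (any(bad)) {
    stop("invalid arm/status in row(s) ",
         paste(utils::head(which(bad), 10), collapse = ", "), call. = FALSE)
  }
  n_failed <- sum(x$status == "failed")
  if (n_failed > 0) {
    message(n_failed, " failed assay row(s) excluded from denominators")
  }
  x[x$status != "failed", , drop = FALSE]
}

#' Aggregate a per-sample cohort table into recurrence records
#'
#' @param cohort A tibble as returned by [load_cohort_table()].
#' @return One recurrence record per site (see [recurrence_record()]).
#' @export
aggregate_cohort <- function(cohort) {
  sites <- unique(cohort$site)
  do.call(rbind, lapply(sites, function(s) {
    sub <- cohort[cohort$site == s, , drop = FALSE]
    recurrence_record(
      s,
      sum(sub$arm == "discovery" & sub$status == "mutated"),
      sum(sub$arm == "discovery"),
      sum(sub$arm == "validation" & sub$status == "mutated"),
      sum(sub$arm == "validation")
    )
  }))
}

#' Recurrence summary table
#'
#' Per-arm and pooled frequencies with exact intervals for a set of
#' recurrence records. Per-arm percentages are rounded half-up to one
#' decimal, pooled percentages to whole percent; the Clopper-Pearson interval
#' is on the pooled counts.
#'
#' @param rec A recurrence record table.
#' @param level Confidence level for the interval.
#' @return `rec` with added columns `discovery_pct`, `validation_pct`,
#'   `pooled_pct`, `pooled_ci_lo`, `pooled_ci_hi`.
#' @examples
#' path <- system.file("extdata", "smzl_recurrence_counts.tsv",
#'                     package = "somaticmz")
#' recurrence_table(load_recurrence_counts(path))
#' @export
recurrence_table <- function(rec, level = 0.95) {
  rec <- tibble::as_tibble(rec)
  rec$discovery_pct <- arm_frequency(rec$n_mutated_discovery, rec$n_discovery)
  rec$validation_pct <- arm_frequency(rec$n_mutated_validation,
                                      rec$n_validation)
  rec$pooled_pct <- pooled_frequency(rec)
  ci <- t(mapply(function(m, s) exact_ci(m, s, level),
                 rec$n_mutated_discovery + rec$n_mutated_validation,
                 rec$n_discovery + rec$n_validation))
  rec$pooled_ci_lo <- ci[, "lo"]
  rec$pooled_ci_hi <- ci[, "hi"]
  rec
}

#' Read a per-site recurrence count table
#'
#' TSV with columns `site`, `n_mutated_discovery`, `n_discovery`,
#' `n_mutated_validation`, `n_validation` (an `assay` column, if present, is
#' carried through). The packaged
#' `extdata/smzl_recurrence_counts.tsv` holds the published screen: five
#' pyrosequenced positions over 2 discovery + 24 validation FFPE samples, and
#' the Sanger screens of the SMYD1 coding region and the NOTCH2 PEST domain
#' over 2 discovery + 8 fresh-tissue validation samples.
#'
#' @param path Path to the TSV.
#' @return A recurrence record tibble.
#' @export
load_recurrence_counts <- function(path) {
  x <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                           stringsAsFactors = FALSE))
  need <- c("site", "n_mutated_discovery", "n_discovery",
            "n_mutated_validation", "n_validation")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("recurrence table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ok <- x$n_mutated_discovery <= x$n_discovery &
    x$n_mutated_validation <= x$n_validation &
    x$n_mutated_discovery >= 0 & x$n_mutated_validation >= 0
  if (!all(ok)) {
    stop("mutated counts exceed screened counts in row(s) ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  }
  x
}
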