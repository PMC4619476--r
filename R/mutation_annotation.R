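# Classification and summarization of the somatic call set.

#' Transition or transversion?
#'
#' A substitution is a transition when it stays within the purines (A<->G) or
#' within the pyrimidines (C<->T), and a transversion otherwise. Strand
#' complementation preserves the classification, so cDNA-strand bases give the
#' same answer as genomic-strand bases.
#'
#' @param ref,alt Character vectors of single bases (A/C/G/T), `ref != alt`
#'   elementwise.
#' @return Character vector of `"transition"` / `"transversion"`.
#' @examples
#' classify_substitution("T", "C")
#' classify_substitution("G", "T")
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  if (any(!(ref %in% VALID_BASES)) || any(!(alt %in% VALID_BASES))) {
    stop("bases must be A, C, G or T", call. = FALSE)
  }
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  purine <- function(b) b %in% c("A", "G")
  ifelse(purine(ref) == purine(alt), "transition", "transversion")
}

#' Tally SIFT and PolyPhen-2 categories
#'
#' Counts the in-silico prediction categories of a call set. Categories are
#' consumed as annotated input — no scores are computed — and
#' `not_applicable` is counted separately, never folded into another class.
#'
#' @param variants A tibble with `sift` and `polyphen` columns (categories
#'   among `damaging`, `tolerated`, `stop_gained`, `not_applicable` and
#'   `benign`, `possibly_damaging`, `probably_damaging`, `not_applicable`
#'   respectively).
#' @return A list with named integer vectors `sift` and `polyphen` covering
#'   every category (zero counts included).
#' @examples
#' tally_predictions(load_discovery_snvs())$sift
#' @export
tally_predictions <- function(variants) {
  check_levels <- function(x, levels, what) {
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad)) {
      stop("unknown ", what, " category: ",
           paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    }
  }
  check_levels(variants$sift, SIFT_LEVELS, "SIFT")
  check_levels(variants$polyphen, POLYPHEN_LEVELS, "PolyPhen")
  count_on <- function(x, levels) {
    tab <- table(factor(x, levels = levels))
    stats::setNames(as.integer(tab), levels)
  }
  list(sift = count_on(variants$sift, SIFT_LEVELS),
       polyphen = count_on(variants$polyphen, POLYPHEN_LEVELS))
}

# Half-up decimal rounding (R's round() is round-half-even); reproduces the
# display convention of the published percentages.
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Summarize a somatic call set
#'
#' Order-independent tallies of a somatic SNV set: totals per case, mutation
#' classes (missense / nonsense / splice-site; a splice-site call with an
#' unchanged codon counts only as splice-site), transition/transversion
#' counts and percentages recomputed from the cDNA substitution itself, and
#' SIFT/PolyPhen-2 category tallies. Percentages are stored unrounded;
#' `ti_pct_display`/`tv_pct_display` round half-up to whole percent.
#'
#' @param variants A tibble with columns `case_id`, `ref`, `alt`,
#'   `consequence`, `sift`, `polyphen` — e.g. [load_discovery_snvs()] output.
#' @return A list of class `mutation_summary`: `n_total`, `per_case`,
#'   `class_counts`, `ti_count`, `tv_count`, `ti_pct`, `tv_pct`,
#'   `ti_pct_display`, `tv_pct_display`, `sift_counts`, `polyphen_counts`.
#' @examples
#' summarize_callset(load_discovery_snvs())$class_counts
#' @export
summarize_callset <- function(variants) {
  n <- nrow(variants)
  titv <- classify_substitution(variants$ref, variants$alt)
  ti <- sum(titv == "transition")
  tv <- sum(titv == "transversion")
  stopifnot(ti + tv == n)
  class_levels <- c("missense", "nonsense", "splice_site")
  extra <- setdiff(unique(variants$consequence), class_levels)
  if (length(extra) > 0) {
    stop("call set contains non-somatic-class consequence(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  per_case_tab <- table(variants$case_id)
  preds <- tally_predictions(variants)
  structure(list(
    n_total = n,
    per_case = stats::setNames(as.integer(per_case_tab), names(per_case_tab)),
    class_counts = stats::setNames(
      as.integer(table(factor(variants$consequence, levels = class_levels))),
      class_levels),
    ti_count = ti,
    tv_count = tv,
    ti_pct = if (n > 0) 100 * ti / n else NA_real_,
    tv_pct = if (n > 0) 100 * tv / n else NA_real_,
    ti_pct_display = if (n > 0) round_half_up(100 * ti / n) else NA_real_,
    tv_pct_display = if (n > 0) round_half_up(100 * tv / n) else NA_real_,
    sift_counts = preds$sift,
    polyphen_counts = preds$polyphen
  ), class = "mutation_summary")
}

#' @export
print.mutation_summary <- function(x, ...) {
  cat("Somatic call-set summary:", x$n_total, "single-base substitutions\n")
  cat("  per case:",
      paste(names(x$per_case), x$per_case, sep = " = ", collapse = ", "), "\n")
  cat("  classes: ",
      paste(names(x$class_counts), x$class_counts, sep = " = ",
            collapse = ", "), "\n")
  cat(sprintf("  transitions %d (%s%%), transversions %d (%s%%)\n",
              x$ti_count, format(x$ti_pct_display), x$tv_count,
              format(x$tv_pct_display)))
  cat("  SIFT damaging:", x$sift_counts[["damaging"]],
      "| PolyPhen possibly+probably damaging:",
      x$polyphen_counts[["possibly_damaging"]] +
        x$polyphen_counts[["probably_damaging"]], "\n")
  invisible(x)
}
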