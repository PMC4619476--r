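# VAF-based clonality, copy-number segment handling and allele placement
# under a single-copy gain.

#' Classify clonality from the variant allele fraction
#'
#' Bins a tumor VAF into the clonality classes used for a high-purity diploid
#' tumor: `subclonal` (VAF <= 0.25), `intermediate` (0.25 < VAF < 0.35),
#' `clonal` (0.35 <= VAF < 0.70; a heterozygous mutation carried by all tumor
#' cells at high purity sits near 0.5), `homozygous_like` (VAF >= 0.70). The
#' published ">35 %" boundary is implemented inclusively (>= 0.35); the table
#' it summarizes carries two calls at exactly 0.35 that are counted in the
#' clonal group, so only the inclusive reading reproduces the printed 9/25.
#'
#' @param vaf Numeric vector of fractions in `[0, 1]`.
#' @return Character vector of labels.
#' @examples
#' classify_clonality(c(0.15, 0.30, 0.49, 0.75))
#' @export
classify_clonality <- function(vaf) {
  if (any(is.na(vaf)) || any(vaf < 0 | vaf > 1)) {
    stop("vaf must lie in [0, 1]", call. = FALSE)
  }
  ifelse(vaf <= 0.25, "subclonal",
         ifelse(vaf < 0.35, "intermediate",
                ifelse(vaf < 0.70, "clonal", "homozygous_like")))
}

#' Filter copy-number segments
#'
#' Keeps SNP-array segments supported by at least `min_markers` SNP markers
#' and spanning at least `min_length` basepairs (1-based closed intervals:
#' length = end - start + 1). Defaults are the study's array settings
#' (5 markers, 100 kb).
#'
#' @param segments A tibble with columns `chrom`, `start`, `end`, `state`,
#'   `n_markers`.
#' @param min_markers Minimum marker count (inclusive).
#' @param min_length Minimum segment length in bp (inclusive).
#' @return The surviving segments.
#' @export
filter_segments <- function(segments, min_markers = 5L, min_length = 100000L) {
  stopifnot(all(c("chrom", "start", "end", "state", "n_markers") %in%
                  names(segments)))
  if (any(segments$end < segments$start)) {
    stop("segment end precedes start", call. = FALSE)
  }
  len <- segments$end - segments$start + 1
  keep <- segments$n_markers >= min_markers & len >= min_length
  segments[keep, , drop = FALSE]
}

#' Annotate variants with the copy-number segment they fall in
#'
#' Closed-interval overlap: a variant at `pos` lies in a segment when the
#' chromosomes match and `start <= pos <= end` (both endpoints included).
#' Segments on the same chromosome must be disjoint — one sample has one copy
#' number per locus — otherwise an error is raised. Implemented on
#' `GenomicRanges::findOverlaps`.
#'
#' @param variants A tibble with `chrom` and `pos` columns.
#' @param segments A filtered segment table (see [filter_segments()]).
#' @return `variants` with added columns `cna_state` (segment state or `NA`)
#'   and `cna_segment` (row index into `segments`, or `NA`).
#' @export
overlap_cna <- function(variants, segments) {
  out <- tibble::as_tibble(variants)
  out$cna_state <- NA_character_
  out$cna_segment <- NA_integer_
  if (nrow(segments) == 0 || nrow(variants) == 0) return(out)
  seg_gr <- GenomicRanges::GRanges(
    seqnames = as.character(segments$chrom),
    ranges = IRanges::IRanges(start = segments$start, end = segments$end))
  if (any(IRanges::width(GenomicRanges::reduce(seg_gr)) !=
          sum(IRanges::width(seg_gr))) ||
      length(GenomicRanges::reduce(seg_gr)) != length(seg_gr)) {
    # reduce() merges touching/overlapping ranges; any merge means overlap or
    # bookended duplication within one profile
    ov_self <- GenomicRanges::findOverlaps(seg_gr, drop.self = TRUE)
    if (length(ov_self) > 0) {
      stop("copy-number segments overlap on the same chromosome",
           call. = FALSE)
    }
  }
  var_gr <- GenomicRanges::GRanges(
    seqnames = as.character(variants$chrom),
    ranges = IRanges::IRanges(start = variants$pos, end = variants$pos))
  hits <- GenomicRanges::findOverlaps(var_gr, seg_gr)
  out$cna_state[S4Vectors::queryHits(hits)] <-
    segments$state[S4Vectors::subjectHits(hits)]
  out$cna_segment[S4Vectors::queryHits(hits)] <-
    S4Vectors::subjectHits(hits)
  out
}

#' Expected VAF of a mutation inside a single-copy gain
#'
#' For a tumor of purity `p` with a three-copy (single-copy gain) region, a
#' mutation present on `multiplicity` of the three tumor copies is expected at
#' VAF `p * multiplicity / (2 * (1 - p) + 3 * p)`: the denominator mixes two
#' stromal copies per impure cell with three tumor copies per tumor cell. At
#' `p = 1` this is the familiar 1/3 (non-duplicated allele) vs 2/3
#' (duplicated allele).
#'
#' @param purity Tumor cell fraction in `(0, 1]`.
#' @param multiplicity Number of mutated copies (1 = non-duplicated allele,
#'   2 = duplicated allele).
#' @return Expected variant allele fraction.
#' @export
expected_gain_vaf <- function(purity, multiplicity) {
  stopifnot(purity > 0, purity <= 1, multiplicity %in% c(1, 2))
  purity * multiplicity / (2 * (1 - purity) + 3 * purity)
}

#' Place a mutation on the duplicated or non-duplicated allele of a gain
#'
#' Under a single-copy gain in a pure tumor, a mutation on the non-duplicated
#' allele is expected in 1/3 of reads and a mutation on the duplicated allele
#' in 2/3. The binomial likelihood ratio
#' `Binom(k; n, 1/3) / Binom(k; n, 2/3)` reduces analytically to
#' `2^(n - 2k)`; the call is `non_duplicated` when the ratio is above the
#' ambiguity band, `duplicated` below it, `ambiguous` within it. With
#' `purity < 1` the two hypothesized fractions are purity-adjusted via
#' [expected_gain_vaf()] (the simple closed form no longer applies).
#'
#' @param k Variant-supporting reads, `0 <= k <= n`.
#' @param n Total reads, `n > 0`.
#' @param purity `NULL` for the pure-tumor 1/3 vs 2/3 comparison (default),
#'   or a tumor purity in `(0, 1]`.
#' @param band Two-sided ambiguity band on the likelihood ratio; calls inside
#'   `[band[1], band[2]]` are `ambiguous`. Default `[1/e, e]`.
#' @return A list of class `allele_placement`: `k`, `n`, `lr` (likelihood
#'   ratio, non-duplicated over duplicated), `log_lr`, `call`.
#' @examples
#' gain_allele_placement(14, 50) # lr = 2^22, non-duplicated
#' @export
gain_allele_placement <- function(k, n, purity = NULL,
                                  band = c(exp(-1), exp(1))) {
  stopifnot(length(k) == 1, length(n) == 1, k >= 0, k <= n,
            length(band) == 2, band[1] > 0, band[1] <= band[2])
  if (n == 0) stop("n must be positive", call. = FALSE)
  if (is.null(purity)) {
    p_nondup <- 1 / 3
    p_dup <- 2 / 3
  } else {
    stopifnot(purity > 0, purity <= 1)
    p_nondup <- expected_gain_vaf(purity, 1)
    p_dup <- expected_gain_vaf(purity, 2)
  }
  log_lr <- stats::dbinom(k, n, p_nondup, log = TRUE) -
    stats::dbinom(k, n, p_dup, log = TRUE)
  lr <- exp(log_lr)
  call <- if (log_lr > log(band[2])) {
    "non_duplicated"
  } else if (log_lr < log(band[1])) {
    "duplicated"
  } else {
    "ambiguous"
  }
  structure(list(k = k, n = n, lr = lr, log_lr = log_lr, call = call),
            class = "allele_placement")
}

#' @export
print.allele_placement <- function(x, ...) {
  cat(sprintf(
    "Gain allele placement: %d of %d reads -> LR(non-dup : dup) = %.4g -> %s\n",
    x$k, x$n, x$lr, x$call))
  invisible(x)
}
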