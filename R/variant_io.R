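# Variant containers, HGVS substitution parsing, table readers/writers and the
# packaged discovery call set.

VALID_BASES <- c("A", "C", "G", "T")

CONSEQUENCE_LEVELS <- c("missense", "nonsense", "splice_site", "synonymous",
                        "intronic", "utr", "other")

SIFT_LEVELS <- c("damaging", "tolerated", "stop_gained", "not_applicable")

POLYPHEN_LEVELS <- c("benign", "possibly_damaging", "probably_damaging",
                     "not_applicable")

# Canonical columns of a paired tumor/normal variant table (one row per locus).
PAIRED_COLUMNS <- c("case_id", "chrom", "pos", "ref", "alt", "gene",
                    "tumor_depth", "tumor_alt_reads", "tumor_vaf",
                    "normal_depth", "normal_alt_reads", "normal_vaf",
                    "quality", "consequence", "cdna_change", "protein_change",
                    "sift", "polyphen")

#' Parse an HGVS-style cDNA substitution
#'
#' Accepts single-base substitutions in the loose spellings found in clinical
#' mutation tables (`"c.794 T > C"`, `"c.8C > T"`, `"c.186T>A"`); internal
#' whitespace is normalized away before matching. Anything that is not a
#' single-base substitution (deletions, insertions, duplications, multi-base
#' changes) is a parse error.
#'
#' @param s Character vector of cDNA change strings, e.g. `"c.794 T > C"`.
#' @return A tibble with one row per input: `cdna_pos` (integer), `ref` and
#'   `alt` (upper-case single bases).
#' @examples
#' parse_cdna_change(c("c.794 T > C", "c.8C > T"))
#' @export
parse_cdna_change <- function(s) {
  stopifnot(is.character(s))
  compact <- gsub("\\s+", "", s)
  m <- regmatches(compact, regexec("^c\\.([0-9]+)([ACGTacgt])>([ACGTacgt])$",
                                   compact))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("not a single-base cDNA substitution: ",
         paste(sQuote(s[bad]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    cdna_pos = vapply(m, function(x) as.integer(x[2]), integer(1)),
    ref = toupper(vapply(m, `[`, character(1), 3)),
    alt = toupper(vapply(m, `[`, character(1), 4))
  )
}

#' Classify an HGVS-style protein change
#'
#' Maps a one-letter protein substitution string to a mutation class. A change
#' to a stop codon (`*`/`X` alternate residue, or a stop-gained flag from the
#' source annotation when the alternate residue is omitted, as in `"p.Q2364"`)
#' is `nonsense`; an unchanged residue is `splice_site` when the call is
#' flagged as affecting a splice site and `synonymous` otherwise; any other
#' residue change is `missense`.
#'
#' @param s Character vector of protein change strings (`"p.L265P"`), or `NA`
#'   for records without a protein-level annotation.
#' @param splice_site Logical vector (recycled): the call is annotated as a
#'   splice-site change.
#' @param stop_gained Logical vector (recycled): the call is annotated as
#'   stop-gained.
#' @return Character vector of classes among `missense`, `nonsense`,
#'   `splice_site`, `synonymous`; `NA` input yields `"other"`.
#' @examples
#' parse_protein_change("p.L265P")
#' parse_protein_change("p.E95E", splice_site = TRUE)
#' parse_protein_change("p.Q2364", stop_gained = TRUE)
#' @export
parse_protein_change <- function(s, splice_site = FALSE, stop_gained = FALSE) {
  stopifnot(is.character(s))
  n <- length(s)
  splice_site <- rep_len(as.logical(splice_site), n)
  stop_gained <- rep_len(as.logical(stop_gained), n)
  out <- character(n)
  for (i in seq_len(n)) {
    if (is.na(s[i]) || s[i] == "") {
      out[i] <- "other"
      next
    }
    compact <- gsub("\\s+", "", s[i])
    m <- regmatches(compact,
                    regexec("^p\\.([A-Za-z])([0-9]+)([A-Za-z*]?)$", compact))[[1]]
    if (length(m) == 0L) {
      stop("malformed protein change: ", sQuote(s[i]), call. = FALSE)
    }
    ref_aa <- toupper(m[2])
    alt_aa <- toupper(m[4])
    out[i] <-
      if (alt_aa %in% c("*", "X") || (alt_aa == "" && stop_gained[i])) {
        "nonsense"
      } else if (alt_aa == "") {
        stop("protein change lacks an alternate residue and is not flagged ",
             "stop-gained: ", sQuote(s[i]), call. = FALSE)
      } else if (ref_aa != alt_aa) {
        "missense"
      } else if (splice_site[i]) {
        "splice_site"
      } else {
        "synonymous"
      }
  }
  out
}

#' Validate a paired tumor/normal variant table
#'
#' Checks the column contract and the record-level invariants: bases are
#' single nucleotides with `ref != alt`, depths are non-negative, alt-read
#' counts do not exceed depths, VAFs lie in `[0, 1]` and agree with
#' `alt_reads / depth` to within 0.005 (absorbing two-decimal display
#' rounding) wherever both are present.
#'
#' @param x A data frame with the columns of [load_variant_table()].
#' @return `x` as a tibble, invisibly classed; errors describe the offending
#'   rows by number.
#' @export
validate_variant_table <- function(x) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(PAIRED_COLUMNS, names(x))
  if (length(missing_cols) > 0) {
    stop("variant table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fail <- function(which, what) {
    if (any(which, na.rm = TRUE)) {
      stop("invalid variant table, ", what, " in row(s) ",
           paste(utils::head(which(which), 10), collapse = ", "),
           call. = FALSE)
    }
  }
  fail(!(x$ref %in% VALID_BASES) | !(x$alt %in% VALID_BASES),
       "ref/alt not a single A/C/G/T base")
  fail(x$ref == x$alt, "ref equals alt")
  fail(x$tumor_depth < 0 | (!is.na(x$normal_depth) & x$normal_depth < 0),
       "negative depth")
  for (side in c("tumor", "normal")) {
    vaf <- x[[paste0(side, "_vaf")]]
    depth <- x[[paste0(side, "_depth")]]
    alt <- x[[paste0(side, "_alt_reads")]]
    fail(!is.na(vaf) & (vaf < 0 | vaf > 1), paste(side, "VAF outside [0, 1]"))
    fail(!is.na(alt) & !is.na(depth) & alt > depth,
         paste(side, "alt reads exceed depth"))
    ok <- !is.na(vaf) & !is.na(alt) & !is.na(depth) & depth > 0
    fail(ok & abs(vaf - alt / depth) > 0.005 + 1e-9,
         paste(side, "VAF inconsistent with alt_reads/depth"))
  }
  bad_csq <- !is.na(x$consequence) & !(x$consequence %in% CONSEQUENCE_LEVELS)
  fail(bad_csq, "unknown consequence class")
  x
}

#' Read a paired tumor/normal variant table
#'
#' Two dialects are supported. `"tsv"` expects the canonical columns
#' `case_id, chrom, pos, ref, alt, gene, tumor_depth, tumor_alt_reads,
#' tumor_vaf, normal_depth, normal_alt_reads, normal_vaf, quality,
#' consequence, cdna_change, protein_change, sift, polyphen` (missing
#' annotation values may be `NA`). `"vcf"` expects a VCF 4.2 file with
#' `TUMOR` and `NORMAL` sample columns carrying `DP` and `AD` (ref,alt) and
#' the annotation fields in INFO as written by [write_variant_table()];
#' parsing is done with the vcfR package.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return A validated tibble, one row per paired variant, input order
#'   preserved.
#' @export
load_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- switch(dialect, tsv = read_paired_tsv(path), vcf = read_paired_vcf(path))
  validate_variant_table(x)
}

read_paired_tsv <- function(path) {
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         na.strings = c("NA", ""), check.names = FALSE)
  if ("chrom" %in% names(x)) x$chrom <- as.character(x$chrom)
  tibble::as_tibble(x)
}

read_paired_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_field <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    ifelse(val == ".", NA_character_, val)
  }
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")
  alt_of <- function(ad_str) {
    as.integer(vapply(strsplit(ad_str, ","), `[`, character(1), 2))
  }
  if (!all(c("TUMOR", "NORMAL") %in% colnames(dp))) {
    stop("VCF must carry TUMOR and NORMAL sample columns", call. = FALSE)
  }
  t_alt <- alt_of(ad[, "TUMOR"])
  n_alt <- alt_of(ad[, "NORMAL"])
  t_dp <- as.integer(dp[, "TUMOR"])
  n_dp <- as.integer(dp[, "NORMAL"])
  tibble::tibble(
    case_id = info_field("CASE"),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gene = info_field("GENE"),
    tumor_depth = t_dp,
    tumor_alt_reads = t_alt,
    tumor_vaf = as.numeric(info_field("TVAF")),
    normal_depth = n_dp,
    normal_alt_reads = n_alt,
    normal_vaf = as.numeric(info_field("NVAF")),
    quality = as.numeric(fix$QUAL),
    consequence = info_field("CSQ"),
    cdna_change = decode_info(info_field("CDNA")),
    protein_change = decode_info(info_field("AA")),
    sift = info_field("SIFT"),
    polyphen = info_field("PPH")
  )
}

# INFO strings must not contain spaces; spaces are carried as underscores.
encode_info <- function(x) {
  x <- gsub(" ", "_", x)
  ifelse(is.na(x) | x == "", ".", x)
}

decode_info <- function(x) gsub("_", " ", x)

#' Write a paired tumor/normal variant table
#'
#' The `"tsv"` dialect writes the canonical columns of
#' [load_variant_table()]; fractions are written with six decimals. The
#' `"vcf"` dialect writes a minimal VCF 4.2 file with `TUMOR`/`NORMAL` sample
#' columns (`GT:DP:AD`), the call quality in `QUAL`, and the annotations in
#' INFO (`CASE`, `GENE`, `CSQ`, `CDNA`, `AA`, `SIFT`, `PPH`, `TVAF`, `NVAF`).
#'
#' @param x A variant table (validated on the way out).
#' @param path Output path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  x <- validate_variant_table(x)
  if (dialect == "tsv") {
    out <- x
    for (col in c("tumor_vaf", "normal_vaf")) {
      out[[col]] <- formatC(out[[col]], digits = 6, format = "f")
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  } else {
    write_paired_vcf(x, path)
  }
  invisible(path)
}

write_paired_vcf <- function(x, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=somaticmz",
    "##INFO=<ID=CASE,Number=1,Type=String,Description=\"Case identifier\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=CDNA,Number=1,Type=String,Description=\"cDNA change (HGVS-like)\">",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Protein change (HGVS-like)\">",
    "##INFO=<ID=SIFT,Number=1,Type=String,Description=\"SIFT category\">",
    "##INFO=<ID=PPH,Number=1,Type=String,Description=\"PolyPhen-2 category\">",
    "##INFO=<ID=TVAF,Number=1,Type=Float,Description=\"Tumor variant allele fraction\">",
    "##INFO=<ID=NVAF,Number=1,Type=Float,Description=\"Normal variant allele fraction\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TUMOR", "NORMAL", sep = "\t")
  )
  num6 <- function(v) ifelse(is.na(v), ".", formatC(v, digits = 6, format = "f"))
  info <- paste0(
    "CASE=", encode_info(x$case_id),
    ";GENE=", encode_info(x$gene),
    ";CSQ=", encode_info(x$consequence),
    ";CDNA=", encode_info(x$cdna_change),
    ";AA=", encode_info(x$protein_change),
    ";SIFT=", encode_info(x$sift),
    ";PPH=", encode_info(x$polyphen),
    ";TVAF=", num6(x$tumor_vaf),
    ";NVAF=", num6(x$normal_vaf)
  )
  sample_field <- function(depth, alt) {
    ifelse(is.na(depth), "./.:.:.",
           paste0("0/1:", depth, ":", depth - alt, ",", alt))
  }
  records <- paste(x$chrom, x$pos, ".", x$ref, x$alt,
                   ifelse(is.na(x$quality), ".", x$quality), "PASS", info,
                   "GT:DP:AD",
                   sample_field(x$tumor_depth, x$tumor_alt_reads),
                   sample_field(x$normal_depth, x$normal_alt_reads),
                   sep = "\t")
  writeLines(c(header, records), path)
}

#' Load the packaged SMZL discovery call set
#'
#' The 25 somatic SNVs called by whole-exome sequencing of laser-microdissected
#' tumor cells from two SMZL discovery cases (12 in case 1, 13 in case 2), as
#' published: per variant the gene, locus, tumor coverage and SNV frequency,
#' the novel-allele call quality, HGVS-style cDNA and protein changes, and
#' SIFT/PolyPhen-2 categories. `ref`/`alt` are the cDNA-strand bases of the
#' substitution; `alt_reads` is reconstructed as `round(depth * vaf)` (the
#' source table prints the fraction, not the count) and agrees with the
#' printed fraction to within 0.005 for every record. The consequence class is
#' derived from the protein change and the table's splice-site / stop-gained
#' flags.
#'
#' @return A tibble of 25 variant observations with columns `gene`, `case_id`,
#'   `chrom`, `pos`, `exon`, `depth`, `alt_reads`, `vaf`, `quality`,
#'   `cdna_change`, `protein_change`, `cdna_pos`, `ref`, `alt`,
#'   `consequence`, `sift`, `polyphen`.
#' @examples
#' snvs <- load_discovery_snvs()
#' table(snvs$case_id)
#' @export
load_discovery_snvs <- function() {
  path <- system.file("extdata", "smzl_discovery_snvs.tsv",
                      package = "somaticmz", mustWork = TRUE)
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = "NA", fill = TRUE, check.names = FALSE)
  raw$footnote[is.na(raw$footnote)] <- ""
  cdna <- parse_cdna_change(raw$nucleotide_change)
  consequence <- parse_protein_change(
    raw$aa_change,
    splice_site = raw$footnote == "splice site",
    stop_gained = raw$footnote == "stop gained"
  )
  sift_map <- c("Damaging" = "damaging", "Tolerated" = "tolerated",
                "Stop gained" = "stop_gained", "N/A" = "not_applicable")
  pph_map <- c("Benign" = "benign", "Possibly damaging" = "possibly_damaging",
               "Probably damaging" = "probably_damaging",
               "N/A" = "not_applicable")
  tibble::tibble(
    gene = raw$gene,
    case_id = raw$case,
    chrom = as.character(raw$chrom),
    pos = as.integer(raw$position),
    exon = raw$exon,
    depth = as.integer(raw$coverage_tumor),
    alt_reads = as.integer(round(raw$coverage_tumor * raw$snv_frequency)),
    vaf = raw$snv_frequency,
    quality = raw$quality_score,
    cdna_change = raw$nucleotide_change,
    protein_change = raw$aa_change,
    cdna_pos = cdna$cdna_pos,
    ref = cdna$ref,
    alt = cdna$alt,
    consequence = consequence,
    sift = unname(sift_map[raw$sift_prediction]),
    polyphen = unname(pph_map[raw$polyphen_prediction])
  )
}

#' Promote single-sample observations to a paired table
#'
#' Builds a paired tumor/normal variant table from tumor-only observations
#' (e.g. the packaged discovery call set), taking the matched normal to carry
#' no variant reads. Useful for pushing a published somatic call set back
#' through the cascade.
#'
#' @param obs A tibble like [load_discovery_snvs()] output.
#' @param normal_depth Depth assumed for the normal sample at each locus.
#' @return A paired variant table (see [load_variant_table()]).
#' @export
as_paired_table <- function(obs, normal_depth = obs$depth) {
  validate_variant_table(tibble::tibble(
    case_id = obs$case_id,
    chrom = obs$chrom,
    pos = obs$pos,
    ref = obs$ref,
    alt = obs$alt,
    gene = obs$gene,
    tumor_depth = obs$depth,
    tumor_alt_reads = obs$alt_reads,
    tumor_vaf = obs$vaf,
    normal_depth = as.integer(normal_depth),
    normal_alt_reads = 0L,
    normal_vaf = 0,
    quality = obs$quality,
    consequence = obs$consequence,
    cdna_change = obs$cdna_change,
    protein_change = obs$protein_change,
    sift = obs$sift,
    polyphen = obs$polyphen
  ))
}

#' Read a known-polymorphism blacklist
#'
#' A TSV of loci (`chrom`, `pos`, `ref`, `alt`) that are previously described
#' polymorphisms; used by [filter_polymorphisms()].
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
load_polymorphism_blacklist <- function(path) {
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("blacklist lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(x[need])
}
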