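---
title: "Somatic SNV discovery and clonality in microdissected SMZL exomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic SNV discovery and clonality in microdissected SMZL exomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticmz)
```

## The problem and the model

Splenic marginal zone lymphoma (SMZL) lacks a signature mutation, and its
exome studies rest on a small number of paired tumor/normal comparisons.
Laser microdissection of tumor cells raises tumor purity to roughly
0.87–0.89, which changes what a variant allele fraction (VAF) means: a
heterozygous mutation carried by every tumor cell is expected at
`f = p/2 ≈ 0.44`, so the VAF axis itself becomes a clonality readout, and
simple threshold rules on paired VAFs separate somatic variants from
germline heterozygotes (expected `f ≈ 0.5` in both tissues).

This package implements that workflow: a deterministic filtering cascade, a
set of call-set summaries, VAF clonality, copy-number segment handling with
a binomial allele-placement test, recurrence statistics over a validation
cohort, and a generative model of the whole design for testing.

## The filtering cascade

`run_cascade()` applies four stages in a fixed order and reports per-stage
attrition, so order effects are visible rather than implicit:

1. **Consequence**: intronic, UTR and synonymous calls are removed.
   Splice-site calls are a class of their own and survive even when the
   codon is unchanged.
2. **Call quality**: calls below `mean − k·sd` of the novel-allele quality
   distribution are discarded, with `k = 2` and the sample (n−1) standard
   deviation. The threshold is computed *within each case*: each
   sequencing run has its own quality scale, so a pooled threshold would
   let a high-quality run mask a low-quality one. The n−1 denominator is a
   documented choice (the convention is not fixed by the design);
   `filter_config(quality_sd_multiplier=)` exposes `k`.
3. **Paired somatic rules**, evaluated in order with the first failure
   reported per variant: tumor depth ≥ 20, tumor VAF ≥ 0.1, normal
   VAF < 0.2, tumor−normal delta ≥ 0.1. All "minimum/at least" bounds are
   inclusive; the normal ceiling is strict. A missing normal observation is
   treated as normal VAF 0 and flagged with a message — the alternative
   (dropping the site) silently discards exactly the loci where the tumor
   signal is strongest.
4. **Known polymorphisms**: exact `(chrom, pos, ref, alt)` match against a
   blacklist.

The tumor-VAF floor is applied inside the somatic rule block rather than
before pairing; with the inclusive/strict readings above this is
equivalent for any variant that has a normal observation, and it keeps the
attrition report interpretable.

### A note on idempotence

The quality stage is data-adaptive, and re-filtering a filtered set can
tighten the threshold: for qualities {3, 14, 20×8} the first pass removes
the 3, after which `mean − 2·sd` of the survivors rises above 14. Re-running
a call set through the cascade is therefore only guaranteed to be a no-op
when the threshold is frozen, which is what reprocessing should do:
`run_cascade()` records the per-case thresholds it used in its report, and
`filter_config(quality_threshold=)` accepts them back. Under a bounded
quality distribution (such as the packaged call set's, range 17–32, or the
simulator's uniform draw) the adaptive threshold falls below the support
and the cascade is idempotent as-is; both behaviours are tested.

## Call-set summaries

`summarize_callset()` recomputes everything from primary fields rather than
stored labels: transition/transversion status from the substitution's own
bases (strand complementation preserves the classification, so cDNA-strand
bases are sufficient), mutation classes from the parsed protein change, and
SIFT/PolyPhen-2 tallies from the annotated categories (the package never
computes prediction scores; `not_applicable` is counted separately, and
SIFT's stop-gained annotation is kept as its own category). Percentages are
stored unrounded; display values round half-up to whole percent, matching
the published convention. On the packaged 25-SNV discovery set this yields
23 missense / 1 splice-site / 1 nonsense, 16 transitions (64%) / 9
transversions (36%), SIFT damaging 10/25 and PolyPhen possibly-or-probably
damaging 13/25.

## Clonality and copy number

`classify_clonality()` partitions the VAF axis at 0.25, 0.35 and 0.70. The
boundary of the clonal band is implemented **inclusively** (≥ 0.35): the
discovery set contains two calls at exactly 0.35, and only the inclusive
reading reproduces the published count of 9 mutations in the clonal range.
The subclonal bound is ≤ 0.25, also inclusive, per the published wording.
On the packaged set this gives 12 subclonal, 9 clonal, 0 homozygous-like.

Copy-number segments are consumed as input (no segmentation is performed),
filtered at ≥ 5 SNP markers and ≥ 100 kb, and overlapped with variants as
1-based fully closed intervals on both sides — the convention of the
variant coordinates; the array platform's convention is not stated, and the
closed choice is documented rather than silently assumed. Segments within a
profile must be disjoint (one copy number per locus); overlap is an error,
not a warning.

`gain_allele_placement(k, n)` compares the two hypotheses for a mutation
inside a single-copy gain — non-duplicated allele (expected read fraction
1/3) versus duplicated (2/3) — by binomial likelihood ratio, which reduces
to `2^(n−2k)`. Calls within `[1/e, e]` are reported `ambiguous`; the band
is configurable because the underlying decision in the source analysis was
qualitative, and one log-unit is a conventional "barely worth mentioning"
evidence band. A purity-adjusted variant replaces 1/3 and 2/3 with
`p·m / (2(1−p) + 3p)` for multiplicity `m`; the default ignores purity
because at `p ≈ 0.88` the adjustment moves the expected fractions by < 0.03
and never changes the direction of the comparison.

## Recurrence statistics

Per-arm frequencies are `100·mutated/screened` rounded half-up to one
decimal; pooled frequencies sum both arms before dividing and round to
whole percent — the two conventions of the published numbers. Pooling the
two discovery exomes with the validation samples assumes exchangeability
across arms; the pooled denominators are 26 (2 + 24 pyrosequenced FFPE
samples) for the single-position screens and 10 (2 + 8 fresh-tissue Sanger
screens) for the gene-level screens, reproducing 15% (MYD88), 30% (SMYD1)
and 10% (NOTCH2 PEST). `exact_ci()` adds Clopper–Pearson intervals — not
part of the source analysis, but the minimal honest uncertainty statement
for proportions from 8–26 samples.

## The synthetic cohort

`simulate_pair()` draws per-locus depths (Poisson with mean 47 by default;
a negative-binomial option adds overdispersion, which the design's summary
statistics neither require nor exclude) and read counts from the binomial
model: germline heterozygotes at expected fraction 0.5 in both tissues,
somatic variants at `purity·CCF/2` on diploid loci (purity 0.88; CCF
mixture 1.0/0.5/0.25 with weights 0.5/0.3/0.2 — a clonal backbone plus two
subclone tiers consistent with roughly half of the observed calls sitting
at VAF ≤ 0.25), sequencing artifacts at an error rate of 0.001 in the tumor
only (a typical substitution-error scale for short-read platforms; the
true platform rate is not published and the parameter is configurable), and
known polymorphisms as heterozygotes whose sites are also returned as the
blacklist. Somatic loci inside a simulated gain segment switch to the
multiplicity-aware expected fraction, with the allele recorded in the truth
labels. Call qualities are uniform on [20, 32]: a bounded distribution
keeps all mass within ~1.73 sd of the mean, so the mean−2·sd rule removes
no true calls at scale — the regime the real call set exhibits, where every
record clears the threshold computed on its own case. A Gaussian quality
model would instead lose a fixed ~2.3% of true calls to the 2-sd rule by
construction.

What the generator does *not* emulate: read-level errors with context-
specific substitution spectra, FFPE deamination damage, mapping artifacts,
correlated depth along the genome, and real polymorphism frequencies.
Passing recovery tests therefore show that the cascade implements its rules
correctly under the stated statistical model — not that the thresholds are
optimal for any particular real dataset.

## Validation scale and observed behaviour

The test suite and acceptance script validate the pipeline at the study's
own scale: ~10⁴ simulated loci (6,000 germline + 4,000 somatic) for
recovery — clonal (CCF 1) somatic recovery and germline rejection both
≥ 99%, as binomial tail bounds at depth 47 predict — and 20 replicates of
50 somatic loci for purity recovery, where twice the median clonal VAF
re-estimates purity 0.88. A single replicate's estimator (median of ~25
binomial fractions at depth 47) has a standard error near 0.036, so
individual replicates scatter beyond ±0.05 by design; the accuracy claim is
made for the median over the 20 replicates (standard error ≈ 0.01). These
sizes run in seconds and leave the binomial standard errors comfortably
inside every asserted tolerance.

## Known limitations

* The cascade reproduces threshold *rules*, not the upstream caller: the
  published 216 → 25 attrition depends on raw per-variant germline calls
  that were never deposited, so it cannot be regression-tested; the
  cascade's correctness is instead established against a brute-force oracle
  and the synthetic truth labels.
* The clonality bands assume a diploid locus in a high-purity tumor;
  variants inside copy-number aberrations need the multiplicity-aware
  reasoning of the placement test instead.
* No indels, no multi-allelic records, no annotation of consequences from
  genomic context — consequence categories, like prediction categories, are
  consumed as input.
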