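test_that("clonality labels partition the VAF axis at 0.25, 0.35 and 0.70", {
  expect_equal(classify_clonality(c(0.15, 0.25, 0.30, 0.35, 0.49, 0.69, 0.70,
                                    0.75, 1.0)),
               c("subclonal", "subclonal", "intermediate", "clonal", "clonal",
                 "clonal", "homozygous_like", "homozygous_like",
                 "homozygous_like"))
  expect_error(classify_clonality(1.2), "\\[0, 1\\]")
  expect_error(classify_clonality(-0.1), "\\[0, 1\\]")
})

test_that("fixture VAFs yield the published clonality split", {
  snvs <- load_discovery_snvs()
  labels <- classify_clonality(snvs$vaf)
  expect_equal(sum(labels == "subclonal"), 12L)
  expect_equal(sum(labels %in% c("clonal", "homozygous_like")), 9L)
  expect_equal(sum(labels == "homozygous_like"), 0L)
})

test_that("segment filtering enforces marker and length floors inclusively", {
  segs <- tibble::tibble(
    chrom = "1",
    start = c(1L, 1L, 1L, 1L),
    end = c(150000L, 500000L, 99999L, 100000L),
    state = "gain",
    n_markers = c(5L, 4L, 10L, 5L)
  )
  kept <- filter_segments(segs)
  expect_equal(kept$end, c(150000L, 100000L)) # 5/150kb and the exact 100kb
  expect_error(filter_segments(transform(segs, end = 0L)), "precedes")
})

test_that("variant-segment overlap uses closed intervals on both ends", {
  segs <- tibble::tibble(chrom = "3", start = 100L, end = 200L,
                         state = "gain", n_markers = 10L)
  v <- tibble::tibble(chrom = c("3", "3", "3", "3", "5"),
                      pos = c(99L, 100L, 200L, 201L, 150L))
  out <- overlap_cna(v, segs)
  expect_equal(out$cna_state, c(NA, "gain", "gain", NA, NA))
})

test_that("overlapping segments on one chromosome are rejected", {
  segs <- tibble::tibble(chrom = c("3", "3"), start = c(100L, 150L),
                         end = c(200L, 250L), state = c("gain", "loss"),
                         n_markers = c(10L, 10L))
  v <- tibble::tibble(chrom = "3", pos = 160L)
  expect_error(overlap_cna(v, segs), "overlap")
  # abutting segments are distinct states, not an overlap
  abut <- segs
  abut$start[2] <- 201L
  abut$end[2] <- 300L
  expect_equal(overlap_cna(v, abut)$cna_state, "gain")
})

test_that("overlap annotation agrees with a brute-force all-pairs scan", {
  set.seed(41)
  for (rep in 1:3) {
    n_seg <- 40
    starts <- sort(sample.int(1e6L, n_seg)) * 50L
    segs <- tibble::tibble(
      chrom = as.character(sample(1:5, n_seg, replace = TRUE)),
      start = starts,
      end = starts + sample.int(40L, n_seg),
      state = sample(c("gain", "loss", "neutral-LOH"), n_seg, replace = TRUE),
      n_markers = 10L
    )
    v <- tibble::tibble(
      chrom = as.character(sample(1:5, 500, replace = TRUE)),
      pos = sample.int(5e7L, 500)
    )
    out <- overlap_cna(v, segs)
    brute <- rep(NA_character_, nrow(v))
    for (i in seq_len(nrow(v))) {
      for (j in seq_len(n_seg)) {
        if (v$chrom[i] == segs$chrom[j] && v$pos[i] >= segs$start[j] &&
            v$pos[i] <= segs$end[j]) {
          brute[i] <- segs$state[j]
        }
      }
    }
    expect_equal(out$cna_state, brute)
  }
})

test_that("gain allele placement matches the analytic 2^(n-2k) form", {
  p <- gain_allele_placement(14, 50)
  expect_equal(p$lr, 2^22)
  expect_equal(p$call, "non_duplicated")
  for (n in c(1, 7, 23, 60)) {
    for (k in 0:n) {
      expect_equal(gain_allele_placement(k, n)$lr, 2^(n - 2 * k),
                   tolerance = 1e-10)
    }
  }
})

test_that("placement calls flip at the expected read fractions", {
  expect_equal(gain_allele_placement(40, 60)$call, "duplicated") # k = 2n/3
  expect_equal(gain_allele_placement(30, 60)$call, "ambiguous")  # lr = 2^0
  expect_error(gain_allele_placement(0, 0), "positive")
  expect_error(gain_allele_placement(5, 3))
})

test_that("purity-adjusted placement uses the mixed-copy expected VAFs", {
  expect_equal(expected_gain_vaf(1, 1), 1 / 3)
  expect_equal(expected_gain_vaf(1, 2), 2 / 3)
  expect_equal(expected_gain_vaf(0.88, 1), 0.88 / (2 * 0.12 + 3 * 0.88))
  adj <- gain_allele_placement(14, 50, purity = 0.88)
  expect_equal(adj$lr,
               dbinom(14, 50, expected_gain_vaf(0.88, 1)) /
                 dbinom(14, 50, expected_gain_vaf(0.88, 2)))
  expect_equal(adj$call, "non_duplicated")
})
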