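test_that("the adaptive quality threshold is mean minus k sample sd", {
  expect_equal(quality_threshold(c(30, 30, 30)), 30)
  expect_equal(quality_threshold(c(10, 20, 30)), 0) # mean 20, sample sd 10
  expect_equal(quality_threshold(42), 42)           # single call: sd 0
  expect_error(quality_threshold(numeric(0)), "non-empty")
})

test_that("quality filtering removes the low tail per case", {
  qualities <- c(10, rep(30, 9)) # mean 28, sd ~6.32, threshold ~15.35
  tbl <- random_paired_table(10, seed = 7)
  tbl$case_id <- "caseA"
  tbl$quality <- qualities
  out <- filter_by_quality(tbl, filter_config())
  expect_equal(nrow(out$removed), 1L)
  expect_equal(out$removed$quality, 10)
  expect_equal(unname(out$thresholds["caseA"]), 28 - 2 * sd(qualities))

  flat <- tbl
  flat$quality <- rep(25, 10)
  expect_equal(nrow(filter_by_quality(flat, filter_config())$removed), 0L)
})

test_that("every packaged discovery record clears its own case's threshold", {
  tbl <- as_paired_table(load_discovery_snvs())
  out <- filter_by_quality(tbl, filter_config())
  expect_equal(nrow(out$kept), 25L)
})

test_that("consequence filtering drops silent classes but keeps splice sites", {
  tbl <- random_paired_table(6, seed = 1)
  tbl$consequence <- c("missense", "intronic", "splice_site", "synonymous",
                       "utr", "nonsense")
  out <- filter_consequence(tbl, filter_config())
  expect_setequal(out$kept$consequence, c("missense", "splice_site", "nonsense"))
  expect_setequal(out$removed$consequence, c("intronic", "synonymous", "utr"))
})

test_that("somatic rules fire in order: coverage, tumor VAF, normal VAF, delta", {
  mk <- function(depth, tvaf, nvaf) {
    tbl <- random_paired_table(1, seed = 2)
    tbl$tumor_depth <- depth
    tbl$tumor_alt_reads <- as.integer(round(depth * tvaf))
    tbl$tumor_vaf <- tbl$tumor_alt_reads / depth
    tbl$normal_depth <- 50L
    tbl$normal_alt_reads <- as.integer(round(50 * nvaf))
    tbl$normal_vaf <- tbl$normal_alt_reads / 50
    tbl
  }
  expect_equal(call_somatic(mk(49, 0.49, 0.0)), "somatic")
  expect_equal(call_somatic(mk(50, 0.50, 0.5)), "normal_vaf") # germline het
  expect_equal(call_somatic(mk(19, 0.50, 0.0)), "coverage")   # just below 20
  expect_equal(call_somatic(mk(50, 0.08, 0.0)), "tumor_vaf")
  expect_equal(call_somatic(mk(50, 0.26, 0.18)), "delta")
  # boundary inclusivity: >= for minima, strict < for the normal ceiling
  expect_equal(call_somatic(mk(20, 0.10, 0.0)), "somatic")
  expect_equal(call_somatic(mk(50, 0.30, 0.20)), "normal_vaf")
  expect_equal(call_somatic(mk(50, 0.28, 0.18)), "somatic")   # delta exactly 0.1
})

test_that("a missing normal observation is assumed wild-type, with a message", {
  tbl <- random_paired_table(1, seed = 3)
  tbl$tumor_depth <- 40L; tbl$tumor_alt_reads <- 20L; tbl$tumor_vaf <- 0.5
  tbl$normal_vaf <- NA_real_
  expect_message(dec <- call_somatic(tbl), "assuming normal VAF 0")
  expect_equal(dec, "somatic")
})

test_that("polymorphism removal is exact on (chrom, pos, ref, alt)", {
  tbl <- random_paired_table(50, seed = 11)
  k <- 7
  bl <- tbl[sample(50, k), c("chrom", "pos", "ref", "alt")]
  out <- filter_polymorphisms(tbl, bl)
  expect_equal(nrow(out$removed), k)
  expect_setequal(variant_key(out$removed), variant_key(bl))
  expect_equal(nrow(filter_polymorphisms(tbl, NULL)$kept), 50L)
  expect_equal(nrow(filter_polymorphisms(tbl, bl[0, ])$kept), 50L)
})

test_that("the cascade conserves counts and reports per-stage attrition", {
  for (seed in c(5, 17)) {
    tbl <- random_paired_table(120, seed = seed)
    bl <- tbl[sample(120, 10), c("chrom", "pos", "ref", "alt")]
    res <- run_cascade(tbl, filter_config(), bl)
    rep <- res$report
    expect_equal(rep$n_input, 120L)
    expect_true(all(diff(c(rep$n_input, rep$n_after_consequence,
                           rep$n_after_quality, rep$n_after_somatic_rules,
                           rep$n_after_polymorphism)) <= 0))
    expect_equal(rep$n_input, nrow(res$somatic) + nrow(rep$removed))
    expect_equal(nrow(res$somatic), rep$n_after_polymorphism)
  }
})

test_that("a cohort of pure germline heterozygotes yields no somatic calls", {
  sim <- simulate_pair(simulation_config(n_germline_het = 300, n_somatic = 0,
                                         seed = 21))
  res <- run_cascade(sim$variants)
  expect_equal(nrow(res$somatic), 0L)
})

test_that("the cascade agrees with an independent brute-force filter", {
  for (seed in c(1, 2, 3)) {
    n <- sample(c(50, 120, 200), 1)
    tbl <- random_paired_table(n, seed = seed)
    bl <- tbl[sample(n, 5), c("chrom", "pos", "ref", "alt")]
    res <- run_cascade(tbl, filter_config(), bl)
    oracle <- brute_force_cascade(tbl, filter_config(), bl)
    expect_setequal(variant_key(res$somatic), variant_key(oracle))
  }
})

test_that("raising any threshold never adds a somatic call", {
  tbl <- random_paired_table(150, seed = 23)
  base <- variant_key(run_cascade(tbl, filter_config())$somatic)
  stricter <- list(
    filter_config(min_coverage = 30),
    filter_config(min_tumor_vaf = 0.2),
    filter_config(max_normal_vaf = 0.1),
    filter_config(min_delta = 0.2),
    filter_config(quality_sd_multiplier = 1),
    filter_config(drop_consequences = c("synonymous", "intronic", "utr",
                                        "nonsense"))
  )
  for (cfg in stricter) {
    expect_true(all(variant_key(run_cascade(tbl, cfg)$somatic) %in% base))
  }
})

test_that("reprocessing a call set with the cascade's own thresholds is idempotent", {
  tbl <- random_paired_table(200, seed = 31)
  first <- run_cascade(tbl, filter_config())
  frozen <- filter_config(quality_threshold = first$report$quality_thresholds)
  second <- run_cascade(first$somatic, frozen)
  expect_equal(variant_key(second$somatic), variant_key(first$somatic))
  expect_equal(nrow(second$report$removed), 0L)
})

test_that("the adaptive cascade is idempotent under a bounded quality regime", {
  # uniform qualities keep all mass within ~1.73 sd of the mean, so the
  # mean-minus-2-sd rule never re-trims a filtered set
  sim <- simulate_pair(simulation_config(n_germline_het = 500, n_somatic = 500,
                                         seed = 37))
  first <- run_cascade(sim$variants)
  second <- run_cascade(first$somatic)
  expect_equal(variant_key(second$somatic), variant_key(first$somatic))
})
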