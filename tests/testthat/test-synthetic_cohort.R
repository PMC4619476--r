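test_that("simulation configs are validated", {
  expect_error(simulation_config(purity = 0), "purity")
  expect_error(simulation_config(purity = 1.1), "purity")
  expect_error(simulation_config(ccf_weights = c(0.5, 0.3, 0.3)), "sum to 1")
  expect_error(simulation_config(ccf_levels = c(1, 0.5),
                                 ccf_weights = c(0.5, 0.3, 0.2)), "ccf_levels")
  expect_error(simulation_config(error_rate = 0.9), "error_rate")
  expect_error(simulation_config(mean_depth = -1), "mean_depth")
})

test_that("the same seed reproduces the same cohort", {
  cfg <- simulation_config(n_germline_het = 50, n_somatic = 30,
                           n_polymorphisms = 10, seed = 5)
  a <- simulate_pair(cfg)
  b <- simulate_pair(cfg)
  expect_identical(a$variants, b$variants)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$blacklist), 10L)
})

test_that("simulated read counts follow the purity-scaled binomial model", {
  cfg <- simulation_config(n_germline_het = 0, n_somatic = 100,
                           ccf_levels = 1, ccf_weights = 1, seed = 8)
  sim <- simulate_pair(cfg)
  # expected clonal VAF = purity / 2 = 0.44; binomial SE at mean depth 47
  se <- sqrt(0.44 * 0.56 / 47) / sqrt(100)
  expect_lt(abs(mean(sim$variants$tumor_vaf) - 0.44), 3 * se)
  expect_true(all(sim$variants$quality >= 20 & sim$variants$quality <= 32))

  het <- simulate_pair(simulation_config(n_germline_het = 200, n_somatic = 0,
                                         seed = 9))
  se_het <- sqrt(0.25 / 47) / sqrt(200)
  expect_lt(abs(mean(het$variants$normal_vaf) - 0.5), 3 * se_het)

  nb <- simulate_pair(simulation_config(depth_model = "negative_binomial",
                                        n_germline_het = 200, n_somatic = 0,
                                        dispersion = 5, seed = 10))
  expect_gt(var(nb$variants$tumor_depth), var(het$variants$tumor_depth))
})

test_that("the simulated copy-number profile passes the segment filter, decoys fail", {
  segs <- simulate_cna_profile()
  expect_equal(nrow(filter_segments(segs)), 2L)
  with_decoys <- simulate_cna_profile(decoys = TRUE)
  expect_equal(nrow(with_decoys), 4L)
  kept <- filter_segments(with_decoys)
  expect_equal(nrow(kept), 2L)
  expect_setequal(kept$state, c("gain", "loss"))
})

test_that("somatic variants inside a simulated gain follow the multiplicity model", {
  cfg <- simulation_config(purity = 1, n_germline_het = 0, n_somatic = 400,
                           ccf_levels = 1, ccf_weights = 1, seed = 12)
  segs <- simulate_cna_profile()
  sim <- simulate_pair(cfg, segments = segs)
  ann <- overlap_cna(sim$variants, segs)
  in_gain <- which(!is.na(ann$cna_state) & ann$cna_state == "gain")
  expect_gt(length(in_gain), 0)
  truth_dup <- sim$truth$on_duplicated_allele[in_gain]
  vafs <- sim$variants$tumor_vaf[in_gain]
  nondup <- vafs[!truth_dup]
  # expected fraction 1/3 for the non-duplicated allele in a pure tumor
  if (length(nondup) >= 3) {
    se <- sqrt((1 / 3) * (2 / 3) / 47) / sqrt(length(nondup))
    expect_lt(abs(mean(nondup) - 1 / 3), 4 * se)
  }
  dup <- vafs[truth_dup]
  if (length(dup) >= 3 && length(nondup) >= 3) {
    expect_gt(mean(dup), mean(nondup))
  }
})

test_that("validation cohorts are Bernoulli draws at the requested prevalence", {
  all_wt <- simulate_validation_cohort(c(site = 0), 40, seed = 3)
  expect_true(all(all_wt$status == "wildtype"))
  all_mut <- simulate_validation_cohort(c(site = 1), 40, seed = 3)
  expect_true(all(all_mut$status == "mutated"))

  big <- simulate_validation_cohort(c(MYD88_T794C = 0.125), 2400, seed = 4)
  rec <- aggregate_cohort(big)
  freq <- arm_frequency(rec$n_mutated_validation, rec$n_validation,
                        digits = NULL)
  se <- 100 * sqrt(0.125 * 0.875 / 2400)
  expect_lt(abs(freq - 12.5), 2 * se)
  expect_error(simulate_validation_cohort(c(0.5), 10), "named")
})

test_that("subclonal variants are recovered less often than clonal ones", {
  cfg <- simulation_config(n_germline_het = 0, n_somatic = 2000, seed = 14)
  sim <- simulate_pair(cfg)
  res <- run_cascade(sim$variants)
  recovered <- variant_key(sim$truth) %in% variant_key(res$somatic)
  rate <- tapply(recovered, sim$truth$ccf, mean)
  expect_lt(rate[["0.25"]], rate[["1"]])
  expect_lt(rate[["0.25"]], rate[["0.5"]])
})
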