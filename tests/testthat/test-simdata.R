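# Gene-dropping cohort generator: planted-haplotype structure,
# frequency calibration, determinism, noise injection.

test_that("config validation enforces the stated invariants", {
  expect_error(simulation_config(carrier_hap_freq = 1.5), "proportions")
  expect_error(simulation_config(n_cases = 0), "n_cases")
  expect_error(simulation_config(causal_pos = 1), "disease_hap_span")
  expect_error(simulation_config(causal_chrom = "99"), "causal_chrom")
})

test_that("every case is homozygous for the planted haplotype", {
  cfg <- small_sim_config(seed = 1, genotyping_error_rate = 0,
                          missing_rate = 0)
  cohort <- simulate_population(cfg)
  tr <- cohort$truth
  idx <- match(tr$span_markers, colnames(cohort$haps))
  for (id in tr$cases) {
    rows <- which(hap_individuals(cohort$haps) == id)
    for (r in rows)
      expect_equal(unname(cohort$haps[r, idx]), tr$founder_hap)
  }
  # affected <=> homozygous, exactly: no control is homozygous
  st <- haplotype_status(cohort$haps, tr$span_markers, tr$founder_hap)
  hom <- names(st)[st == "homozygous"]
  expect_setequal(hom, tr$cases)
})

test_that("control haplotype frequency is calibrated to carrier_hap_freq", {
  cfg <- simulation_config(seed = 1, n_controls = 10000,
                           n_markers_per_chrom = 400, n_chromosomes = 1,
                           causal_chrom = "1", carrier_hap_freq = 0.004,
                           genotyping_error_rate = 0, missing_rate = 0,
                           n_panel_individuals = 0)
  cohort <- simulate_population(cfg)
  tr <- cohort$truth
  n_copies <- 2 * cfg$n_controls
  obs <- length(tr$carrier_hap_rows) / n_copies
  se <- sqrt(0.004 * 0.996 / n_copies)
  expect_lt(abs(obs - 0.004), 3 * se)
  # and the measured frequency from the data agrees
  stats <- haplotype_carrier_stats(cohort$haps, tr$span_markers,
                                   tr$founder_hap, cohort$phenotypes)
  expect_equal(stats$carrier_copies, length(tr$carrier_hap_rows))
  expect_equal(stats$n_hom, 0)
})

test_that("identical seeds give identical cohorts; different seeds differ", {
  a <- simulate_population(small_sim_config(seed = 9))
  b <- simulate_population(small_sim_config(seed = 9))
  expect_identical(a$haps, b$haps)
  expect_identical(a$map, b$map)
  expect_identical(a$truth, b$truth)
  d <- simulate_population(small_sim_config(seed = 10))
  expect_false(identical(a$haps, d$haps))
})

test_that("phased truth reconstructs genotypes when noise is zero", {
  cohort <- simulate_population(small_sim_config(
    seed = 3, genotyping_error_rate = 0, missing_rate = 0))
  g <- haps_to_genotypes(cohort$haps)
  expect_false(anyNA(g))
  h1 <- cohort$haps[seq(1, nrow(cohort$haps), 2), ]
  h2 <- cohort$haps[seq(2, nrow(cohort$haps), 2), ]
  expect_true(all(g == h1 + h2))
})

test_that("noise injection produces the configured rates", {
  cfg <- small_sim_config(seed = 5, genotyping_error_rate = 0,
                          missing_rate = 0.02)
  cohort <- simulate_population(cfg)
  miss <- mean(is.na(haps_to_genotypes(cohort$haps)))
  expect_lt(abs(miss - 0.02), 0.005)
})

test_that("edge cases: zero carriers warn, sparse maps error", {
  expect_warning(simulate_population(small_sim_config(
    seed = 2, carrier_hap_freq = 0)), "zero control carriers")
  expect_error(
    simulate_population(simulation_config(
      seed = 1, n_markers_per_chrom = 10, marker_spacing_bp = 1000,
      n_chromosomes = 5)),
    "no markers")
})

test_that("sequence cohort carries the causal variant with exact genotypes", {
  cfg <- small_sim_config(seed = 4)
  cohort <- simulate_population(cfg)
  calls <- simulate_sequence_cohort(cfg, cohort$truth)
  roles <- calls$roles
  v <- calls$variants
  causal <- which(v$id == "rs_causal_del")
  expect_length(causal, 1L)
  expect_equal(unname(calls$geno[causal, "DW_hom"]), 2L)
  expect_equal(unname(calls$geno[causal, "DW_het"]), 1L)
  ctrl <- roles$sample[roles$role == "control"]
  expect_true(all(calls$geno[causal, ctrl] == 0L))
  # recessive filter retains the causal deletion by construction
  cand <- recessive_compatibility_filter(calls, "DW_hom", "DW_het", ctrl)
  expect_true(cand$compatible[causal])
})

test_that("compatible decoys and panel flags mirror the ten-variant design", {
  cfg <- small_sim_config(seed = 6, n_background_variants = 9,
                          panel_polymorphic_fraction = 8 / 9)
  cohort <- simulate_population(cfg)
  calls <- simulate_sequence_cohort(cfg, cohort$truth)
  parts <- split_panel(calls)
  roles <- calls$roles
  cand <- recessive_compatibility_filter(
    parts$study, "DW_hom", "DW_het",
    roles$sample[roles$role == "control"])
  expect_equal(sum(cand$compatible), 10L)  # causal + 9 decoys
  ex <- cross_population_exclusion(cand, parts$panel)
  expect_equal(nrow(ex$retained), 2L)      # post-exclusion count, Table-1 style
  expect_equal(nrow(ex$excluded), 8L)
  expect_true("rs_causal_del" %in% ex$retained$id)
})

test_that("zero background variants leave only the causal candidate", {
  cfg <- small_sim_config(seed = 7, n_background_variants = 0,
                          n_incompatible_variants = 10)
  cohort <- simulate_population(cfg)
  calls <- simulate_sequence_cohort(cfg, cohort$truth)
  roles <- calls$roles
  cand <- recessive_compatibility_filter(
    calls, "DW_hom", "DW_het", roles$sample[roles$role == "control"])
  expect_equal(cand$id[cand$compatible], "rs_causal_del")
})
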