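# Array QC: per-marker statistics and the filter cascade.

test_that("marker statistics use called genotypes only", {
  # 99 hom-ref, 1 het, 0 hom-alt, 2 missing of 102 individuals
  g <- matrix(c(rep(0L, 99), 1L, NA, NA), ncol = 1,
              dimnames = list(sprintf("i%03d", 1:102), "mk"))
  st <- compute_marker_stats(g, "mk")
  expect_equal(st$maf, 1 / 200)
  expect_equal(st$call_rate, 100 / 102)
  expect_equal(st$n_alt, 1L)
  expect_equal(st$n_missing, 2L)
  # all-missing marker: call rate 0, maf/hwe undefined
  g2 <- matrix(NA_integer_, nrow = 5, ncol = 1,
               dimnames = list(sprintf("i%d", 1:5), "mk"))
  st2 <- compute_marker_stats(g2, "mk")
  expect_equal(st2$call_rate, 0)
  expect_true(is.na(st2$maf) && is.na(st2$hwe_p))
  expect_error(compute_marker_stats(g, "nope"), "not found")
})

test_that("HWE column of marker stats matches the exact test", {
  g <- matrix(c(rep(0L, 25), rep(1L, 50), rep(2L, 25)), ncol = 1,
              dimnames = list(sprintf("i%03d", 1:100), "mk"))
  expect_equal(compute_marker_stats(g, "mk")$hwe_p, 1.0)
  g2 <- matrix(c(rep(0L, 5), rep(2L, 5)), ncol = 1,
               dimnames = list(sprintf("i%d", 1:10), "mk"))
  expect_equal(compute_marker_stats(g2, "mk")$hwe_p, hwe_oracle(5, 0, 5),
               tolerance = 1e-12)
})

test_that("apply_qc removes failing markers and individuals with reasons", {
  set.seed(30)
  n <- 150
  n_mark <- 40
  copies <- replicate(2 * n, paste0(rbinom(n_mark, 1, 0.4), collapse = ""))
  haps <- toy_haps(as.list(copies))
  map <- toy_map(n_mark)
  # marker 1: rare allele: maf = 1/300 <= 0.005
  haps[, 1] <- 0L; haps[3, 1] <- 1L
  # marker 2: poor call rate: missing in 20% of individuals (each loses
  # only 1/40 markers, so no individual falls below its own threshold)
  miss_rows <- seq(1, 60, 2)
  haps[miss_rows, 2] <- NA_integer_; haps[miss_rows + 1, 2] <- NA_integer_
  # marker 3: gross HWE violation: all het
  haps[, 3] <- rep(c(0L, 1L), n)
  phen <- toy_phenos(unique(hap_individuals(haps)),
                     rep("unaffected", n))
  qc <- apply_qc(haps, map, phen, qc_config())
  expect_false("m1" %in% colnames(qc$haps))
  expect_false("m2" %in% colnames(qc$haps))
  expect_false("m3" %in% colnames(qc$haps))
  rep_reason <- setNames(qc$report$reason, qc$report$entity)
  expect_equal(unname(rep_reason["m1"]), "MAF")
  expect_equal(unname(rep_reason["m2"]), "marker call rate")
  expect_equal(unname(rep_reason["m3"]), "HWE")
  expect_identical(qc$map$marker, colnames(qc$haps))
})

test_that("individuals are removed before marker stats are recomputed", {
  n <- 20
  copies <- replicate(2 * n, strrep("0", 10))
  haps <- toy_haps(as.list(copies))
  haps[, 2] <- rep(c(0L, 1L), n)  # het everywhere except in ind01
  haps[1:2, ] <- NA_integer_      # ind01 fully missing (call rate 0)
  haps[1:2, 2] <- 0L
  phen <- toy_phenos(unique(hap_individuals(haps)), rep("unaffected", n))
  qc <- apply_qc(haps, toy_map(10), phen,
                 qc_config(maf_min = 0, hwe_p_min = 0))
  expect_false("ind01" %in% hap_individuals(qc$haps))
  # with ind01 gone, no marker has missing calls: all call rates 1
  expect_true(all(qc$marker_stats$call_rate == 1))
})

test_that("QC is idempotent and clean simulated cohorts pass untouched", {
  cohort <- simulate_population(small_sim_config(
    seed = 12, genotyping_error_rate = 0, missing_rate = 0))
  qc1 <- apply_qc(cohort$haps, cohort$map, cohort$phenotypes)
  expect_equal(nrow(qc1$report), 0L)
  expect_equal(ncol(qc1$haps), ncol(cohort$haps))
  qc2 <- apply_qc(qc1$haps, qc1$map, cohort$phenotypes)
  expect_identical(qc2$haps, qc1$haps)
  expect_identical(qc2$map, qc1$map)
})

test_that("affected animals are excluded from HWE by default", {
  # 20 affected homozygous-alt + 80 controls in HWE: with cases included
  # the marker is far from HWE, excluded it is clean
  n_case <- 20; n_ctrl <- 80
  set.seed(40)
  ctrl_geno <- rbinom(n_ctrl, 2, 0.5)
  copies <- c(rep("1", 2 * n_case),
              as.vector(rbind(as.integer(ctrl_geno >= 1),
                              as.integer(ctrl_geno == 2))))
  haps <- toy_haps(as.list(as.character(copies)))
  ids <- unique(hap_individuals(haps))
  phen <- toy_phenos(ids, c(rep("affected", n_case),
                            rep("unaffected", n_ctrl)))
  st_excl <- compute_marker_stats(haps, "m1",
                                  hwe_exclude = ids[seq_len(n_case)])
  st_incl <- compute_marker_stats(haps, "m1")
  expect_gt(st_excl$hwe_p, st_incl$hwe_p)
})

test_that("thresholds are strict: a marker AT the boundary fails", {
  n <- 100
  haps <- toy_haps(as.list(replicate(2 * n, "0")))
  haps[seq_len(sum(2 * n * 0.005)) + 4, 1] <- 1L  # maf exactly 0.005
  phen <- toy_phenos(unique(hap_individuals(haps)), rep("unaffected", n))
  expect_error(apply_qc(haps, toy_map(1), phen, qc_config()),
               "QC removed everything")
})
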