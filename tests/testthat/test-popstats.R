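# LD, concordance cross-tabs and frequency trends.

test_that("ld_r2 matches hand arithmetic and handles degeneracy", {
  # perfectly coupled loci
  expect_equal(ld_r2(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  # all four haplotypes equally frequent
  expect_equal(ld_r2(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  # AB=4, ab=4, Ab=1, aB=1: D = 0.4 - 0.25, r2 = 0.0225/0.0625 = 0.36
  a <- c(rep(1, 4), rep(0, 4), 1, 0)
  b <- c(rep(1, 4), rep(0, 4), 0, 1)
  expect_equal(ld_r2(a, b), 0.36)
  # symmetric in loci and invariant under allele-label swap
  expect_equal(ld_r2(a, b), ld_r2(b, a))
  expect_equal(ld_r2(1 - a, b), ld_r2(a, b))
  expect_equal(ld_r2(a, 1 - b), ld_r2(a, b))
  # monomorphic -> NA with warning, never 0
  expect_warning(r <- ld_r2(c(1, 1, 1, 1), c(1, 0, 1, 0)), "monomorphic")
  expect_true(is.na(r))
  expect_error(ld_r2(c(1, 0), c(1)), "equal length")
})

test_that("published validation cross-tab yields exactly one discordance", {
  # genotype counts vs haplotype status for the coding deletion:
  # non-carrier: 3581 hom-ref; carrier: 1 hom-ref + 82 het;
  # homozygous: 27 hom-alt; unknown: 180 hom-ref + 11 het
  status <- c(rep("non-carrier", 3581), rep("carrier", 83),
              rep("homozygous", 27), rep("unknown", 191))
  geno <- c(rep(0L, 3581), 0L, rep(1L, 82), rep(2L, 27),
            rep(0L, 180), rep(1L, 11))
  ct <- genotype_haplotype_crosstab(geno, status)
  expect_equal(ct$n, 3882L)
  expect_equal(ct$discordant, 1L)
  expect_equal(unname(ct$table["carrier", "hom-ref"]), 1L)
  expect_equal(unname(ct$table["homozygous", "hom-alt"]), 27L)
  # the 2x2 allelic test over the unaffected animals of this cohort:
  # 93 deletion alleles among 3855 unaffected -> the published KASP P
  n_unaffected_alleles <- 2 * (3882 - 27)
  expect_equal(n_unaffected_alleles - 93, 7617)
  p <- fisher_allelic_test(54, 0, 93, 7617)
  expect_equal(signif(p$p, 3), 1.55e-98)
})

test_that("crosstab edge behaviour", {
  ct <- genotype_haplotype_crosstab(c(0L, 1L, 2L),
                                    c("non-carrier", "carrier",
                                      "homozygous"))
  expect_equal(ct$discordant, 0L)
  # unknown status and missing genotypes never count as discordant
  ct2 <- genotype_haplotype_crosstab(c(2L, NA), c("unknown", "carrier"))
  expect_equal(ct2$discordant, 0L)
  expect_error(genotype_haplotype_crosstab(0L, "weird"), "unknown")
})

test_that("frequency trend arithmetic and grouping", {
  # 1 het among 50 animals in one year -> 1%
  st <- c("carrier", rep("non-carrier", 49))
  tr <- frequency_trend(st, rep(2010L, 50))
  expect_equal(tr$frequency, 0.01)
  expect_equal(tr$n, 50L)
  # all non-carriers -> 0 in every year
  tr0 <- frequency_trend(rep("non-carrier", 30),
                         rep(2001:2003, each = 10))
  expect_true(all(tr0$frequency == 0))
  # homozygotes count two copies; unknowns drop out
  tr2 <- frequency_trend(c("homozygous", "carrier", "unknown",
                           "non-carrier"),
                         rep(2005L, 4))
  expect_equal(tr2$n, 3L)
  expect_equal(tr2$frequency, 3 / 6)
  # sex grouping keeps groups separate
  tr3 <- frequency_trend(c("carrier", "non-carrier", "carrier",
                           "non-carrier"),
                         rep(2005L, 4), sex = c("m", "m", "f", "f"))
  expect_equal(nrow(tr3), 2L)
  expect_true(all(tr3$frequency == 0.25))
  expect_warning(frequency_trend(rep("unknown", 3), rep(2000L, 3)),
                 "empty trend")
})

test_that("a configured frequency jump shows up in the trend", {
  set.seed(90)
  n <- 4000
  yr <- sample(2000:2009, n, replace = TRUE)
  p <- ifelse(yr >= 2005, 0.05, 0.005)
  st <- ifelse(runif(n) < 2 * p, "carrier", "non-carrier")
  tr <- frequency_trend(st, yr)
  early <- mean(tr$frequency[tr$birth_year < 2005])
  late <- mean(tr$frequency[tr$birth_year >= 2005])
  expect_gt(late, 4 * early)
})

test_that("synthetic truth: zero error gives concordance and r2 = 1", {
  cfg <- small_sim_config(seed = 17, genotyping_error_rate = 0,
                          missing_rate = 0)
  cohort <- simulate_population(cfg)
  tr <- cohort$truth
  hstat <- haplotype_status(cohort$haps, tr$span_markers, tr$founder_hap)
  vgeno <- genotype_validation_cohort(cohort)
  ids <- names(hstat)
  ct <- genotype_haplotype_crosstab(vgeno[ids], hstat[ids])
  expect_equal(ct$discordant, 0L)
  # per-copy LD between planted haplotype and causal allele is exactly 1
  idx <- match(tr$span_markers, colnames(cohort$haps))
  eq <- cohort$haps[, idx] == rep(tr$founder_hap,
                                  each = nrow(cohort$haps))
  hap_copy <- as.integer(rowSums(eq) == length(idx))
  var_copy <- hap_copy  # error-free direct gene test tracks the haplotype
  expect_equal(ld_r2(hap_copy, var_copy), 1)
  # with genotyping error the observed r2 drops below 1 but stays high
  cfg_e <- small_sim_config(seed = 17, genotyping_error_rate = 0.01,
                            missing_rate = 0)
  cohort_e <- simulate_population(cfg_e)
  eq_e <- cohort_e$haps[, idx] == rep(tr$founder_hap,
                                      each = nrow(cohort_e$haps))
  hap_copy_e <- as.integer(rowSums(eq_e) == length(idx))
  r2_e <- ld_r2(hap_copy_e, hap_copy)
  expect_lt(r2_e, 1)
  expect_gt(r2_e, 0.5)
})
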