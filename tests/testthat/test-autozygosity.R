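# ROH detection against an exhaustive oracle, shared-segment
# intersection, and carrier statistics.

roh_from_geno <- function(g, cfg) {
  geno <- matrix(g, nrow = 1, dimnames = list("x", sprintf(
    "m%d", seq_along(g))))
  detect_roh(geno, toy_map(length(g)), "x", cfg)
}

test_that("textbook genotype strings give the expected runs", {
  # AA AA AA AB AA with max_het = 0: markers 1-3 only
  g <- c(0L, 0L, 0L, 1L, 0L)
  r0 <- roh_from_geno(g, roh_config(min_markers = 3, max_het = 0,
                                    max_missing = 0))
  expect_equal(r0$start_idx, 1L)
  expect_equal(r0$end_idx, 3L)
  # with max_het = 1 the whole string is one run
  r1 <- roh_from_geno(g, roh_config(min_markers = 3, max_het = 1,
                                    max_missing = 0))
  expect_equal(nrow(r1), 1L)
  expect_equal(c(r1$start_idx, r1$end_idx), c(1L, 5L))
  # bp bounds are the first/last marker positions
  expect_equal(r1$start, 1000)
  expect_equal(r1$end, 5000)
  expect_error(detect_roh(matrix(0L, 1, 2,
                                 dimnames = list("a", c("m1", "m2"))),
                          toy_map(2), "zz"), "absent")
})

test_that("detection equals the exhaustive subinterval oracle", {
  set.seed(60)
  for (i in 1:25) {
    g <- sample(c(0L, 1L, 2L, NA), 60, replace = TRUE,
                prob = c(0.45, 0.2, 0.3, 0.05))
    max_het <- sample(0:2, 1); max_miss <- sample(0:2, 1)
    min_mark <- sample(c(1, 3, 5), 1)
    cfg <- roh_config(min_markers = min_mark, max_het = max_het,
                      max_missing = max_miss)
    got <- roh_from_geno(g, cfg)
    want <- roh_oracle(g, max_het, max_miss, min_mark)
    expect_equal(got$start_idx, want$start, label = paste("case", i))
    expect_equal(got$end_idx, want$end, label = paste("case", i))
  }
})

test_that("reported runs are maximal and anti-monotone in max_het", {
  set.seed(61)
  g <- sample(c(0L, 1L, 2L), 80, replace = TRUE, prob = c(0.5, 0.15, 0.35))
  for (mh in 0:2) {
    cfg <- roh_config(min_markers = 1, max_het = mh, max_missing = 0)
    r <- roh_from_geno(g, cfg)
    het <- g == 1L
    for (k in seq_len(nrow(r))) {
      s <- r$start_idx[k]; e <- r$end_idx[k]
      expect_lte(sum(het[s:e]), mh)
      if (s > 1) expect_gt(sum(het[(s - 1):e]), mh)
      if (e < length(g)) expect_gt(sum(het[s:(e + 1)]), mh)
    }
  }
  # decreasing max_het never lengthens any segment
  r2 <- roh_from_geno(g, roh_config(1, 2, 0))
  r1 <- roh_from_geno(g, roh_config(1, 1, 0))
  if (nrow(r1) > 0 && nrow(r2) > 0)
    expect_lte(max(r1$n_markers), max(r2$n_markers))
})

test_that("shared segment is the intersection of case ROH", {
  roh_a <- data.frame(individual = "a", chrom = "3", start = 10, end = 100,
                      start_idx = 1, end_idx = 5, n_markers = 5,
                      n_het = 0, n_missing = 0)
  roh_b <- roh_a; roh_b$individual <- "b"
  roh_b$start <- 50; roh_b$end <- 200
  sh <- shared_case_segment(list(a = roh_a, b = roh_b))
  expect_equal(c(sh$start, sh$end), c(50, 100))
  expect_false(sh$empty)
  # a case with no ROH in the hint region -> explicitly empty
  sh2 <- shared_case_segment(list(a = roh_a, b = roh_b),
                             region_hint = list(chrom = "3", start = 300,
                                                end = 400))
  expect_true(sh2$empty)
  # shared segment is contained in every case's covering ROH
  expect_true(sh$start >= roh_a$start && sh$end <= roh_a$end)
  expect_true(sh$start >= roh_b$start && sh$end <= roh_b$end)
})

test_that("simulated cases share a segment containing the causal site", {
  cfg <- small_sim_config(seed = 15)
  cohort <- simulate_population(cfg)
  geno <- haps_to_genotypes(cohort$haps)
  rohs <- lapply(cohort$truth$cases, function(id)
    detect_roh(geno, cohort$map, id))
  names(rohs) <- cohort$truth$cases
  sh <- shared_case_segment(rohs, list(chrom = "1", start = 0, end = Inf))
  expect_false(sh$empty)
  expect_lte(sh$start, cfg$causal_pos)
  expect_gte(sh$end, cfg$causal_pos)
})

test_that("carrier statistics reproduce the published arithmetic", {
  # 81 heterozygous carriers, 0 homozygous among 10,454 controls:
  # haplotype frequency 81/20908
  n <- 10454
  copies <- rep("000", 2 * n)
  copies[seq_len(81) * 2] <- "111"
  haps <- toy_haps(as.list(copies))
  phen <- toy_phenos(unique(hap_individuals(haps)), rep("unaffected", n))
  st <- haplotype_carrier_stats(haps, c("m1", "m2", "m3"), c(1L, 1L, 1L),
                                phen)
  expect_equal(st$n_het, 81L)
  expect_equal(st$n_hom, 0L)
  expect_equal(st$frequency, 81 / 20908)
  expect_equal(signif(100 * st$frequency, 2), 0.39)  # full precision kept

  # all homozygous carriers -> frequency 1
  haps2 <- toy_haps(as.list(rep("101", 6)))
  phen2 <- toy_phenos(unique(hap_individuals(haps2)),
                      rep("unaffected", 3))
  st2 <- haplotype_carrier_stats(haps2, c("m1", "m2", "m3"),
                                 c(1L, 0L, 1L), phen2)
  expect_equal(st2$n_hom, 3L)
  expect_equal(st2$frequency, 1)

  # absent haplotype -> zero counts
  st3 <- haplotype_carrier_stats(haps2, c("m1", "m2", "m3"),
                                 c(0L, 1L, 0L), phen2)
  expect_equal(st3$carrier_copies, 0L)
})
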