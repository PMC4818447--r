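# Recessive-compatibility filtering, cross-population exclusion and
# region classification.

toy_calls <- function(geno, pos = NULL) {
  n <- nrow(geno)
  v <- data.frame(chrom = "3", pos = pos %||% seq_len(n) * 100,
                  id = sprintf("v%d", seq_len(n)),
                  ref = "A", alt = "T", class = "SNV",
                  stringsAsFactors = FALSE)
  variant_calls(v, geno)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("three-condition filter keeps exactly the compatible variant", {
  geno <- rbind(c(2L, 1L, 0L, 0L, 0L),   # compatible
                c(2L, 1L, 1L, 0L, 0L),   # het control
                c(1L, 1L, 0L, 0L, 0L))   # case not hom-alt
  colnames(geno) <- c("case1", "carrier1", "c1", "c2", "c3")
  cand <- recessive_compatibility_filter(toy_calls(geno), "case1",
                                         "carrier1", c("c1", "c2", "c3"))
  expect_equal(cand$id[cand$compatible], "v1")
  expect_false(cand$compatible[2])   # het in one control -> excluded
  expect_false(cand$compatible[3])
  expect_error(
    recessive_compatibility_filter(toy_calls(geno), "case1", "carrier1",
                                   character(0)),
    "empty")
  expect_error(
    recessive_compatibility_filter(toy_calls(geno), "nope", "carrier1",
                                   "c1"),
    "absent")
})

test_that("missing genotypes: strict fails, lenient ignores", {
  geno <- rbind(c(2L, 1L, NA, 0L))
  colnames(geno) <- c("case1", "carrier1", "c1", "c2")
  calls <- toy_calls(geno)
  strict <- recessive_compatibility_filter(calls, "case1", "carrier1",
                                           c("c1", "c2"))
  expect_false(strict$compatible)
  lenient <- recessive_compatibility_filter(calls, "case1", "carrier1",
                                            c("c1", "c2"),
                                            missing_mode = "lenient")
  expect_true(lenient$compatible)
})

test_that("filter is monotone in controls and invariant to sample order", {
  set.seed(70)
  geno <- matrix(rbinom(20 * 8, 2, 0.3), nrow = 20)
  geno[, 1] <- 2L; geno[, 2] <- 1L
  colnames(geno) <- c("case1", "carrier1", sprintf("c%d", 1:6))
  calls <- toy_calls(geno)
  small <- recessive_compatibility_filter(calls, "case1", "carrier1",
                                          c("c1", "c2"))
  big <- recessive_compatibility_filter(calls, "case1", "carrier1",
                                        sprintf("c%d", 1:6))
  expect_true(all(big$compatible <= small$compatible))
  shuffled <- recessive_compatibility_filter(
    calls, "case1", "carrier1", sample(sprintf("c%d", 1:6)))
  expect_identical(big$compatible, shuffled$compatible)
})

test_that("panel exclusion over the ten published variants retains two", {
  t1 <- table1_variants()
  cand <- data.frame(chrom = t1$chrom, pos = t1$pos, id = t1$id,
                     ref = t1$ref, alt = t1$alt,
                     class = ifelse(t1$type == "SNP", "SNV", "indel"),
                     compatible = TRUE, stringsAsFactors = FALSE)
  # synthetic panel: the eight flagged variants segregate in at least one
  # of the panel animals, the two unflagged ones are monomorphic ref
  n_panel <- 40
  pgeno <- matrix(0L, nrow = nrow(t1), ncol = n_panel,
                  dimnames = list(NULL, sprintf("p%02d", seq_len(n_panel))))
  set.seed(71)
  for (i in which(t1$panel_flag))
    pgeno[i, sample(n_panel, 3)] <- 1L
  panel <- variant_calls(cand[, c("chrom", "pos", "id", "ref", "alt",
                                  "class")], pgeno)
  ex <- cross_population_exclusion(cand, panel)
  expect_equal(nrow(ex$retained), 2L)
  expect_equal(nrow(ex$excluded), 8L)
  expect_setequal(ex$retained$id, c("rs723240647", "rs715250609"))

  # empty panel: everything retained, flagged untested
  empty <- variant_calls(cand[0, c("chrom", "pos", "id", "ref", "alt",
                                   "class")],
                         matrix(integer(0), 0, 0))
  ex0 <- cross_population_exclusion(cand, empty)
  expect_equal(nrow(ex0$retained), 10L)
  expect_true(all(ex0$retained$panel_status == "untested"))

  # panel where every candidate segregates: zero retained
  pgeno1 <- pgeno; pgeno1[, 1] <- 1L
  ex1 <- cross_population_exclusion(
    cand, variant_calls(cand[, c("chrom", "pos", "id", "ref", "alt",
                                 "class")], pgeno1))
  expect_equal(nrow(ex1$retained), 0L)
  # adding panel samples can only shrink the retained set
  expect_lte(nrow(ex1$retained), nrow(ex$retained))
})

test_that("region classification partitions the contig", {
  fx <- make_gene_fixture()
  gene <- fx$gene
  # deep intronic decoy 4500 bp inside the long intron -> deprioritized
  li <- fx$info$spec$long_intron_index
  deep_pos <- gene$exons$end[li] + 4500
  deep <- classify_variant_region(
    list(chrom = "3", pos = deep_pos, ref = "A", alt = "T"), gene)
  expect_equal(deep$region, "intronic")
  expect_equal(deep$splice_distance, 4500)
  expect_equal(deep$priority, "deprioritized")
  # exon first base -> exonic, no splice distance
  ex1 <- classify_variant_region(
    list(chrom = "3", pos = gene$exons$start[2], ref = "A", alt = "T"),
    gene)
  expect_equal(ex1$region, "exonic")
  expect_true(is.na(ex1$splice_distance))
  # 1 bp inside an intron -> intronic, distance 1, kept
  in1 <- classify_variant_region(
    list(chrom = "3", pos = gene$exons$end[2] + 1, ref = "A", alt = "T"),
    gene)
  expect_equal(in1$region, "intronic")
  expect_equal(in1$splice_distance, 1)
  expect_equal(in1$priority, "candidate")
  # outside the gene -> intergenic; threshold is configurable
  ig <- classify_variant_region(
    list(chrom = "3", pos = min(gene$exons$start) - 10, ref = "A",
         alt = "T"), gene)
  expect_equal(ig$region, "intergenic")
  tight <- classify_variant_region(
    list(chrom = "3", pos = gene$exons$end[2] + 150, ref = "A",
         alt = "T"), gene, splice_distance_max = 100)
  expect_equal(tight$priority, "deprioritized")
  # every position maps to exactly one region class
  set.seed(72)
  pos <- floor(runif(200, fx$genome$offset + 1,
                     fx$genome$offset + nchar(fx$genome$seq)))
  cls <- vapply(pos, function(p) classify_variant_region(
    list(chrom = "3", pos = p, ref = "A", alt = "T"), gene)$region,
    character(1))
  expect_true(all(cls %in% c("exonic", "intronic", "intergenic")))
  # malformed gene models are rejected
  expect_error(gene_model("g", "t", "3", "+",
                          data.frame(start = c(1, 5), end = c(10, 20))),
               "overlapping")
})
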