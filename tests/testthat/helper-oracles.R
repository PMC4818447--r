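# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately take different computational paths than the
# package code (direct factorial arithmetic, exhaustive enumeration,
# stats::fisher.test) so agreement is informative.

# Exact HWE test by direct enumeration with plain factorial arithmetic
# (valid for n <= 50: (2n)! stays inside double range).
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_bb + n_ab
  n_b <- 2 * n - n_a
  if (n_a == 0 || n_b == 0) return(1)
  hets <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  prob <- vapply(hets, function(h) {
    factorial(n) / (factorial((n_a - h) / 2) * factorial(h) *
                      factorial((n_b - h) / 2)) *
      2^h * factorial(n_a) * factorial(n_b) / factorial(2 * n)
  }, numeric(1))
  sum(prob[prob <= prob[match(n_ab, hets)] * (1 + 1e-7)])
}

# Exhaustive ROH oracle: enumerate every subinterval, keep valid ones,
# then discard intervals contained in a longer valid interval.
roh_oracle <- function(g, max_het, max_missing, min_markers) {
  n <- length(g)
  het <- !is.na(g) & g == 1L
  miss <- is.na(g)
  valid <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (sum(het[i:j]) <= max_het && sum(miss[i:j]) <= max_missing)
      valid[[length(valid) + 1L]] <- c(i, j)
  }
  if (length(valid) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  v <- do.call(rbind, valid)
  maximal <- vapply(seq_len(nrow(v)), function(k) {
    !any(v[, 1L] <= v[k, 1L] & v[, 2L] >= v[k, 2L] &
           (v[, 1L] < v[k, 1L] | v[, 2L] > v[k, 2L]))
  }, logical(1))
  v <- v[maximal & (v[, 2L] - v[, 1L] + 1L) >= min_markers, ,
         drop = FALSE]
  v <- v[order(v[, 1L]), , drop = FALSE]
  data.frame(start = v[, 1L], end = v[, 2L])
}

# tiny phased haplotype matrix from per-individual allele strings
# (list of c(hap1, hap2) character strings over markers "m1"..)
toy_haps <- function(copies, ids = NULL) {
  n <- length(copies)
  stopifnot(n %% 2L == 0L)
  if (is.null(ids)) ids <- sprintf("ind%02d", seq_len(n / 2L))
  h <- do.call(rbind, lapply(copies, function(s)
    suppressWarnings(as.integer(strsplit(s, "")[[1L]]))))
  rownames(h) <- paste0(rep(ids, each = 2L), "|", rep(1:2, n / 2L))
  colnames(h) <- sprintf("m%d", seq_len(ncol(h)))
  attr(h, "individuals") <- rep(ids, each = 2L)
  h
}

toy_map <- function(n, chrom = "1", spacing = 1000) {
  data.frame(marker = sprintf("m%d", seq_len(n)), chrom = chrom,
             pos = seq_len(n) * spacing, ref = "A", alt = "B",
             stringsAsFactors = FALSE)
}

toy_phenos <- function(ids, status) {
  data.frame(id = ids, status = status, role = "control",
             breed = "test", sex = "female", birth_year = 2010,
             stringsAsFactors = FALSE)
}

# small fast simulation world used across tests
small_sim_config <- function(seed = 1L, ...) {
  simulation_config(seed = seed, n_controls = 400L,
                    n_markers_per_chrom = 400L, n_chromosomes = 1L,
                    causal_chrom = "1", n_panel_individuals = 100L,
                    n_seq_controls = 50L, ...)
}

# the ten published compatible variants (positions/ids as printed; the
# asterisk flags mark the eight that segregate in other breeds)
table1_variants <- function() {
  data.frame(
    chrom = "3",
    pos = c(15079217, 15713943, 15713959, 15737755, 15737992, 15738245,
            15815016, 15924914, 16046490, 16131785),
    id = c("rs723240647", "rs524337907", "rs719431247", "rs723848297",
           "ss1457237026", "rs720131431", "rs723370534", "rs717718209",
           "rs720952332", "rs715250609"),
    type = c("indel", "SNP", "SNP", "SNP", "indel", "indel", "SNP",
             "SNP", "SNP", "SNP"),
    ref = c("C", "G", "G", "C", "T", "C", "G", "G", "T", "T"),
    alt = c("-", "C", "A", "T", "-", "-", "A", "A", "C", "C"),
    gene = c("GON4L", NA, NA, NA, NA, NA, "KCNN3", "KCNN3", "ADAR",
             "TDRD10"),
    panel_flag = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                   TRUE, FALSE),
    stringsAsFactors = FALSE)
}
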