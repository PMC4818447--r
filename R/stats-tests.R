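#' Two-sided Fisher exact test of allelic association
#'
#' Computes the two-sided Fisher exact P value for a 2x2 table of allele
#' counts contrasting carrier/non-carrier allele copies in cases versus
#' controls.  All arithmetic is carried out on log factorials so that P
#' values far below the double-precision underflow limit of intermediate
#' hypergeometric terms (e.g. 1e-124) are computed accurately; the log10 P
#' is returned alongside so downstream ranking never touches a denormal.
#'
#' The two-sided P is the sum of hypergeometric point probabilities (over
#' the support of the table with fixed margins) that do not exceed the
#' probability of the observed table, the same convention used by
#' \code{stats::fisher.test}.  A table with a zero margin carries no
#' information and returns P = 1.
#'
#' @param case_carrier,case_noncarrier carrier / non-carrier allele counts
#'   among cases (for an allelic test, 2 x number of called case animals
#'   in total).
#' @param control_carrier,control_noncarrier the same counts among controls.
#' @return A list with elements \code{p} (double; may underflow to 0 for
#'   astronomically small values), \code{log10p} (always finite for a
#'   non-degenerate table) and \code{table} (the 2x2 input matrix).
#' @examples
#' fisher_allelic_test(54, 0, 81, 20827)$log10p  # about -123.66
#' @export
fisher_allelic_test <- function(case_carrier, case_noncarrier,
                                control_carrier, control_noncarrier) {
  a <- case_carrier; b <- case_noncarrier
  cc <- control_carrier; d <- control_noncarrier
  counts <- c(a, b, cc, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("all four counts must be non-negative integers")
  tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("case", "control"),
                                c("carrier", "noncarrier")))
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; n <- r1 + r2
  if (r1 == 0L || r2 == 0L || c1 == 0L || (n - c1) == 0L)
    return(list(p = 1, log10p = 0, table = tab))
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  log_obs <- logp[match(a, support)]
  # relative tolerance mirrors fisher.test()'s handling of ties
  keep <- logp <= log_obs + log(1 + 1e-7)
  log_p_two <- min(logsumexp(logp[keep]), 0)
  list(p = exp(log_p_two), log10p = log_p_two / log(10), table = tab)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on diploid genotype counts: conditional on the
#' observed allele counts, the probability of each possible heterozygote
#' count is computed and the P value is the sum of probabilities not
#' exceeding that of the observed configuration (two-sided, the standard
#' exact HWE test for array QC).
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return P value in (0, 1]; \code{NA} if no genotypes are supplied.
#' @examples
#' hwe_exact_test(25, 50, 25)  # modal table -> 1
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0L) return(NA_real_)
  n_a <- 2L * n_hom_alt + n_het  # minor-or-not is irrelevant: test is symmetric
  n_b <- 2L * n - n_a
  if (n_a == 0L || n_b == 0L) return(1)
  # heterozygote support shares the parity of the rarer allele count
  parity <- n_a %% 2L
  het_support <- seq.int(parity, min(n_a, n_b), by = 2L)
  log_const <- lfactorial(n) + lfactorial(n_a) + lfactorial(n_b) -
    lfactorial(2L * n)
  logp <- log_const + het_support * log(2) -
    lfactorial((n_a - het_support) %/% 2L) -
    lfactorial(het_support) -
    lfactorial((n_b - het_support) %/% 2L)
  log_obs <- logp[match(n_het, het_support)]
  if (is.na(log_obs)) stopf("inconsistent genotype counts")
  keep <- logp <= log_obs + log(1 + 1e-7)
  min(exp(logsumexp(logp[keep])), 1)
}

#' Expected number of homozygous-affected births under random mating
#'
#' Hardy-Weinberg expectation q^2 * N: with a deleterious allele at
#' frequency q and N births per year under random mating, q^2 N homozygous
#' (affected) calves are expected annually.
#'
#' @param q allele frequency in [0, 1].
#' @param n_births number of births.
#' @return Expected count (double).
#' @examples
#' expected_homozygous_births(0.002, 1500000)  # 6
#' @export
expected_homozygous_births <- function(q, n_births) {
  if (q < 0 || q > 1) stopf("q must be in [0, 1]")
  q^2 * n_births
}
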