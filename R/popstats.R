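# Population-genetic summaries supporting validation: LD r2 from phased
# haplotypes, genotype vs haplotype-status concordance cross-tabs, and
# carrier-frequency trends by birth year / sex.

#' LD r-squared between two loci from phased haplotypes
#'
#' r2 = D^2 / (pA (1-pA) pB (1-pB)) with D = pAB - pA pB, computed from
#' phased haplotype copies (pairs with a missing allele at either locus
#' are dropped).  A monomorphic locus makes r2 undefined: NA is returned
#' with a warning (never 0).
#'
#' @param alleles_a,alleles_b 0/1 allele vectors, one entry per haplotype
#'   copy, in the same copy order.
#' @return r2 in [0, 1], or NA for a monomorphic locus.
#' @examples
#' ld_r2(c(1,1,1,1,0,0,0,0,1,0), c(1,1,1,1,0,0,0,0,0,1))  # 0.36
#' @export
ld_r2 <- function(alleles_a, alleles_b) {
  if (length(alleles_a) != length(alleles_b))
    stopf("allele vectors must have equal length")
  ok <- !is.na(alleles_a) & !is.na(alleles_b)
  a <- alleles_a[ok]; b <- alleles_b[ok]
  if (length(a) < 2L) stopf("need at least 2 haplotype copies")
  p_a <- mean(a); p_b <- mean(b)
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    warnf("monomorphic locus: r2 undefined")
    return(NA_real_)
  }
  p_ab <- mean(a == 1L & b == 1L)
  d <- p_ab - p_a * p_b
  d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
}

#' Cross-tabulate variant genotypes against haplotype status
#'
#' Rows are haplotype statuses (non-carrier / carrier / homozygous /
#' unknown), columns genotype classes (hom-ref / het / hom-alt /
#' missing).  Concordant cells are (non-carrier, hom-ref), (carrier,
#' het), (homozygous, hom-alt); the discordance count is the number of
#' individuals with known haplotype status and called genotype outside
#' those cells.
#'
#' @param genotype integer dosage vector (0/1/2, NA missing), one entry
#'   per individual.
#' @param hap_status character vector with values in non-carrier /
#'   carrier / homozygous / unknown, aligned with \code{genotype}.
#' @return List of class \code{crosstab}: \code{table} (4 x 4 counts),
#'   \code{discordant} (count), \code{discordant_idx} (indices),
#'   \code{n}.
#' @export
genotype_haplotype_crosstab <- function(genotype, hap_status) {
  if (length(genotype) != length(hap_status))
    stopf("inputs must be aligned per individual")
  status_lv <- c("non-carrier", "carrier", "homozygous", "unknown")
  geno_lv <- c("hom-ref", "het", "hom-alt", "missing")
  bad <- setdiff(unique(hap_status), status_lv)
  if (length(bad) > 0L)
    stopf("unknown haplotype status: %s", paste(bad, collapse = ", "))
  gclass <- factor(ifelse(is.na(genotype), "missing",
                          geno_lv[genotype + 1L]), levels = geno_lv)
  sclass <- factor(hap_status, levels = status_lv)
  tab <- table(haplotype = sclass, genotype = gclass)
  expected <- c(`non-carrier` = "hom-ref", carrier = "het",
                homozygous = "hom-alt")
  disc <- sclass %in% names(expected) & !is.na(genotype) &
    gclass != expected[as.character(sclass)]
  structure(list(table = tab, discordant = sum(disc),
                 discordant_idx = which(disc), n = length(genotype)),
            class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  print(x$table)
  cat(sprintf("discordant individuals: %d of %d\n", x$discordant, x$n))
  invisible(x)
}

#' Carrier-haplotype frequency trend by group
#'
#' Per-group carrier haplotype frequency = carrier copies / (2 x group
#' size); heterozygous carriers contribute 1 copy, homozygotes 2.
#' Individuals with unknown status are excluded; empty groups are omitted
#' with a warning.
#'
#' @param hap_status vector (non-carrier / carrier / homozygous /
#'   unknown).
#' @param birth_year integer vector aligned with \code{hap_status}.
#' @param sex optional vector; when given, grouping is (year, sex).
#' @return data.frame of trend points: group columns, cohort size n,
#'   carrier_copies, frequency.
#' @export
frequency_trend <- function(hap_status, birth_year, sex = NULL) {
  known <- hap_status != "unknown" & !is.na(birth_year)
  if (!any(known)) {
    warnf("no individuals with known status: empty trend")
    return(data.frame(birth_year = integer(0), n = integer(0),
                      carrier_copies = integer(0), frequency = numeric(0)))
  }
  copies <- c(`non-carrier` = 0L, carrier = 1L, homozygous = 2L)
  cp <- copies[hap_status[known]]
  grp <- if (is.null(sex)) list(birth_year = birth_year[known]) else
    list(birth_year = birth_year[known], sex = sex[known])
  agg_n <- aggregate(cp, by = grp, FUN = length)
  agg_c <- aggregate(cp, by = grp, FUN = sum)
  out <- agg_n
  names(out)[names(out) == "x"] <- "n"
  out$carrier_copies <- agg_c$x
  out$frequency <- out$carrier_copies / (2 * out$n)
  out[order(out$birth_year), , drop = FALSE]
}

#' Derive per-individual haplotype status from phased haplotypes
#'
#' Counts copies of a segment allele string per individual and maps 0/1/2
#' copies to non-carrier/carrier/homozygous.  An individual with a
#' missing allele inside the segment on either copy cannot be typed
#' exactly and is labelled "unknown".
#'
#' @param haps phased haplotype matrix.
#' @param markers marker ids of the segment.
#' @param allele_string 0/1 vector defining the carrier haplotype.
#' @return Named character vector of statuses, one per individual.
#' @export
haplotype_status <- function(haps, markers, allele_string) {
  idx <- match(markers, colnames(haps))
  if (anyNA(idx)) stopf("segment markers absent from haplotype matrix")
  sub <- haps[, idx, drop = FALSE]
  eq <- sub == rep(allele_string, each = nrow(sub))
  rs <- rowSums(eq)
  match_hap <- ifelse(is.na(rs), NA, as.integer(rs == length(idx)))
  per_ind <- tapply(match_hap, hap_individuals(haps), sum)
  out <- ifelse(is.na(per_ind), "unknown",
                c("non-carrier", "carrier", "homozygous")[
                  pmin(as.integer(per_ind), 2L) + 1L])
  setNames(out, names(per_ind))
}
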