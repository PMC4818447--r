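# Array quality control: per-marker minor allele frequency, call rate and
# exact Hardy-Weinberg test; per-individual call rate.  Thresholds follow
# the common array-QC convention for recessive-defect mapping: MAF >
# 0.5%, HWE exact P > 1e-4, per-marker and per-individual call rates >
# 95% (all strict inequalities; a marker AT the threshold fails).

#' Array QC configuration
#'
#' @param maf_min minimum minor allele frequency (exclusive).
#' @param hwe_p_min minimum exact HWE P value (exclusive).
#' @param marker_call_rate_min,individual_call_rate_min minimum call
#'   rates (exclusive).
#' @param hwe_include_affected include affected animals in the HWE test?
#'   Default FALSE: a case set enriched for a recessive genotype violates
#'   HWE at the mapped locus by design, so cases are excluded from the
#'   HWE computation (but not from MAF/call-rate).
#' @return Object of class \code{qc_config}.
#' @export
qc_config <- function(maf_min = 0.005, hwe_p_min = 1e-4,
                      marker_call_rate_min = 0.95,
                      individual_call_rate_min = 0.95,
                      hwe_include_affected = FALSE) {
  vals <- c(maf_min, hwe_p_min, marker_call_rate_min,
            individual_call_rate_min)
  if (any(vals < 0 | vals > 1)) stopf("thresholds must lie in [0, 1]")
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                 marker_call_rate_min = marker_call_rate_min,
                 individual_call_rate_min = individual_call_rate_min,
                 hwe_include_affected = isTRUE(hwe_include_affected)),
            class = "qc_config")
}

marker_stats_matrix <- function(geno, hwe_exclude = character(0)) {
  n_ind <- nrow(geno)
  n_missing <- colSums(is.na(geno))
  n_called <- n_ind - n_missing
  alt_copies <- colSums(geno, na.rm = TRUE)
  ref_copies <- 2L * n_called - alt_copies
  p_alt <- ifelse(n_called > 0L, alt_copies / (2L * n_called), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  call_rate <- n_called / n_ind
  hwe_geno <- geno[!rownames(geno) %in% hwe_exclude, , drop = FALSE]
  hwe_p <- vapply(seq_len(ncol(geno)), function(j) {
    g <- hwe_geno[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0L) return(NA_real_)
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(1))
  data.frame(marker = colnames(geno),
             n_ref = ref_copies, n_alt = alt_copies,
             n_missing = n_missing, maf = maf, call_rate = call_rate,
             hwe_p = hwe_p, stringsAsFactors = FALSE)
}

#' Per-marker QC statistics
#'
#' MAF and allele counts are computed over called genotypes only; the HWE
#' P value is from the exact conditional test
#' (\code{\link{hwe_exact_test}}).  A marker with no called genotypes gets
#' call rate 0 and undefined (NA) MAF and HWE P.
#'
#' @param genotypes diploid dosage matrix (individuals x markers; see
#'   \code{\link{haps_to_genotypes}}) or a phased haplotype matrix.
#' @param marker marker identifier (column name).
#' @param hwe_exclude individual ids excluded from the HWE test (typically
#'   the affected animals).
#' @return One-row data.frame: marker, allele counts (ref/alt/missing),
#'   maf, call_rate, hwe_p.
#' @export
compute_marker_stats <- function(genotypes, marker,
                                 hwe_exclude = character(0)) {
  genotypes <- as_genotypes(genotypes)
  if (!marker %in% colnames(genotypes)) stopf("marker %s not found", marker)
  marker_stats_matrix(genotypes[, marker, drop = FALSE], hwe_exclude)
}

as_genotypes <- function(x) {
  if (!is.null(attr(x, "individuals"))) haps_to_genotypes(x) else x
}

#' Apply array QC filters
#'
#' Individuals below the individual call-rate threshold are removed first;
#' marker statistics are then recomputed on the surviving animals and
#' markers failing call rate, MAF or HWE are removed (in that reason
#' order).  All comparisons are strict: a marker passes only with
#' maf > maf_min, hwe_p > hwe_p_min and call rate > the threshold.
#'
#' @param haps phased haplotype matrix (2 rows per individual).
#' @param map marker map (filtered in step with the matrix).
#' @param phenotypes phenotype table (used to exclude affected animals
#'   from the HWE test unless \code{hwe_include_affected}).
#' @param config a \code{\link{qc_config}}.
#' @return List: \code{haps}, \code{map} (both filtered), \code{report}
#'   (one row per removed entity with reason, plus summary counts in
#'   attributes), \code{marker_stats} for the surviving markers.
#' @export
apply_qc <- function(haps, map, phenotypes = NULL,
                     config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  geno <- haps_to_genotypes(haps)
  report <- list()

  ind_call <- rowMeans(!is.na(geno))
  bad_ind <- rownames(geno)[ind_call <= config$individual_call_rate_min]
  if (length(bad_ind) > 0L) {
    report[[length(report) + 1L]] <- data.frame(
      entity_type = "individual", entity = bad_ind, statistic = "call_rate",
      value = ind_call[bad_ind], reason = "individual call rate",
      stringsAsFactors = FALSE)
    keep_rows <- !hap_row_ids(rownames(haps)) %in% bad_ind
    ind_keep <- attr(haps, "individuals")[keep_rows]
    haps <- haps[keep_rows, , drop = FALSE]
    attr(haps, "individuals") <- ind_keep
    geno <- haps_to_genotypes(haps)
  }

  hwe_exclude <- character(0)
  if (!config$hwe_include_affected && !is.null(phenotypes))
    hwe_exclude <- phenotypes$id[phenotypes$status == "affected"]
  st <- marker_stats_matrix(geno, hwe_exclude)

  fail_cr <- st$call_rate <= config$marker_call_rate_min
  fail_maf <- !fail_cr & (is.na(st$maf) | st$maf <= config$maf_min)
  fail_hwe <- !fail_cr & !fail_maf &
    (is.na(st$hwe_p) | st$hwe_p <= config$hwe_p_min)
  for (spec in list(list(fail_cr, "call_rate", "marker call rate"),
                    list(fail_maf, "maf", "MAF"),
                    list(fail_hwe, "hwe_p", "HWE"))) {
    bad <- spec[[1L]]
    if (any(bad))
      report[[length(report) + 1L]] <- data.frame(
        entity_type = "marker", entity = st$marker[bad],
        statistic = spec[[2L]], value = st[[spec[[2L]]]][bad],
        reason = spec[[3L]], stringsAsFactors = FALSE)
  }
  bad_mark <- fail_cr | fail_maf | fail_hwe
  ind_attr <- attr(haps, "individuals")
  haps <- haps[, !bad_mark, drop = FALSE]
  attr(haps, "individuals") <- ind_attr
  map <- map[match(colnames(haps), map$marker), , drop = FALSE]
  rownames(map) <- NULL
  if (ncol(haps) == 0L || nrow(haps) == 0L)
    stopf("QC removed everything: %d individuals and %d markers failed",
          length(bad_ind), sum(bad_mark))
  report <- if (length(report) > 0L) do.call(rbind, report) else
    data.frame(entity_type = character(0), entity = character(0),
               statistic = character(0), value = numeric(0),
               reason = character(0))
  rownames(report) <- NULL
  list(haps = haps, map = map, report = report,
       marker_stats = st[!bad_mark, , drop = FALSE])
}

#' Write a QC report as TSV
#' @param qc result of \code{\link{apply_qc}}.
#' @param path output path.
#' @export
write_qc_report <- function(qc, path) {
  write.table(qc$report, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
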