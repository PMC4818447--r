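# Sliding-window haplotype association scan: exact allele strings over
# windows of W contiguous markers (stepped by s, never crossing a
# chromosome boundary) are tested for case/control association with
# two-sided Fisher exact tests on haplotype-copy counts, and the 5%
# Bonferroni threshold is alpha / (total haplotypes tested across all
# windows).

#' Scan configuration
#'
#' @param window_size markers per window (default 25, about 1.4 Mb at
#'   typical 50k-array density).
#' @param step marker step between consecutive windows (default 2).
#' @param hap_freq_min haplotypes at population frequency <= this are not
#'   tested (default 0.005).
#' @param alpha family-wise significance level for the Bonferroni
#'   threshold (default 0.05).
#' @return Object of class \code{scan_config}.
#' @export
scan_config <- function(window_size = 25L, step = 2L,
                        hap_freq_min = 0.005, alpha = 0.05) {
  window_size <- as.integer(window_size); step <- as.integer(step)
  if (window_size < 1L) stopf("window_size must be >= 1")
  if (step < 1L || step > window_size)
    stopf("step must satisfy 1 <= step <= window_size")
  structure(list(window_size = window_size, step = step,
                 hap_freq_min = hap_freq_min, alpha = alpha),
            class = "scan_config")
}

#' Enumerate sliding windows over a marker map
#'
#' Windows never span chromosome boundaries; a chromosome with M >= W
#' markers yields floor((M - W)/s) + 1 windows and trailing markers not
#' covered by a full window are skipped.  Chromosomes with fewer than W
#' markers contribute no windows (with a warning).
#'
#' @param map marker map sorted by (chrom, pos).
#' @param config a \code{\link{scan_config}}.
#' @return data.frame: chrom, start_idx, end_idx (row indices into the
#'   map), start_bp, end_bp.
#' @export
enumerate_windows <- function(map, config = scan_config()) {
  w <- config$window_size; s <- config$step
  out <- list()
  for (ch in unique(map$chrom)) {
    rows <- which(map$chrom == ch)
    m <- length(rows)
    if (m < w) {
      warnf("chromosome %s has %d < %d markers: no windows", ch, m, w)
      next
    }
    starts <- seq.int(1L, m - w + 1L, by = s)
    out[[ch]] <- data.frame(
      chrom = ch,
      start_idx = rows[starts], end_idx = rows[starts + w - 1L],
      start_bp = map$pos[rows[starts]],
      end_bp = map$pos[rows[starts + w - 1L]],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start_idx = integer(0),
                      end_idx = integer(0), start_bp = numeric(0),
                      end_bp = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# integer key per haplotype copy over a marker-index window; copies with
# a missing allele get NA and are excluded from tabulation
window_hap_keys <- function(haps, idx) {
  sub <- haps[, idx, drop = FALSE]
  drop(sub %*% 2^(seq_along(idx) - 1L))
}

key_to_string <- function(key, w) {
  bits <- lapply(seq_len(w) - 1L, function(b)
    as.integer((key %/% 2^b) %% 2))
  do.call(paste0, bits)
}

#' Tabulate window haplotypes with case/control carrier counts
#'
#' Haplotype identity is the exact allele string over the window.
#' Population frequency is computed over all fully observed haplotype
#' copies of all individuals (cases, controls and unknowns); copies with
#' a missing allele inside the window are excluded.  Haplotypes at
#' frequency <= \code{hap_freq_min} are flagged untested.  The 2x2 test
#' counts use only case/control individuals.
#'
#' @param haps phased haplotype matrix.
#' @param window one row of \code{\link{enumerate_windows}}.
#' @param phenotypes phenotype table (status: affected / unaffected /
#'   unknown).
#' @param hap_freq_min frequency threshold (exclusive).
#' @return data.frame: haplotype string, count, freq, tested flag and the
#'   four 2x2 cells (case_carrier, case_noncarrier, control_carrier,
#'   control_noncarrier).
#' @export
tabulate_window_haplotypes <- function(haps, window, phenotypes,
                                       hap_freq_min = 0.005) {
  idx <- window$start_idx:window$end_idx
  keys <- window_hap_keys(haps, idx)
  ok <- !is.na(keys)
  status <- phenotypes$status[match(hap_individuals(haps),
                                    phenotypes$id)]
  status[is.na(status)] <- "unknown"
  keys_ok <- keys[ok]
  status_ok <- status[ok]
  key_vals <- sort(unique(keys_ok))
  m <- match(keys_ok, key_vals)
  count <- tabulate(m, length(key_vals))
  freq <- count / length(keys_ok)
  is_case <- status_ok == "affected"
  is_ctrl <- status_ok == "unaffected"
  n_case_copies <- sum(is_case)
  n_ctrl_copies <- sum(is_ctrl)
  case_carrier <- tabulate(m[is_case], length(key_vals))
  ctrl_carrier <- tabulate(m[is_ctrl], length(key_vals))
  tested <- freq > hap_freq_min
  # allele strings are built for tested haplotypes (and for small tables);
  # untested singletons in large tables keep NA to avoid pointless work
  hap_str <- rep(NA_character_, length(key_vals))
  want <- if (length(key_vals) <= 64L) seq_along(key_vals) else which(tested)
  if (length(want) > 0L)
    hap_str[want] <- key_to_string(key_vals[want], length(idx))
  data.frame(haplotype = hap_str,
             count = count, freq = freq,
             tested = tested,
             case_carrier = case_carrier,
             case_noncarrier = n_case_copies - case_carrier,
             control_carrier = ctrl_carrier,
             control_noncarrier = n_ctrl_copies - ctrl_carrier,
             stringsAsFactors = FALSE)
}

#' Genome-wide sliding-window haplotype association scan
#'
#' One Fisher exact allelic test per (window, retained haplotype); the
#' Bonferroni threshold is alpha divided by the total number of tested
#' haplotypes summed over all windows.  Results are sorted by P value
#' (ties broken by chromosome and window start) and flagged significant
#' by strict inequality P < threshold.
#'
#' @param haps phased, QC'd haplotype matrix.
#' @param map matching marker map.
#' @param phenotypes phenotype table.
#' @param config a \code{\link{scan_config}}.
#' @return List of class \code{hap_scan}: \code{results} (data.frame with
#'   window coordinates, haplotype, 2x2 counts, p, log10p, significant),
#'   \code{threshold}, \code{n_tests}, \code{config}.
#' @export
scan_genome <- function(haps, map, phenotypes, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  windows <- enumerate_windows(map, config)
  res <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    wtab <- tabulate_window_haplotypes(haps, windows[i, ], phenotypes,
                                       config$hap_freq_min)
    wtab <- wtab[wtab$tested, , drop = FALSE]
    if (nrow(wtab) == 0L) next
    p <- lapply(seq_len(nrow(wtab)), function(j)
      fisher_allelic_test(wtab$case_carrier[j], wtab$case_noncarrier[j],
                          wtab$control_carrier[j],
                          wtab$control_noncarrier[j]))
    res[[i]] <- data.frame(
      chrom = windows$chrom[i],
      window_start_bp = windows$start_bp[i],
      window_end_bp = windows$end_bp[i],
      haplotype = wtab$haplotype, freq = wtab$freq,
      case_carrier = wtab$case_carrier,
      case_noncarrier = wtab$case_noncarrier,
      control_carrier = wtab$control_carrier,
      control_noncarrier = wtab$control_noncarrier,
      p = vapply(p, `[[`, numeric(1), "p"),
      log10p = vapply(p, `[[`, numeric(1), "log10p"),
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)
  if (is.null(results) || nrow(results) == 0L)
    stopf("no haplotype exceeded the frequency threshold: nothing tested")
  n_tests <- nrow(results)
  threshold <- config$alpha / n_tests
  results$significant <- results$p < threshold
  ord <- order(results$log10p, results$chrom, results$window_start_bp)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  structure(list(results = results, threshold = threshold,
                 n_tests = n_tests, config = config),
            class = "hap_scan")
}

#' @export
print.hap_scan <- function(x, ...) {
  cat(sprintf(
    "hap_scan: %d haplotype tests, Bonferroni threshold %.3g, %d significant\n",
    x$n_tests, x$threshold, sum(x$results$significant)))
  top <- x$results[1L, ]
  cat(sprintf("  top: chr%s %.0f-%.0f log10(P) = %.2f\n", top$chrom,
              top$window_start_bp, top$window_end_bp, top$log10p))
  invisible(x)
}

#' Write scan results as TSV and significant windows as BED
#' @param scan a \code{hap_scan}.
#' @param tsv_path,bed_path output paths (either may be NULL).
#' @export
write_scan_results <- function(scan, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path))
    write.table(scan$results, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(bed_path)) {
    sig <- scan$results[scan$results$significant, , drop = FALSE]
    write_bed(data.frame(chrom = sig$chrom, start = sig$window_start_bp,
                         end = sig$window_end_bp, name = sig$haplotype),
              bed_path)
  }
  invisible(scan)
}
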