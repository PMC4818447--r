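# Autozygosity mapping: detect runs of homozygosity (ROH) per animal from
# (possibly unphased) genotypes, then intersect the case ROHs to delimit
# the segment of extended homozygosity shared by all affected animals.
# ROH detection is genotype-based (AA/BB vs AB), matching how
# autozygosity is displayed and interpreted on array data.

#' ROH detection configuration
#'
#' The defaults (20 markers, at most 1 heterozygous and 2 missing calls
#' per run) recover a ~1.8-Mb autozygous segment at typical 50k-array
#' density; all three are exposed because no standard exists.
#'
#' @param min_markers minimum markers per reported run.
#' @param max_het maximum heterozygous calls tolerated inside a run.
#' @param max_missing maximum missing calls tolerated inside a run.
#' @return Object of class \code{roh_config}.
#' @export
roh_config <- function(min_markers = 20L, max_het = 1L, max_missing = 2L) {
  min_markers <- as.integer(min_markers)
  max_het <- as.integer(max_het); max_missing <- as.integer(max_missing)
  if (min_markers < 1L) stopf("min_markers must be >= 1")
  if (max_het < 0L || max_missing < 0L)
    stopf("max_het and max_missing must be >= 0")
  structure(list(min_markers = min_markers, max_het = max_het,
                 max_missing = max_missing), class = "roh_config")
}

# maximal valid runs in a het/missing indicator pair; two-pointer O(n).
# A run [i, j] is valid iff it contains <= max_het heterozygous and
# <= max_missing missing calls; validity is closed under taking
# subintervals, so maximal runs are [i, R(i)] with R non-decreasing and a
# run is maximal iff R(i-1) < R(i).  When max_het > 0 maximal runs can
# share flanking markers (they are reported sorted, possibly overlapping).
maximal_runs <- function(het, miss, max_het, max_missing) {
  n <- length(het)
  out_s <- integer(0); out_e <- integer(0)
  j <- 0L; n_het <- 0L; n_miss <- 0L
  prev_r <- 0L
  for (i in seq_len(n)) {
    if (j < i) { j <- i - 1L; n_het <- 0L; n_miss <- 0L }
    while (j < n &&
           n_het + (het[j + 1L]) <= max_het &&
           n_miss + (miss[j + 1L]) <= max_missing) {
      j <- j + 1L
      n_het <- n_het + het[j]
      n_miss <- n_miss + miss[j]
    }
    if (j >= i && j > prev_r) {
      out_s <- c(out_s, i); out_e <- c(out_e, j)
      prev_r <- j
    }
    # slide left edge out of the window
    if (j >= i) {
      n_het <- n_het - het[i]
      n_miss <- n_miss - miss[i]
    }
  }
  list(start = out_s, end = out_e)
}

#' Detect runs of homozygosity for one individual
#'
#' Reports, per chromosome, every maximal run of consecutive markers with
#' at most \code{max_het} heterozygous and \code{max_missing} missing
#' calls and at least \code{min_markers} markers.  Runs are maximal:
#' extending either end by one marker violates a constraint.  Segment bp
#' bounds are the first and last marker positions of the run.
#'
#' @param genotypes dosage matrix (individuals x markers) or phased
#'   haplotype matrix.
#' @param map marker map matching the columns.
#' @param individual individual id (row name).
#' @param config a \code{\link{roh_config}}.
#' @return data.frame of class segments: individual, chrom, start, end
#'   (bp), start_idx/end_idx (map rows), n_markers, n_het, n_missing.
#' @export
detect_roh <- function(genotypes, map, individual,
                       config = roh_config()) {
  stopifnot(inherits(config, "roh_config"))
  geno <- as_genotypes(genotypes)
  if (!individual %in% rownames(geno))
    stopf("individual %s absent from genotype matrix", individual)
  g <- geno[individual, ]
  out <- list()
  for (ch in unique(map$chrom)) {
    rows <- which(map$chrom == ch)
    gc <- g[rows]
    het <- as.integer(!is.na(gc) & gc == 1L)
    miss <- as.integer(is.na(gc))
    runs <- maximal_runs(het, miss, config$max_het, config$max_missing)
    len <- runs$end - runs$start + 1L
    keep <- len >= config$min_markers
    if (!any(keep)) next
    s <- runs$start[keep]; e <- runs$end[keep]
    out[[ch]] <- data.frame(
      individual = individual, chrom = ch,
      start = map$pos[rows[s]], end = map$pos[rows[e]],
      start_idx = rows[s], end_idx = rows[e],
      n_markers = e - s + 1L,
      n_het = vapply(seq_along(s), function(k)
        sum(het[s[k]:e[k]]), integer(1)),
      n_missing = vapply(seq_along(s), function(k)
        sum(miss[s[k]:e[k]]), integer(1)),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(individual = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      start_idx = integer(0), end_idx = integer(0),
                      n_markers = integer(0), n_het = integer(0),
                      n_missing = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Shared autozygous segment across all cases
#'
#' Returns the maximal genomic interval(s) contained in at least one ROH
#' of every case (interval intersection of the per-case ROH unions),
#' optionally restricted to a hint region.  An empty intersection is a
#' valid outcome and is reported explicitly.
#'
#' @param roh_by_case named list (one element per case) of ROH
#'   data.frames from \code{\link{detect_roh}}.
#' @param region_hint optional list(chrom, start, end) restriction.
#' @return List of class \code{shared_segment}: \code{chrom},
#'   \code{start}, \code{end} of the longest shared interval (NA when
#'   empty), \code{intervals} (all shared intervals), \code{empty} flag,
#'   \code{n_cases}.
#' @export
shared_case_segment <- function(roh_by_case, region_hint = NULL) {
  if (length(roh_by_case) < 1L) stopf("need at least one case with ROH")
  per_case <- lapply(roh_by_case, function(df) {
    if (!is.null(region_hint)) {
      df <- df[df$chrom == region_hint$chrom &
               df$end >= region_hint$start &
               df$start <= region_hint$end, , drop = FALSE]
      df$start <- pmax(df$start, region_hint$start)
      df$end <- pmin(df$end, region_hint$end)
    }
    df
  })
  chroms <- unique(unlist(lapply(per_case, function(df) df$chrom)))
  intervals <- list()
  for (ch in chroms) {
    cur <- NULL
    ok <- TRUE
    for (df in per_case) {
      r <- df[df$chrom == ch, , drop = FALSE]
      if (nrow(r) == 0L) { ok <- FALSE; break }
      ir <- IRanges::reduce(IRanges::IRanges(r$start, r$end))
      cur <- if (is.null(cur)) ir else IRanges::intersect(cur, ir)
      if (length(cur) == 0L) { ok <- FALSE; break }
    }
    if (ok && length(cur) > 0L)
      intervals[[ch]] <- data.frame(
        chrom = ch, start = IRanges::start(cur),
        end = IRanges::end(cur), stringsAsFactors = FALSE)
  }
  if (length(intervals) == 0L)
    return(structure(list(chrom = NA_character_, start = NA_real_,
                          end = NA_real_,
                          intervals = data.frame(chrom = character(0),
                                                 start = numeric(0),
                                                 end = numeric(0)),
                          empty = TRUE, n_cases = length(roh_by_case)),
                     class = "shared_segment"))
  iv <- do.call(rbind, intervals)
  rownames(iv) <- NULL
  best <- which.max(iv$end - iv$start)
  structure(list(chrom = iv$chrom[best], start = iv$start[best],
                 end = iv$end[best], intervals = iv, empty = FALSE,
                 n_cases = length(roh_by_case)),
            class = "shared_segment")
}

#' @export
print.shared_segment <- function(x, ...) {
  if (x$empty) cat("shared_segment: empty intersection\n")
  else cat(sprintf("shared_segment: %s:%.0f-%.0f (%.2f Mb, %d cases)\n",
                   x$chrom, x$start, x$end, (x$end - x$start) / 1e6,
                   x$n_cases))
  invisible(x)
}

#' Carrier statistics for a segment haplotype
#'
#' Counts, in a chosen cohort, the individuals carrying 0, 1 or 2 copies
#' of a given allele string over a set of markers, and the resulting
#' haplotype frequency (carrier copies / total copies).  A haplotype copy
#' with a missing allele inside the segment is counted as non-carrier.
#'
#' @param haps phased haplotype matrix.
#' @param markers marker ids defining the segment.
#' @param allele_string integer vector (0/1) of the carrier haplotype.
#' @param phenotypes phenotype table.
#' @param statuses which phenotype statuses form the cohort (default
#'   controls only).
#' @return List: n_het, n_hom, n_noncarrier, n_individuals, carrier
#'   copies and \code{frequency} (full precision; rounding is left to the
#'   report layer).
#' @export
haplotype_carrier_stats <- function(haps, markers, allele_string,
                                    phenotypes,
                                    statuses = "unaffected") {
  idx <- match(markers, colnames(haps))
  if (anyNA(idx)) stopf("segment markers absent from haplotype matrix")
  ind <- hap_individuals(haps)
  keep <- ind %in% phenotypes$id[phenotypes$status %in% statuses]
  sub <- haps[keep, idx, drop = FALSE]
  match_hap <- !is.na(rowSums(sub == rep(allele_string,
                                         each = nrow(sub)))) &
    rowSums(sub == rep(allele_string, each = nrow(sub))) == length(idx)
  per_ind <- tapply(match_hap, ind[keep], sum)
  n_het <- sum(per_ind == 1L)
  n_hom <- sum(per_ind == 2L)
  n_non <- sum(per_ind == 0L)
  copies <- sum(match_hap)
  n_ind <- length(per_ind)
  list(n_het = n_het, n_hom = n_hom, n_noncarrier = n_non,
       n_individuals = n_ind, carrier_copies = copies,
       frequency = copies / (2L * n_ind))
}
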