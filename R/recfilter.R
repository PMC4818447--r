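# Mendelian-compatibility filtering of sequence variants: a variant is a
# candidate for a fully penetrant recessive defect iff the affected
# sample(s) are homozygous for the alternate allele, the obligate
# carrier(s) are heterozygous, and every control is homozygous reference.
# Candidates are then screened against a multi-population panel (a
# breed-specific founder mutation must not segregate elsewhere) and
# classified by genic region.

#' Filter variants for compatibility with recessive inheritance
#'
#' @param calls a \code{\link{variant_calls}} object.
#' @param case_ids,carrier_ids,control_ids sample names for the affected,
#'   obligate-carrier and control groups; each group must be non-empty and
#'   present in \code{calls}.
#' @param missing_mode \code{"strict"} (default): a missing genotype in
#'   any decisive sample fails the variant; \code{"lenient"}: missing
#'   genotypes are ignored (the condition is evaluated on called samples
#'   only, but at least one called sample per group is still required).
#' @return data.frame of candidate variants (all rows of the input with
#'   the three compatibility flags and a \code{compatible} column; only
#'   rows with \code{compatible == TRUE} are candidates).
#' @export
recessive_compatibility_filter <- function(calls, case_ids, carrier_ids,
                                           control_ids,
                                           missing_mode = c("strict",
                                                            "lenient")) {
  missing_mode <- match.arg(missing_mode)
  groups <- list(case = case_ids, carrier = carrier_ids,
                 control = control_ids)
  for (g in names(groups)) {
    if (length(groups[[g]]) == 0L)
      stopf("empty %s sample group: each condition must be testable", g)
    miss <- setdiff(groups[[g]], calls$samples)
    if (length(miss) > 0L)
      stopf("%s sample(s) absent from call set: %s", g,
            paste(miss, collapse = ", "))
  }
  check <- function(sub, want) {
    if (missing_mode == "strict") {
      ok <- rowSums(sub == want, na.rm = TRUE) == ncol(sub) &
        rowSums(is.na(sub)) == 0L
    } else {
      called <- rowSums(!is.na(sub))
      ok <- called > 0L &
        rowSums(sub == want, na.rm = TRUE) == called
    }
    ok
  }
  case_hom_alt <- check(calls$geno[, case_ids, drop = FALSE], 2L)
  carrier_het <- check(calls$geno[, carrier_ids, drop = FALSE], 1L)
  controls_hom_ref <- check(calls$geno[, control_ids, drop = FALSE], 0L)
  out <- calls$variants
  out$case_hom_alt <- case_hom_alt
  out$carrier_het <- carrier_het
  out$controls_hom_ref <- controls_hom_ref
  out$compatible <- case_hom_alt & carrier_het & controls_hom_ref
  out
}

#' Exclude candidates that segregate in a multi-population panel
#'
#' A candidate is excluded iff its alternate allele is observed in at
#' least one panel genotype (dosage >= 1).  Candidates absent from the
#' panel data are retained with \code{panel_status = "untested"}.
#'
#' @param candidates data.frame of candidate variants (rows with
#'   \code{compatible == TRUE} are used when the column is present).
#' @param panel a \code{\link{variant_calls}} object for the exclusion
#'   panel (sample set disjoint from the study samples).
#' @return List with \code{retained} and \code{excluded} data.frames; both
#'   carry \code{panel_polymorphic} and \code{panel_status} columns.
#' @export
cross_population_exclusion <- function(candidates, panel) {
  cand <- candidates
  if ("compatible" %in% names(cand)) cand <- cand[cand$compatible, ]
  if (nrow(cand) == 0L)
    return(list(retained = cand, excluded = cand))
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  if (nrow(panel$variants) > 0L && ncol(panel$geno) > 0L) {
    seg <- rowSums(panel$geno >= 1L, na.rm = TRUE) > 0L
    panel_key <- key(panel$variants)
  } else {
    seg <- logical(0); panel_key <- character(0)
  }
  idx <- match(key(cand), panel_key)
  cand$panel_polymorphic <- !is.na(idx) & seg[pmax(idx, 1L)]
  cand$panel_polymorphic[is.na(idx)] <- FALSE
  cand$panel_status <- ifelse(is.na(idx), "untested",
                              ifelse(cand$panel_polymorphic,
                                     "polymorphic", "absent"))
  list(retained = cand[!cand$panel_polymorphic, , drop = FALSE],
       excluded = cand[cand$panel_polymorphic, , drop = FALSE])
}

#' Classify a variant by genic region and splice distance
#'
#' Every position on the contig maps to exactly one class per gene model:
#' exonic (inside an exon), intronic (between two exons of the gene) or
#' intergenic.  Intronic variants get the distance to the nearest splice
#' site (min bp to the flanking exon boundaries, 1 for the first intronic
#' base) and are labelled \code{"deprioritized"} when that distance
#' exceeds \code{splice_distance_max} -- a deep-intronic variant is an
#' unlikely splice-disrupting candidate.
#'
#' @param variant list/row with chrom, pos, ref, alt.
#' @param gene a \code{\link{gene_model}}.
#' @param splice_distance_max deprioritization threshold in bp
#'   (default 4000).
#' @return List: \code{region} ("exonic"/"intronic"/"intergenic"),
#'   \code{splice_distance} (bp, NA unless intronic), \code{gene_id} (NA
#'   for intergenic), \code{priority} ("candidate"/"deprioritized").
#' @export
classify_variant_region <- function(variant, gene,
                                    splice_distance_max = 4000) {
  stopifnot(inherits(gene, "gene_model"))
  # classify by the first affected base (indel anchors are untouched)
  p <- variant$pos
  if (nchar(variant$ref) > 1L &&
      substr(variant$ref, 1L, 1L) == substr(variant$alt, 1L, 1L))
    p <- p + 1L
  ex <- gene$exons
  if (!identical(as.character(variant$chrom), gene$contig))
    return(list(region = "intergenic", splice_distance = NA_real_,
                gene_id = NA_character_, priority = "candidate"))
  if (any(ex$start <= p & ex$end >= p))
    return(list(region = "exonic", splice_distance = NA_real_,
                gene_id = gene$gene_id, priority = "candidate"))
  if (p < min(ex$start) || p > max(ex$end))
    return(list(region = "intergenic", splice_distance = NA_real_,
                gene_id = NA_character_, priority = "candidate"))
  i <- max(which(ex$end < p))
  dist <- min(p - ex$end[i], ex$start[i + 1L] - p)
  list(region = "intronic", splice_distance = dist, gene_id = gene$gene_id,
       priority = if (dist > splice_distance_max) "deprioritized"
                  else "candidate")
}

#' Tabulate candidates in the published ten-variant layout
#'
#' Convenience formatter mirroring a candidate table: one row per
#' compatible variant with its panel flag and retention status.
#'
#' @param exclusion result of \code{\link{cross_population_exclusion}}.
#' @return data.frame sorted by position.
#' @export
candidate_table <- function(exclusion) {
  all <- rbind(exclusion$retained, exclusion$excluded)
  all$retained <- !all$panel_polymorphic
  all[order(all$chrom, all$pos), ]
}
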