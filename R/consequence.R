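# Coding-consequence prediction on a gene model: apply a small variant to
# the spliced CDS, translate to the first stop, name the protein change in
# HGVS, model intron-retention transcripts, and run exact-match in-silico
# RT-PCR.  Coordinates are 1-based inclusive in genomic space and 1-based
# from transcription start in transcript space; translation uses the
# standard genetic code only.

# edit the genomic slice with one normalized variant and shift the exon
# coordinates of the gene model accordingly
edit_genome <- function(gene, genome, variant) {
  v <- normalize_variant(variant, genome)
  v_end <- v$pos + nchar(v$ref) - 1
  obs <- slice_seq(genome, v$pos, v_end)
  if (obs != v$ref)
    stopf("variant REF %s does not match sequence %s at %s:%.0f",
          v$ref, obs, v$chrom, v$pos)
  delta <- nchar(v$alt) - nchar(v$ref)
  local <- v$pos - genome$offset
  new_seq <- paste0(substr(genome$seq, 1L, local - 1L), v$alt,
                    substr(genome$seq, local + nchar(v$ref),
                           nchar(genome$seq)))
  ex <- gene$exons
  containing <- which(ex$start <= v$pos & ex$end >= v_end)
  if (length(containing) != 1L) {
    spanning <- any(ex$start <= v_end & ex$end >= v$pos)
    if (spanning) stopf("variant straddles an exon boundary; unsupported")
  }
  contain <- ex$start <= v$pos & ex$end >= v_end
  after <- ex$start > v_end
  ex$start[after] <- ex$start[after] + delta
  ex$end[after | contain] <- ex$end[after | contain] + delta
  list(gene = gene_model(gene$gene_id, gene$transcript_id, gene$contig,
                         gene$strand, ex),
       genome = genome_slice(genome$contig, genome$offset, new_seq),
       variant = v)
}

# genomic position -> CDS (transcript) coordinate, NA if not exonic
genomic_to_cds <- function(gene, pos) {
  ex <- gene$exons
  widths <- ex$end - ex$start + 1L
  cum <- cumsum(widths)
  i <- which(ex$start <= pos & ex$end >= pos)
  if (length(i) == 0L) return(NA_integer_)
  fwd <- (if (i > 1L) cum[i - 1L] else 0L) + (pos - ex$start[i] + 1L)
  if (gene$strand == "+") fwd else sum(widths) - fwd + 1L
}

consequence_record <- function(variant, gene, wt_protein, mut, cdna,
                               protein_hgvs, first_altered) {
  wt_len <- nchar(wt_protein)
  mut_len <- nchar(mut$protein)
  runoff <- !mut$stopped
  rec <- list(variant = variant,
              transcript_id = gene$transcript_id,
              cdna_hgvs = cdna,
              protein_hgvs = protein_hgvs,
              first_altered_residue = first_altered,
              stop_residue = if (runoff) NA_integer_ else mut_len + 1L,
              mutant_length = mut_len,
              residues_removed = if (runoff) NA_integer_ else
                wt_len - mut_len,
              truncation_fraction = if (runoff) NA_real_ else
                (wt_len - mut_len) / wt_len,
              wild_type_length = wt_len,
              runoff = runoff,
              mutant_protein = mut$protein)
  structure(rec, class = "consequence_record")
}

#' @export
print.consequence_record <- function(x, ...) {
  cat(sprintf("%s %s: %s | wt %d aa -> mutant %d aa (%s removed, %.1f%%)\n",
              x$transcript_id, x$cdna_hgvs, x$protein_hgvs,
              x$wild_type_length, x$mutant_length,
              ifelse(is.na(x$residues_removed), "NA",
                     x$residues_removed),
              100 * (x$truncation_fraction %||% NA_real_)))
  invisible(x)
}

first_divergence <- function(wt, mut) {
  n <- min(nchar(wt), nchar(mut))
  if (n > 0L) {
    a <- utf8ToInt(substr(wt, 1L, n)); b <- utf8ToInt(substr(mut, 1L, n))
    d <- which(a != b)
    if (length(d) > 0L) return(d[1L])
  }
  if (nchar(wt) == nchar(mut)) return(NA_integer_)
  n + 1L
}

#' Apply a coding variant to a gene model and translate
#'
#' Splices the exons, applies the (normalized, left-aligned) variant and
#' translates the mutant CDS with the standard genetic code until the
#' first stop codon.  Frameshift, in-frame and synonymous variants are all
#' handled; translation running off the transcript end is flagged
#' (\code{runoff}) with truncation statistics undefined.
#'
#' @param gene a \code{\link{gene_model}}.
#' @param genome a \code{\link{genome_slice}} covering the gene.
#' @param variant list with chrom, pos, ref, alt (VCF conventions).
#' @return A \code{consequence_record}: HGVS cDNA/protein descriptions,
#'   first altered residue, position of the mutant termination codon,
#'   mutant length, residues removed and truncation fraction.
#' @export
apply_variant_and_translate <- function(gene, genome, variant) {
  wt_tx <- splice_transcript(gene, genome)
  wt <- translate_to_stop(wt_tx)
  ed <- edit_genome(gene, genome, variant)
  mut_tx <- splice_transcript(ed$gene, ed$genome)
  mut <- translate_to_stop(mut_tx)

  v <- ed$variant
  cds_pos <- genomic_to_cds(gene, if (nchar(v$ref) > 1L) v$pos + 1L else v$pos)
  if (is.na(cds_pos)) stopf("variant does not overlap the coding sequence")
  delta <- nchar(v$alt) - nchar(v$ref)
  cdna <- if (delta == 0L) {
    if (gene$strand == "+") sprintf("c.%d%s>%s", cds_pos, v$ref, v$alt)
    else sprintf("c.%d%s>%s", cds_pos, revcomp(v$ref), revcomp(v$alt))
  } else if (delta < 0L) {
    n_del <- -delta
    if (n_del == 1L) sprintf("c.%ddel", cds_pos)
    else sprintf("c.%d_%ddel", cds_pos, cds_pos + n_del - 1L)
  } else {
    sprintf("c.%d_%dins%s", cds_pos - 1L, cds_pos, substr(v$alt, 2L,
                                                          nchar(v$alt)))
  }

  div <- first_divergence(wt$protein, mut$protein)
  phgvs <- if (is.na(div)) {
    "p.(=)"
  } else if (delta %% 3L == 0L) {
    w <- substr(wt$protein, div, div); m <- substr(mut$protein, div, div)
    sprintf("p.%s%d%s", aa3(w), div, if (nzchar(m)) aa3(m) else "Ter")
  } else {
    name_frameshift(wt$protein, mut$protein)
  }
  consequence_record(v, gene, wt$protein, mut, cdna, phgvs,
                     if (is.na(div)) NA_integer_ else div)
}

#' HGVS protein name for a frameshift (or simple nonsense) change
#'
#' Emits \code{p.<Ref><Pos><Alt>fsTer<N>} where Pos is the first residue
#' that differs between the wild-type and mutant proteins and N counts the
#' termination codon with the first changed residue as 1 (so the stop sits
#' at overall residue Pos + N - 1).  When the mutant protein is a clean
#' prefix of the wild type (immediate stop, nothing substituted) the
#' simple nonsense form \code{p.<Ref><Pos>Ter} is emitted instead.  "X" is
#' accepted as a legacy synonym for "Ter" when comparing names.
#'
#' @param wild_protein,mutant_protein one-letter amino-acid strings
#'   (stops excluded).
#' @return HGVS protein string.
#' @examples
#' name_frameshift("MKLT", "MN")  # "p.Lys2AsnfsTer2"
#' @export
name_frameshift <- function(wild_protein, mutant_protein) {
  div <- first_divergence(wild_protein, mutant_protein)
  if (is.na(div)) stopf("not a frameshift: proteins are identical")
  if (div > nchar(mutant_protein)) {
    # pure truncation: stop codon where wild type has residue div
    return(sprintf("p.%s%dTer", aa3(substr(wild_protein, div, div)), div))
  }
  n_ter <- nchar(mutant_protein) - div + 2L
  sprintf("p.%s%d%sfsTer%d",
          aa3(substr(wild_protein, div, div)), div,
          aa3(substr(mutant_protein, div, div)), n_ter)
}

#' Translate a transcript with one intron retained
#'
#' Builds the transcript in which the named intron (intron i follows the
#' i-th exon in transcript orientation) is retained in the mature mRNA,
#' optionally after applying an upstream variant, and translates it.
#'
#' @param gene a \code{\link{gene_model}}.
#' @param genome a \code{\link{genome_slice}}.
#' @param intron_index which intron to retain (1-based, transcript order).
#' @param upstream_variant optional variant (chrom/pos/ref/alt) applied
#'   before splicing.
#' @return List with \code{record} (a \code{consequence_record} relative
#'   to the wild-type spliced protein) and \code{transcript} (the
#'   intron-retaining mRNA sequence).
#' @export
retained_intron_translate <- function(gene, genome, intron_index,
                                      upstream_variant = NULL) {
  n_ex <- nrow(gene$exons)
  if (intron_index < 1L || intron_index >= n_ex)
    stopf("intron_index must be in 1..%d", n_ex - 1L)
  wt <- translate_to_stop(splice_transcript(gene, genome))
  if (!is.null(upstream_variant)) {
    ed <- edit_genome(gene, genome, upstream_variant)
    gene2 <- ed$gene; genome2 <- ed$genome; v <- ed$variant
  } else {
    gene2 <- gene; genome2 <- genome; v <- NULL
  }
  # transcript-order exon indices flanking the retained intron
  ord <- if (gene$strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
  i <- ord[intron_index]; j <- ord[intron_index + 1L]
  ex <- gene2$exons
  lo <- min(i, j); hi <- max(i, j)
  merged <- data.frame(start = ex$start[lo], end = ex$end[hi])
  new_ex <- rbind(ex[seq_len(lo - 1L), ], merged,
                  ex[seq.int(hi + 1L, length.out = n_ex - hi), ])
  rownames(new_ex) <- NULL
  gene_ri <- gene_model(gene$gene_id,
                        paste0(gene$transcript_id, "_ri", intron_index),
                        gene$contig, gene$strand, new_ex)
  tx <- splice_transcript(gene_ri, genome2)
  mut <- translate_to_stop(tx)
  div <- first_divergence(wt$protein, mut$protein)
  phgvs <- if (is.na(div)) "p.(=)" else if (div > nchar(mut$protein)) {
    sprintf("p.%s%dTer", aa3(substr(wt$protein, div, div)), div)
  } else if (!mut$stopped || nchar(mut$protein) >= nchar(wt$protein)) {
    sprintf("p.%s%dext", aa3(substr(wt$protein, div, div)), div)
  } else {
    name_frameshift(wt$protein, mut$protein)
  }
  rec <- consequence_record(v %||% list(chrom = gene$contig, pos = NA,
                                        ref = "", alt = "",
                                        id = "intron_retention"),
                            gene_ri, wt$protein, mut,
                            sprintf("r.intron%d_retained", intron_index),
                            phgvs,
                            if (is.na(div)) NA_integer_ else div)
  list(record = rec, transcript = tx)
}

#' Exact-match in-silico RT-PCR
#'
#' Searches each transcript for exact matches of the forward primer on the
#' sense strand and of the reverse complement of the reverse primer
#' downstream; every (forward, reverse) site pair yields one product whose
#' length is the inclusive span.  No mismatches, degeneracy or
#' thermodynamics are modelled.
#'
#' @param transcripts character vector (or list) of transcript sequences.
#' @param forward_primer,reverse_primer primer sequences (>= 15 nt); the
#'   reverse primer is given 5'->3' on the antisense strand.
#' @return A list (one element per transcript) of integer product lengths;
#'   empty when either primer has no exact site.
#' @export
insilico_rtpcr <- function(transcripts, forward_primer, reverse_primer) {
  forward_primer <- toupper(forward_primer)
  reverse_primer <- toupper(reverse_primer)
  if (nchar(forward_primer) < 15L || nchar(reverse_primer) < 15L)
    stopf("primers must be at least 15 nt")
  rsite <- revcomp(reverse_primer)
  out <- lapply(as.character(transcripts), function(tx) {
    f <- gregexpr(forward_primer, tx, fixed = TRUE)[[1L]]
    r <- gregexpr(rsite, tx, fixed = TRUE)[[1L]]
    if (f[1L] == -1L || r[1L] == -1L) return(integer(0))
    out <- integer(0)
    for (fs in f) {
      ends <- r[r >= fs] + nchar(rsite) - 1L
      out <- c(out, ends - fs + 1L)
    }
    sort(out)
  })
  names(out) <- names(transcripts)
  out
}
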