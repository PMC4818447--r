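#' Specification of the engineered disease-gene fixture
#'
#' The fixture is a synthetic 31-exon gene engineered so that (i) the
#' wild-type CDS translates to a 2239-residue protein with no internal
#' stop; (ii) a 1-bp deletion in a CCC homopolymer at codon 1429/1430
#' turns residue 1430 from Glu to Lys and the shifted reading frame meets
#' its first stop as the 66th shifted codon (p.Glu1430LysfsTer66, mutant
#' length 1494, 745 residues removed); (iii) the transcript retaining the
#' intron downstream of the deletion exon terminates at residue 1492; and
#' (iv) RT-PCR primers in the two exons flanking that intron amplify a
#' 348-bp spliced product (348 + intron length when the intron is
#' retained).
#'
#' @param n_exons number of exons.
#' @param protein_length wild-type protein length in residues.
#' @param deletion_exon exon carrying the engineered 1-bp deletion.
#' @param deletion_codon first residue altered by the frameshift.
#' @param shifted_frame_stop_offset shifted-frame codons to the first stop
#'   (the N of fsTer\emph{N}).
#' @param retained_intron_index intron whose retention is modelled (intron
#'   i follows exon i).
#' @param retained_intron_stop_residue position of the termination codon in
#'   the deletion + intron-retention reading (NA when
#'   \code{retained_intron_inframe_stop = FALSE}).
#' @param retained_intron_length intron length in bp (348-bp amplicon +
#'   1140 = the observed 1488-bp retained product).
#' @param retained_intron_inframe_stop when FALSE the retained intron is
#'   built stop-free and in frame (length must be divisible by 3),
#'   exercising the non-truncating branch: retention then lengthens the
#'   protein by length/3 residues.
#' @param primer_exons integer pair: exons carrying the forward primer and
#'   the reverse-primer binding site.
#' @param spliced_amplicon_length RT-PCR product length on the spliced
#'   transcript.
#' @param forward_primer,reverse_primer primer sequences (reverse primer
#'   given 5'->3' on the antisense strand, as ordered from a supplier).
#' @param long_intron_index,long_intron_length one intron is made long so
#'   that deep-intronic decoy variants (> 4 kb from any splice site) can
#'   be placed in it.
#' @param strand "+" or "-"; the minus-strand gene is the exact
#'   reverse-complement mirror and must translate identically.
#' @param genomic_offset global coordinate of the base preceding the
#'   contig slice (the slice models a small region of a real chromosome).
#' @return A validated list of class \code{gene_fixture_spec}.
#' @export
gene_fixture_spec <- function(n_exons = 31L,
                              protein_length = 2239L,
                              deletion_exon = 20L,
                              deletion_codon = 1430L,
                              shifted_frame_stop_offset = 66L,
                              retained_intron_index = 20L,
                              retained_intron_stop_residue = 1492L,
                              retained_intron_length = 1140L,
                              retained_intron_inframe_stop = TRUE,
                              primer_exons = c(20L, 21L),
                              spliced_amplicon_length = 348L,
                              forward_primer = "GAGTCAAGCAGCTCAAACCC",
                              reverse_primer = "AGCCAAGTCAGTTTCTCCATT",
                              long_intron_index = 10L,
                              long_intron_length = 9000L,
                              strand = "+",
                              genomic_offset = NULL) {
  spec <- list(n_exons = as.integer(n_exons),
               protein_length = as.integer(protein_length),
               deletion_exon = as.integer(deletion_exon),
               deletion_codon = as.integer(deletion_codon),
               shifted_frame_stop_offset = as.integer(shifted_frame_stop_offset),
               retained_intron_index = as.integer(retained_intron_index),
               retained_intron_stop_residue =
                 as.integer(retained_intron_stop_residue),
               retained_intron_length = as.integer(retained_intron_length),
               retained_intron_inframe_stop =
                 isTRUE(retained_intron_inframe_stop),
               primer_exons = as.integer(primer_exons),
               spliced_amplicon_length = as.integer(spliced_amplicon_length),
               forward_primer = toupper(forward_primer),
               reverse_primer = toupper(reverse_primer),
               long_intron_index = as.integer(long_intron_index),
               long_intron_length = as.integer(long_intron_length),
               strand = strand,
               genomic_offset = genomic_offset)
  if (spec$deletion_codon >= spec$protein_length)
    stopf("deletion_codon must be < protein_length")
  if (spec$retained_intron_length <= 0)
    stopf("retained_intron_length must be > 0")
  if (spec$deletion_codon + spec$shifted_frame_stop_offset >
      spec$protein_length)
    stopf("unsatisfiable: shifted-frame stop offset %d exceeds remaining sequence after codon %d",
          spec$shifted_frame_stop_offset, spec$deletion_codon)
  if (spec$retained_intron_inframe_stop &&
      spec$retained_intron_index != spec$deletion_exon)
    stopf("unsatisfiable: a stop-bearing retained intron must follow the deletion exon")
  if (!spec$retained_intron_inframe_stop &&
      spec$retained_intron_length %% 3L != 0L)
    stopf("unsatisfiable: a stop-free in-frame retained intron needs length divisible by 3")
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  structure(spec, class = "gene_fixture_spec")
}

# codons with no stop in frame 0; used as random filler for the CDS body
SAFE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE)
                       [Biostrings::GENETIC_CODE != "*"],
                       c("TAC", "TAT", "TGC", "TGT", "AGA", "AGG"))
# (the exclusions keep fillers from forming TAA/TAG/TGA across codon
#  junctions with a following A/G-initial codon is NOT guaranteed by
#  frame-0 safety alone; junction stops only matter in shifted frames,
#  which are fully controlled by the designed window, so plain frame-0
#  safety suffices there.  The exclusion list above additionally avoids
#  fillers whose last two bases are TA/TG or first base completes AG*,
#  keeping the left-alignment anchor logic simple.)

random_safe_codons <- function(n) {
  paste0(sample(SAFE_CODONS, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build the engineered gene fixture
#'
#' Constructs the genomic slice (contig + flanks), the gene model and the
#' truth bookkeeping for the engineered disease gene described in
#' \code{\link{gene_fixture_spec}}.  Construction is deterministic: filler
#' sequence is drawn from an internal fixed-seed RNG, so two calls with
#' the same spec are identical.
#'
#' @param spec a \code{\link{gene_fixture_spec}}.
#' @param causal_pos global (1-based) coordinate the engineered deletion's
#'   3'-most deleted base should fall on; the contig offset is solved for
#'   this.  Ignored when \code{spec$genomic_offset} is given.
#' @return List of class \code{gene_fixture} with elements \code{gene} (a
#'   \code{gene_model}), \code{genome} (a \code{genome_slice}), and
#'   \code{info} (deletion VCF record, primers, wild-type protein, intron
#'   table, deep-intronic position, coordinates).
#' @export
make_gene_fixture <- function(spec = gene_fixture_spec(),
                              causal_pos = 15079217) {
  stopifnot(inherits(spec, "gene_fixture_spec"))
  with_seed(20160331L, build_fixture(spec, causal_pos))
}

build_fixture <- function(spec, causal_pos) {
  P <- spec$protein_length
  D <- spec$deletion_codon
  S <- spec$shifted_frame_stop_offset
  cds_len <- 3L * P + 3L

  ## ---- design the CDS codon-by-codon -------------------------------
  codons <- character(P + 1L)
  codons[P + 1L] <- "TAA"
  body <- sample(SAFE_CODONS, P, replace = TRUE)
  codons[seq_len(P)] <- body
  # designed window around the deletion: codon D-2 anchors left-alignment
  # (must not end in C), D-1 is the CCC homopolymer, D is Glu; the GAA run
  # keeps both reading frames stop-free until the engineered CTA/AGA pair
  # places the shifted-frame stop at codon D+S-1|D+S.
  if (D < 3L) stopf("unsatisfiable: deletion_codon must be >= 3")
  codons[D - 2L] <- "GAT"
  codons[D - 1L] <- "CCC"
  if (D + S - 2L >= D) codons[D:(D + S - 2L)] <- "GAA"
  codons[D + S - 1L] <- "CTA"
  codons[D + S] <- "AGA"

  ## ---- exon layout --------------------------------------------------
  n_ex <- spec$n_exons
  dex <- spec$deletion_exon
  if (dex < 2L || dex >= n_ex)
    stopf("unsatisfiable: deletion_exon must be internal")
  # CDS length through the deletion exon: chosen so the mutant (deleted)
  # exonic sequence ends exactly on a codon boundary and the retained
  # intron supplies residues (stop_residue-1, stop_residue)
  if (spec$retained_intron_inframe_stop) {
    ri_stop <- spec$retained_intron_stop_residue
    cum_dex <- 3L * (ri_stop - 2L) + 1L
  } else {
    cum_dex <- 3L * (D + 5L) + 1L  # anything past the deletion works
  }
  del_base <- 3L * (D - 1L)        # 3rd base of the CCC codon (CDS coords)
  if (cum_dex <= del_base || cum_dex >= cds_len)
    stopf("unsatisfiable: retained_intron_stop_residue inconsistent with deletion_codon/protein_length")

  # reverse-primer site: first codon-aligned CDS position past the
  # designed window and past the deletion-exon boundary
  pf <- nchar(spec$forward_primer)
  pr <- nchar(spec$reverse_primer)
  A <- spec$spliced_amplicon_length
  if ((A - pr) %% 3L != 0L)
    stopf("unsatisfiable: spliced_amplicon_length - reverse primer length must be divisible by 3")
  r0 <- max(3L * (D + S) + 1L, cum_dex + 1L)
  r0 <- r0 + (1L - r0 %% 3L + 3L) %% 3L    # round up to == 1 (mod 3)
  r_end <- r0 + pr - 1L
  f0 <- r_end - A + 1L
  if (f0 <= 0L || f0 + pf + 2L > 3L * (D - 3L))
    stopf("unsatisfiable: amplicon/primer geometry collides with the designed deletion window")

  # exon cumulative CDS lengths: exons 1..dex-1 codon-aligned (so any
  # early intron can be retained in frame), exon dex ends at cum_dex
  cum_prev <- 3L * ((min(f0, del_base) - 1L) %/% 3L)
  cum_prev <- cum_prev - 3L  # strictly before both primer and deletion
  if (cum_prev < 3L * (dex - 1L))
    stopf("unsatisfiable: not enough CDS before the deletion exon")
  lens_early <- rep(cum_prev %/% 3L %/% (dex - 1L) * 3L, dex - 1L)
  lens_early[dex - 1L] <- cum_prev - sum(lens_early[seq_len(dex - 2L)])
  remaining <- cds_len - cum_dex
  n_late <- n_ex - dex
  if (n_late < 1L || remaining < n_late)
    stopf("unsatisfiable: no CDS left for exons after the deletion exon")
  lens_late <- rep(remaining %/% n_late, n_late)
  lens_late[n_late] <- remaining - sum(lens_late[-n_late])
  min_e21 <- r_end - cum_dex
  if (lens_late[1L] < min_e21) {
    lens_late[1L] <- min_e21
    lens_late[n_late] <- remaining - sum(lens_late[-n_late])
    if (lens_late[n_late] < 1L)
      stopf("unsatisfiable: reverse-primer site does not fit in the next exon")
  }
  exon_cds_len <- c(lens_early, cum_dex - cum_prev, lens_late)
  stopifnot(sum(exon_cds_len) == cds_len, all(exon_cds_len >= 1L))

  ## ---- assemble the CDS string and plant primers --------------------
  cds <- paste0(codons, collapse = "")
  substr(cds, f0, f0 + pf - 1L) <- spec$forward_primer
  pad <- f0 + pf
  pad_end <- 3L * ((pad + 2L) %/% 3L)      # complete the partial codon
  if (pad_end >= pad) substr(cds, pad, pad_end) <- substr("TTT", 1L,
                                                          pad_end - pad + 1L)
  rsite <- revcomp(spec$reverse_primer)
  substr(cds, r0, r_end) <- rsite
  # planting is frame-0 aligned by construction; verify no stop appeared
  wt <- translate_to_stop(cds)
  if (nchar(wt$protein) != P)
    stopf("unsatisfiable: primer planting introduced a premature stop")

  ## ---- introns -------------------------------------------------------
  n_in <- n_ex - 1L
  intron_len <- rep(300L, n_in)
  intron_len[spec$long_intron_index] <- spec$long_intron_length
  intron_len[spec$retained_intron_index] <- spec$retained_intron_length
  introns <- vapply(seq_len(n_in), function(i) {
    L <- intron_len[i]
    if (L < 8L) stopf("unsatisfiable: intron %d too short", i)
    if (i == spec$retained_intron_index) {
      if (spec$retained_intron_inframe_stop) {
        paste0("GTGTAA", random_dna(L - 8L), "AG")
      } else {
        k <- (L - 6L) %/% 3L
        paste0("GTT", strrep("GAA", k), "CAG")
      }
    } else {
      paste0("GT", random_dna(L - 4L), "AG")
    }
  }, character(1))

  ## ---- genomic assembly (plus strand first) -------------------------
  flank5 <- random_dna(2000L)
  flank3 <- random_dna(2000L)
  pieces <- character(0)
  exon_starts_local <- integer(n_ex)
  cum_cds <- cumsum(exon_cds_len)
  cds_starts <- c(1L, head(cum_cds, -1L) + 1L)
  pos_local <- nchar(flank5) + 1L
  for (i in seq_len(n_ex)) {
    exon_starts_local[i] <- pos_local
    ex_seq <- substr(cds, cds_starts[i], cum_cds[i])
    pieces <- c(pieces, ex_seq)
    pos_local <- pos_local + exon_cds_len[i]
    if (i <= n_in) {
      pieces <- c(pieces, introns[i])
      pos_local <- pos_local + intron_len[i]
    }
  }
  contig_seq <- paste0(flank5, paste0(pieces, collapse = ""), flank3)
  exon_ends_local <- exon_starts_local + exon_cds_len - 1L

  # solve the offset so the 3'-most deleted C sits at causal_pos
  del_base_local <- exon_starts_local[dex] +
    (del_base - cds_starts[dex])           # local coord of CDS base del_base
  offset <- if (!is.null(spec$genomic_offset)) spec$genomic_offset else
    causal_pos - del_base_local
  if (offset < 0) offset <- 0

  exons <- data.frame(start = exon_starts_local + offset,
                      end = exon_ends_local + offset)
  genome <- genome_slice(contig = "3", offset = offset, seq = contig_seq)
  gene <- gene_model(gene_id = "gon4l_fixture", transcript_id = "tx_fx1",
                     contig = "3", strand = "+", exons = exons)

  # left-aligned VCF record for the engineered deletion: anchor is the T
  # preceding the CCC run (codon D-2 ends in T by design)
  run_start_local <- del_base_local - 2L
  del_rec <- list(chrom = "3", pos = run_start_local - 1L + offset,
                  id = "rs_causal_del",
                  ref = paste0(substr(contig_seq, run_start_local - 1L,
                                      run_start_local)),
                  alt = substr(contig_seq, run_start_local - 1L,
                               run_start_local - 1L),
                  class = "indel")

  long_intron_mid <- offset + exon_ends_local[spec$long_intron_index] +
    intron_len[spec$long_intron_index] %/% 2L

  fx <- list(gene = gene, genome = genome,
             info = list(spec = spec,
                         wt_protein = wt$protein,
                         cds = cds,
                         deletion = del_rec,
                         causal_g_pos = del_base_local + offset,
                         forward_primer = spec$forward_primer,
                         reverse_primer = spec$reverse_primer,
                         intron_lengths = intron_len,
                         deep_intronic_pos = long_intron_mid,
                         exon_cds_len = exon_cds_len))
  if (spec$strand == "-") fx <- mirror_fixture(fx)
  structure(fx, class = "gene_fixture")
}

# reverse-complement mirror of the fixture: same protein, minus strand
mirror_fixture <- function(fx) {
  g <- fx$genome
  L <- nchar(g$seq)
  flip <- function(p) g$offset + L - (p - g$offset) + 1L
  new_seq <- revcomp(g$seq)
  ex <- fx$gene$exons
  new_ex <- data.frame(start = flip(ex$end), end = flip(ex$start))
  new_ex <- new_ex[order(new_ex$start), ]
  rownames(new_ex) <- NULL
  fx$genome <- genome_slice(g$contig, g$offset, new_seq)
  fx$gene <- gene_model(fx$gene$gene_id, fx$gene$transcript_id,
                        fx$gene$contig, "-", new_ex)
  d <- fx$info$deletion
  # re-anchor the deletion on the new forward strand: the CC run is now GG;
  # keep the original (plus-strand CDS) coordinates for bookkeeping and
  # re-derive the VCF record by normalizing the reverse-complement edit
  ref_rc <- revcomp(d$ref); alt_rc <- revcomp(d$alt)
  new_pos <- flip(d$pos + nchar(d$ref) - 1L)
  fx$info$deletion <- normalize_variant(list(chrom = d$chrom, pos = new_pos,
                                             id = d$id, ref = ref_rc,
                                             alt = alt_rc,
                                             class = d$class), fx$genome)
  fx$info$causal_g_pos <- flip(fx$info$causal_g_pos)
  fx$info$deep_intronic_pos <- flip(fx$info$deep_intronic_pos)
  fx
}
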