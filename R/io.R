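# Containers for the sequence-level side of the pipeline and readers /
# writers for the plain-text interchange formats (TSV, VCF, GFF3, FASTA,
# BED, JSON truth sidecar).  All coordinates are 1-based inclusive in
# genomic space; BED output is converted to 0-based half-open on write.

#' Genomic slice: a contig interval with its sequence
#'
#' The pipeline models a small region of a chromosome (the mapped
#' interval) rather than a whole genome: \code{offset} is the global
#' coordinate of the base preceding the first base of \code{seq}, so
#' global position p corresponds to \code{substr(seq, p - offset, ...)}.
#'
#' @param contig contig/chromosome name.
#' @param offset global coordinate of the base before the slice (0 for a
#'   whole contig).
#' @param seq nucleotide sequence (character).
#' @return Object of class \code{genome_slice}.
#' @export
genome_slice <- function(contig, offset, seq) {
  structure(list(contig = as.character(contig), offset = as.numeric(offset),
                 seq = toupper(as.character(seq))),
            class = "genome_slice")
}

slice_seq <- function(genome, start, end) {
  a <- start - genome$offset
  b <- end - genome$offset
  if (a < 1 || b > nchar(genome$seq))
    stopf("interval %d-%d outside genomic slice", start, end)
  substr(genome$seq, a, b)
}

#' Gene model: exon/intron structure of one transcript
#'
#' @param gene_id,transcript_id identifiers.
#' @param contig contig name.
#' @param strand "+" or "-".
#' @param exons data.frame with columns \code{start}, \code{end} (1-based
#'   inclusive, genomic order); exons must be sorted and non-overlapping.
#'   The full exonic sequence is coding (no UTR is modelled).
#' @return Object of class \code{gene_model}.
#' @export
gene_model <- function(gene_id, transcript_id, contig, strand, exons) {
  exons <- as.data.frame(exons)[, c("start", "end")]
  if (any(exons$end < exons$start)) stopf("malformed gene model: exon end < start")
  if (is.unsorted(exons$start, strictly = TRUE))
    stopf("malformed gene model: exons not sorted")
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stopf("malformed gene model: overlapping exons")
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 contig = as.character(contig), strand = strand,
                 exons = exons),
            class = "gene_model")
}

# spliced transcript sequence (5'->3' in transcript orientation)
splice_transcript <- function(gene, genome) {
  pieces <- mapply(slice_seq, gene$exons$start, gene$exons$end,
                   MoreArgs = list(genome = genome))
  s <- paste0(pieces, collapse = "")
  if (gene$strand == "-") s <- revcomp(s)
  s
}

# Parsimonious left-aligned representation of a REF/ALT pair: trim the
# shared suffix, then the shared prefix (keeping one anchor base for
# indels), then shift an indel leftwards through any homopolymer run.
normalize_variant <- function(variant, genome = NULL) {
  ref <- toupper(variant$ref); alt <- toupper(variant$alt)
  pos <- variant$pos
  # trim common suffix
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # trim common prefix, keep an anchor for indels
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  # left-shift pure indels through repeats when sequence context is known
  if (!is.null(genome) && nchar(ref) != nchar(alt) &&
      substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    repeat {
      last_ref <- substr(ref, nchar(ref), nchar(ref))
      last_alt <- substr(alt, nchar(alt), nchar(alt))
      if (last_ref != last_alt || pos - 1L <= genome$offset) break
      prev <- slice_seq(genome, pos - 1L, pos - 1L)
      ref <- paste0(prev, substr(ref, 1L, nchar(ref) - 1L))
      alt <- paste0(prev, substr(alt, 1L, nchar(alt) - 1L))
      pos <- pos - 1L
    }
  }
  variant$pos <- pos; variant$ref <- ref; variant$alt <- alt
  variant
}

#' Sequence-level variant calls with per-sample genotypes
#'
#' @param variants data.frame with columns chrom, pos, id, ref, alt, class
#'   (one of "SNV", "indel", "SV").
#' @param geno integer matrix of alternate-allele dosages (variants x
#'   samples; 0/1/2, NA = missing).
#' @param roles optional data.frame (sample, role) with roles in
#'   case/carrier/control/panel.
#' @return Object of class \code{variant_calls}.
#' @export
variant_calls <- function(variants, geno, roles = NULL) {
  variants <- as.data.frame(variants)
  need <- c("chrom", "pos", "id", "ref", "alt", "class")
  if (!all(need %in% names(variants)))
    stopf("variants must have columns %s", paste(need, collapse = ", "))
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(variants))
    stopf("geno rows must match variants")
  structure(list(variants = variants, geno = geno,
                 samples = colnames(geno), roles = roles),
            class = "variant_calls")
}

#' @export
print.variant_calls <- function(x, ...) {
  cat(sprintf("variant_calls: %d variants x %d samples\n",
              nrow(x$variants), ncol(x$geno)))
  invisible(x)
}

#' Subset a variant-call set by sample
#' @param calls a \code{\link{variant_calls}} object.
#' @param samples sample names to keep.
#' @return A \code{variant_calls} with the selected samples.
#' @export
subset_samples <- function(calls, samples) {
  miss <- setdiff(samples, calls$samples)
  if (length(miss) > 0L)
    stopf("samples absent from call set: %s", paste(miss, collapse = ", "))
  variant_calls(calls$variants, calls$geno[, samples, drop = FALSE],
                roles = if (!is.null(calls$roles))
                  calls$roles[calls$roles$sample %in% samples, ])
}

## ---------------------------------------------------------------------
## TSV array formats

#' @rdname array_io
#' @param haps phased haplotype matrix (2 rows per individual).
#' @param path output/input file path.
#' @export
write_hap_tsv <- function(haps, path) {
  df <- data.frame(hap_id = rownames(haps),
                   individual = hap_individuals(haps),
                   haps, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Array-format TSV readers and writers
#'
#' One row per haplotype copy (columns: hap_id, individual, then one
#' column per marker with 0/1/NA alleles); the marker map and phenotype
#' tables are plain TSV.
#'
#' @name array_io
#' @return Readers return the corresponding object; writers return
#'   invisibly.
#' @export
read_hap_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = NA)
  h <- as.matrix(df[, -(1:2), drop = FALSE])
  mode(h) <- "integer"
  rownames(h) <- df$hap_id
  attr(h, "individuals") <- as.character(df$individual)
  h
}

#' @rdname array_io
#' @param map marker map data.frame.
#' @export
write_map_tsv <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname array_io
#' @export
read_map_tsv <- function(path) {
  read.delim(path, colClasses = c(chrom = "character"))
}

#' @rdname array_io
#' @param phenotypes phenotype data.frame.
#' @export
write_pheno_tsv <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname array_io
#' @export
read_pheno_tsv <- function(path) {
  read.delim(path, colClasses = c(id = "character"))
}

## ---------------------------------------------------------------------
## VCF

dosage_to_gt <- function(d, phased = FALSE) {
  sep <- if (phased) "|" else "/"
  out <- rep("./.", length(d))
  out[!is.na(d) & d == 0L] <- paste0("0", sep, "0")
  out[!is.na(d) & d == 1L] <- paste0("0", sep, "1")
  out[!is.na(d) & d == 2L] <- paste0("1", sep, "1")
  out
}

gt_to_dosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  a <- strsplit(gt, "[/|]")
  vapply(a, function(x) {
    x <- suppressWarnings(as.integer(x))
    if (anyNA(x)) NA_integer_ else sum(x > 0L)
  }, integer(1))
}

#' Write a variant-call set as VCF v4.2
#'
#' Genotypes are emitted as GT fields (unphased "/"; the sequence-level
#' calls carry no phase information in this pipeline).
#'
#' @param calls a \code{\link{variant_calls}} object.
#' @param path output path (plain text).
#' @export
write_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=recessmap",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", calls$samples),
                     collapse = "\t")), con)
  v <- calls$variants
  gt <- apply(calls$geno, 1L, dosage_to_gt)
  gt <- if (is.matrix(gt)) t(gt) else matrix(gt, nrow = nrow(v))
  body <- paste(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE),
                v$id, v$ref, v$alt, ".", "PASS", paste0("CLASS=", v$class),
                "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a VCF into a variant-call set
#'
#' Uses Bioconductor's VariantAnnotation parser when available and falls
#' back to a minimal GT-only reader for the plain VCFs this package
#' writes.
#'
#' @param path VCF path.
#' @return A \code{\link{variant_calls}} object (dosage-coded genotypes).
#' @export
read_vcf <- function(path) {
  if (requireNamespace("VariantAnnotation", quietly = TRUE)) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    alt <- vapply(as.list(rr$ALT), function(a)
      as.character(a)[1L], character(1))
    info <- VariantAnnotation::info(vcf)
    cls <- if ("CLASS" %in% names(info)) as.character(info$CLASS) else
      ifelse(nchar(as.character(rr$REF)) == nchar(alt), "SNV", "indel")
    v <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(rr)),
                    pos = IRanges::start(IRanges::ranges(rr)),
                    id = names(rr) %||% sprintf("var%05d", seq_along(rr)),
                    ref = as.character(rr$REF), alt = alt, class = cls,
                    stringsAsFactors = FALSE)
    gtm <- VariantAnnotation::geno(vcf)$GT
    geno <- matrix(gt_to_dosage(gtm), nrow = nrow(gtm),
                   dimnames = dimnames(gtm))
    return(variant_calls(v, geno))
  }
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  cols <- strsplit(hdr, "\t")[[1]]
  body <- lines[!startsWith(lines, "#")]
  f <- strsplit(body, "\t")
  m <- do.call(rbind, f)
  cls <- sub("^CLASS=", "", m[, 8L])
  cls[!cls %in% c("SNV", "indel", "SV")] <-
    ifelse(nchar(m[!cls %in% c("SNV", "indel", "SV"), 4L]) ==
             nchar(m[!cls %in% c("SNV", "indel", "SV"), 5L]), "SNV", "indel")
  v <- data.frame(chrom = m[, 1L], pos = as.numeric(m[, 2L]), id = m[, 3L],
                  ref = m[, 4L], alt = m[, 5L], class = cls,
                  stringsAsFactors = FALSE)
  geno <- matrix(gt_to_dosage(m[, -(1:9), drop = FALSE]), nrow = nrow(m),
                 dimnames = list(NULL, cols[-(1:9)]))
  variant_calls(v, geno)
}

## ---------------------------------------------------------------------
## GFF3 / FASTA / BED / JSON

#' Write a gene model as GFF3
#' @param gene a \code{\link{gene_model}}.
#' @param path output path.
#' @export
write_gff3 <- function(gene, path) {
  ex <- gene$exons
  g_start <- min(ex$start); g_end <- max(ex$end)
  att <- function(...) paste(..., sep = ";")
  rows <- c(
    sprintf("%s\trecessmap\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            gene$contig, g_start, g_end, gene$strand, gene$gene_id),
    sprintf("%s\trecessmap\tmRNA\t%d\t%d\t.\t%s\t.\t%s",
            gene$contig, g_start, g_end, gene$strand,
            att(paste0("ID=", gene$transcript_id),
                paste0("Parent=", gene$gene_id))),
    sprintf("%s\trecessmap\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
            gene$contig, ex$start, ex$end, gene$strand, gene$transcript_id),
    sprintf("%s\trecessmap\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
            gene$contig, ex$start, ex$end, gene$strand, gene$transcript_id))
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Read a single-transcript gene model from GFF3
#' @param path GFF3 path.
#' @return A \code{\link{gene_model}}.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t")
  m <- do.call(rbind, f)
  typ <- m[, 3L]
  get_attr <- function(s, key) {
    v <- regmatches(s, regexec(paste0(key, "=([^;]+)"), s))[[1]]
    if (length(v) == 2L) v[2L] else NA_character_
  }
  gene_row <- which(typ == "gene")[1L]
  mrna_row <- which(typ == "mRNA")[1L]
  ex <- m[typ == "exon", , drop = FALSE]
  gene_model(gene_id = get_attr(m[gene_row, 9L], "ID"),
             transcript_id = get_attr(m[mrna_row, 9L], "ID"),
             contig = m[gene_row, 1L], strand = m[gene_row, 7L],
             exons = data.frame(start = as.integer(ex[, 4L]),
                                end = as.integer(ex[, 5L])))
}

#' Write / read a genome slice as FASTA
#'
#' The global offset is carried in the description line
#' (\code{>contig offset=N}), keeping the file a valid FASTA.
#'
#' @param genome a \code{\link{genome_slice}}.
#' @param path file path.
#' @name fasta_io
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$seq)
  names(x) <- sprintf("%s offset=%.0f", genome$contig, genome$offset)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname fasta_io
#' @export
read_fasta_slice <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- names(x)[1L]
  contig <- sub("\\s.*$", "", nm)
  off <- regmatches(nm, regexec("offset=([0-9]+)", nm))[[1]]
  offset <- if (length(off) == 2L) as.numeric(off[2L]) else 0
  genome_slice(contig, offset, as.character(x[[1L]]))
}

#' Write genomic intervals as BED (0-based half-open)
#' @param df data.frame with columns chrom, start, end (1-based inclusive)
#'   and optionally name.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  name <- if ("name" %in% names(df)) df$name else "."
  out <- data.frame(df$chrom, format(df$start - 1L, scientific = FALSE,
                                     trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE), name)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the simulation truth sidecar as JSON
#' @param truth truth record from \code{\link{simulate_population}}.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
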