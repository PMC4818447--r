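# Sequence-cohort generator: emulates multi-sample variant calls over the
# mapped interval for one affected animal (hom-alt at the causal site),
# the obligate-carrier founder bull (het), a control cohort (hom-ref) and
# a multi-breed exclusion panel.  Decoy variants pass the same
# three-sample compatibility conditions; a configured fraction of them
# segregate in the panel (and are therefore excluded downstream), the
# remainder are panel-clean but placed deep inside a long intron so that
# region classification deprioritizes them -- mirroring how the real
# analysis narrowed ten compatible variants to one coding candidate.

#' Simulate a sequence-level variant-call cohort around the causal site
#'
#' @param config a \code{\link{simulation_config}}.
#' @param truth truth sidecar from \code{\link{simulate_population}}.
#' @param fixture optional \code{\link{make_gene_fixture}} result; built
#'   with the config's causal position when omitted.
#' @return A \code{\link{variant_calls}} object containing the causal
#'   1-bp deletion, \code{n_background_variants} compatible decoys,
#'   \code{n_incompatible_variants} ordinary polymorphisms and genotypes
#'   for DW_hom (case), DW_het (obligate carrier),
#'   \code{n_seq_controls} controls and \code{n_panel_individuals} panel
#'   animals; sample roles are in \code{$roles} and the fixture is
#'   attached as attribute \code{"fixture"}.
#' @export
simulate_sequence_cohort <- function(config, truth,
                                     fixture = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(fixture))
    fixture <- make_gene_fixture(causal_pos = config$causal_pos)
  with_seed(config$seed + 1000003L,
            simulate_sequence_cohort_impl(config, truth, fixture))
}

simulate_sequence_cohort_impl <- function(cfg, truth, fx) {
  genome <- fx$genome
  slice_start <- genome$offset + 1
  slice_end <- genome$offset + nchar(genome$seq)
  n_bg <- cfg$n_background_variants
  n_inc <- cfg$n_incompatible_variants
  n_poly <- round(cfg$panel_polymorphic_fraction * n_bg)
  n_clean <- n_bg - n_poly

  samples <- c("DW_hom", "DW_het",
               sprintf("seqctrl_%03d", seq_len(cfg$n_seq_controls)),
               if (cfg$n_panel_individuals > 0L)
                 sprintf("panel_%04d", seq_len(cfg$n_panel_individuals)))
  roles <- data.frame(
    sample = samples,
    role = c("case", "carrier", rep("control", cfg$n_seq_controls),
             rep("panel", cfg$n_panel_individuals)),
    stringsAsFactors = FALSE)
  is_panel <- roles$role == "panel"

  used <- fx$info$deletion$pos
  draw_pos <- function(lo, hi) {
    p <- floor(runif(1, lo, hi + 1))
    while (p %in% used) p <- p + 1  # deterministic repositioning
    used <<- c(used, p)
    p
  }
  snv_at <- function(pos, id) {
    ref <- slice_seq(genome, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    data.frame(chrom = genome$contig, pos = pos, id = id, ref = ref,
               alt = alt, class = "SNV", stringsAsFactors = FALSE)
  }

  # deep-intronic window of the long intron: > splice_distance_max from
  # both splice sites
  deep_lo <- fx$info$deep_intronic_pos - 200
  deep_hi <- fx$info$deep_intronic_pos + 200
  # anywhere else in the slice (flanks, short introns, other exons)
  variants <- list()
  genos <- list()
  n_samp <- length(samples)

  compat_geno <- function(panel_polymorphic) {
    g <- integer(n_samp)
    g[1L] <- 2L; g[2L] <- 1L
    if (panel_polymorphic && any(is_panel)) {
      k <- max(1L, rbinom(1L, sum(is_panel), 0.02))
      hit <- sample(which(is_panel), k)
      g[hit] <- pmin(1L + rbinom(k, 1L, 0.1), 2L)
    }
    g
  }

  # causal deletion
  variants[[1L]] <- as.data.frame(fx$info$deletion,
                                  stringsAsFactors = FALSE)
  genos[[1L]] <- compat_geno(FALSE)

  k <- 1L
  if (n_clean > 0L) for (i in seq_len(n_clean)) {
    k <- k + 1L
    variants[[k]] <- snv_at(draw_pos(deep_lo, deep_hi),
                            sprintf("bg_clean_%02d", i))
    genos[[k]] <- compat_geno(FALSE)
  }
  if (n_poly > 0L) for (i in seq_len(n_poly)) {
    k <- k + 1L
    variants[[k]] <- snv_at(draw_pos(slice_start + 10, slice_end - 10),
                            sprintf("bg_poly_%02d", i))
    genos[[k]] <- compat_geno(TRUE)
  }
  if (n_inc > 0L) for (i in seq_len(n_inc)) {
    k <- k + 1L
    variants[[k]] <- snv_at(draw_pos(slice_start + 10, slice_end - 10),
                            sprintf("bg_inc_%02d", i))
    maf <- runif(1, 0.02, 0.3)
    g <- rbinom(n_samp, 2L, maf)
    # guarantee incompatibility: at least one control carries the alt
    ctrl_idx <- 2L + seq_len(cfg$n_seq_controls)
    if (all(g[ctrl_idx] == 0L)) g[ctrl_idx[1L]] <- 1L
    genos[[k]] <- g
  }

  v <- do.call(rbind, variants)
  geno <- do.call(rbind, genos)
  colnames(geno) <- samples
  ord <- order(v$pos)
  calls <- variant_calls(v[ord, , drop = FALSE],
                         geno[ord, , drop = FALSE], roles = roles)
  attr(calls, "fixture") <- fx
  calls
}

#' Split a sequence cohort into study and panel call sets
#' @param calls result of \code{\link{simulate_sequence_cohort}}.
#' @return List with \code{study} and \code{panel} \code{variant_calls}.
#' @export
split_panel <- function(calls) {
  stopifnot(!is.null(calls$roles))
  pan <- calls$roles$sample[calls$roles$role == "panel"]
  stu <- setdiff(calls$samples, pan)
  list(study = subset_samples(calls, stu),
       panel = subset_samples(calls, pan))
}

#' Emulate validation-cohort genotyping of the array animals
#'
#' Mirrors a direct gene test (KASP-style) of the causal variant in the
#' array cohort: each animal's dosage equals its number of planted
#' founder-haplotype copies (derived from the simulation truth record,
#' i.e. genotyping is error-free).
#'
#' @param cohort a \code{sim_cohort}.
#' @return Named integer vector of alternate-allele dosages, one per
#'   array individual.
#' @export
genotype_validation_cohort <- function(cohort) {
  ids <- unique(hap_individuals(cohort$haps))
  truth <- cohort$truth
  d <- setNames(integer(length(ids)), ids)
  d[truth$cases] <- 2L
  carrier_ids <- hap_row_ids(truth$carrier_hap_rows)
  tab <- table(carrier_ids)
  d[names(tab)] <- pmin(as.integer(tab), 2L)
  d[truth$cases] <- 2L
  d
}
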