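#' Simulation configuration for a founder-haplotype recessive cohort
#'
#' Describes the synthetic world the generator emits: a livestock
#' population segregating a rare founder-derived haplotype that causes a
#' fully penetrant recessive defect.  Defaults mirror the published
#' dwarfism mapping cohort where a stated value exists (27 affected
#' half-sibs, carrier haplotype frequency about 0.4\%, a ~1.85-Mb founder
#' segment on chromosome 3, ten recessive-compatible sequence variants of
#' which eight segregate in other breeds, a 1005-animal multi-breed
#' exclusion panel, 288 sequenced controls); the control cohort is scaled
#' down from 10,454 to 2,000 animals so the full pipeline runs in seconds.
#'
#' @param seed integer seed; identical configs and seeds give bit-identical
#'   cohorts.
#' @param n_cases number of affected animals (homozygous for the planted
#'   haplotype).
#' @param n_controls number of unaffected array-genotyped animals.
#' @param n_markers_per_chrom,n_chromosomes array geometry; markers are
#'   evenly spaced with jitter at ~50 kb.
#' @param causal_chrom chromosome carrying the defect (identifier).
#' @param causal_pos 1-based bp position of the causal 1-bp deletion.
#' @param disease_hap_span length-2 numeric, bp interval of the planted
#'   founder haplotype (must contain \code{causal_pos}).
#' @param carrier_hap_freq founder-haplotype frequency among control
#'   haplotype copies.
#' @param background_maf_range length-2 numeric, per-marker minor allele
#'   frequencies are drawn uniformly from this range.
#' @param genotyping_error_rate per-genotype-call probability of a
#'   symmetric single-allele flip (applied after truth phase is recorded).
#' @param missing_rate per-genotype-call probability of missingness (both
#'   alleles set to NA).
#' @param n_background_variants sequence-level decoy variants that pass the
#'   three-sample recessive-compatibility conditions (the Table-1 analogue
#'   world has 9 decoys + 1 causal = 10 compatible variants).
#' @param n_incompatible_variants additional sequence variants that violate
#'   at least one of the three conditions (background polymorphism).
#' @param panel_polymorphic_fraction fraction of compatible decoys whose
#'   alternate allele segregates in the multi-breed exclusion panel
#'   (default 8/9, so cross-population exclusion retains 2 of 10).
#' @param n_panel_individuals size of the multi-breed exclusion panel.
#' @param n_seq_controls sequenced control animals in the variant-call set.
#' @param marker_spacing_bp mean inter-marker distance in bp.
#' @return An object of class \code{sim_config} (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              n_cases = 27L,
                              n_controls = 2000L,
                              n_markers_per_chrom = 400L,
                              n_chromosomes = 5L,
                              causal_chrom = "3",
                              causal_pos = 15079217,
                              disease_hap_span = c(14880000, 16730000),
                              carrier_hap_freq = 0.004,
                              background_maf_range = c(0.05, 0.5),
                              genotyping_error_rate = 0.001,
                              missing_rate = 0.005,
                              n_background_variants = 9L,
                              n_incompatible_variants = 40L,
                              panel_polymorphic_fraction = 8 / 9,
                              n_panel_individuals = 1005L,
                              n_seq_controls = 288L,
                              marker_spacing_bp = 50000) {
  cfg <- list(seed = as.integer(seed), n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              n_markers_per_chrom = as.integer(n_markers_per_chrom),
              n_chromosomes = as.integer(n_chromosomes),
              causal_chrom = as.character(causal_chrom),
              causal_pos = as.numeric(causal_pos),
              disease_hap_span = as.numeric(disease_hap_span),
              carrier_hap_freq = carrier_hap_freq,
              background_maf_range = as.numeric(background_maf_range),
              genotyping_error_rate = genotyping_error_rate,
              missing_rate = missing_rate,
              n_background_variants = as.integer(n_background_variants),
              n_incompatible_variants = as.integer(n_incompatible_variants),
              panel_polymorphic_fraction = panel_polymorphic_fraction,
              n_panel_individuals = as.integer(n_panel_individuals),
              n_seq_controls = as.integer(n_seq_controls),
              marker_spacing_bp = as.numeric(marker_spacing_bp))
  props <- c(cfg$carrier_hap_freq, cfg$background_maf_range,
             cfg$genotyping_error_rate, cfg$missing_rate,
             cfg$panel_polymorphic_fraction)
  if (any(props < 0 | props > 1))
    stopf("all proportions must lie in [0, 1]")
  if (cfg$n_cases < 1L) stopf("n_cases must be >= 1")
  if (length(cfg$disease_hap_span) != 2L ||
      diff(cfg$disease_hap_span) <= 0)
    stopf("disease_hap_span must be an increasing bp interval")
  if (cfg$causal_pos < cfg$disease_hap_span[1] ||
      cfg$causal_pos > cfg$disease_hap_span[2])
    stopf("causal_pos must lie inside disease_hap_span")
  if (!cfg$causal_chrom %in% as.character(seq_len(cfg$n_chromosomes)))
    stopf("causal_chrom must name one of the simulated chromosomes")
  structure(cfg, class = "sim_config")
}

# individual ids of a haplotype matrix (two consecutive rows per animal)
hap_individuals <- function(haps) attr(haps, "individuals")

#' Collapse a phased haplotype matrix to diploid dosage genotypes
#'
#' @param haps phased 0/1 haplotype matrix (2 rows per individual) as
#'   produced by \code{\link{simulate_population}}.
#' @return Integer matrix (individuals x markers) of alternate-allele
#'   dosages 0/1/2 with NA for missing calls.
#' @export
haps_to_genotypes <- function(haps) {
  ids <- unique(hap_individuals(haps))
  i1 <- seq(1L, nrow(haps), by = 2L)
  g <- haps[i1, , drop = FALSE] + haps[i1 + 1L, , drop = FALSE]
  rownames(g) <- ids
  g
}

#' Simulate an array-genotyped cohort with a planted recessive haplotype
#'
#' Gene-dropping generator: a founder haplotype (a fixed allele string over
#' the markers inside \code{disease_hap_span} on \code{causal_chrom}) is
#' planted homozygously in every case and in heterozygous state in a
#' random ~\code{carrier_hap_freq} fraction of control haplotype copies
#' (never homozygous in controls).  All other marker alleles are drawn
#' independently per locus with MAF uniform in \code{background_maf_range}
#' (no background LD).  Genotyping error (symmetric single-allele flips)
#' and missingness are injected only after the truth phase is recorded.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return A list of class \code{sim_cohort}:
#'   \describe{
#'     \item{haps}{integer phased haplotype matrix, 2 rows per individual
#'       (rownames \code{<id>|1}, \code{<id>|2}), 0 = ref, 1 = alt, NA =
#'       missing.}
#'     \item{map}{data.frame marker/chrom/pos/ref/alt, sorted by
#'       (chrom, pos).}
#'     \item{phenotypes}{data.frame id/status/role/breed/sex/birth_year.}
#'     \item{truth}{planted-haplotype sidecar: span, founder allele
#'       string, carrier ids, carrier haplotype rows, causal position.}
#'   }
#' @export
simulate_population <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_population_impl(config))
}

simulate_population_impl <- function(cfg) {
  chroms <- as.character(seq_len(cfg$n_chromosomes))
  m <- cfg$n_markers_per_chrom
  # evenly spaced positions with jitter; jitter < spacing/2 keeps order
  map <- do.call(rbind, lapply(chroms, function(ch) {
    base <- seq_len(m) * cfg$marker_spacing_bp
    pos <- round(base + runif(m, -0.4, 0.4) * cfg$marker_spacing_bp)
    data.frame(marker = sprintf("snp%s_%04d", ch, seq_len(m)),
               chrom = ch, pos = pos, ref = "A", alt = "B",
               stringsAsFactors = FALSE)
  }))
  map <- map[order(match(map$chrom, chroms), map$pos), ]
  rownames(map) <- NULL

  span_idx <- which(map$chrom == cfg$causal_chrom &
                    map$pos >= cfg$disease_hap_span[1] &
                    map$pos <= cfg$disease_hap_span[2])
  if (length(span_idx) == 0L)
    stopf("no markers fall inside disease_hap_span: map too sparse")

  n_ind <- cfg$n_cases + cfg$n_controls
  ids <- c(sprintf("case_%03d", seq_len(cfg$n_cases)),
           sprintf("ctrl_%05d", seq_len(cfg$n_controls)))
  n_hap <- 2L * n_ind
  n_mark <- nrow(map)

  maf <- runif(n_mark, cfg$background_maf_range[1],
               cfg$background_maf_range[2])
  haps <- matrix(0L, nrow = n_hap, ncol = n_mark,
                 dimnames = list(paste0(rep(ids, each = 2L), "|",
                                        rep(1:2, n_ind)),
                                 map$marker))
  for (j in seq_len(n_mark))
    haps[, j] <- as.integer(runif(n_hap) < maf[j])

  founder <- as.integer(runif(length(span_idx)) < 0.5)

  # plant: cases homozygous; control haplotype copies carriers at ~freq,
  # never two copies in one control (affected <=> homozygous, exactly)
  case_rows <- seq_len(2L * cfg$n_cases)
  haps[case_rows, span_idx] <- rep(founder, each = length(case_rows))
  ctrl_rows <- (2L * cfg$n_cases + 1L):n_hap
  carrier_draw <- runif(length(ctrl_rows)) < cfg$carrier_hap_freq
  # de-duplicate within an individual: keep only the first copy
  first_of_pair <- seq_along(ctrl_rows) %% 2L == 1L
  both <- which(!first_of_pair & carrier_draw &
                carrier_draw[pmax(seq_along(ctrl_rows) - 1L, 1L)])
  carrier_draw[both] <- FALSE
  carrier_rows <- ctrl_rows[carrier_draw]
  if (length(carrier_rows) == 0L)
    warnf("carrier_hap_freq so low that zero control carriers were drawn")
  haps[carrier_rows, span_idx] <- rep(founder, each = length(carrier_rows))

  carrier_ids <- unique(hap_row_ids(rownames(haps)[carrier_rows]))
  truth <- list(chrom = cfg$causal_chrom,
                span = cfg$disease_hap_span,
                span_markers = map$marker[span_idx],
                founder_hap = founder,
                cases = ids[seq_len(cfg$n_cases)],
                carriers = carrier_ids,
                carrier_hap_rows = rownames(haps)[carrier_rows],
                causal_pos = cfg$causal_pos)

  attr(haps, "individuals") <- rep(ids, each = 2L)

  # post-truth noise: symmetric allele flip per genotype call, then missing
  if (cfg$genotyping_error_rate > 0) {
    flip <- matrix(runif(n_ind * n_mark) < cfg$genotyping_error_rate,
                   n_ind, n_mark)
    which_allele <- matrix(sample(c(0L, 1L), n_ind * n_mark, TRUE),
                           n_ind, n_mark)
    idx <- which(flip, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      rows <- 2L * (idx[, 1L] - 1L) + 1L + which_allele[flip]
      flat <- cbind(rows, idx[, 2L])
      haps[flat] <- 1L - haps[flat]
    }
  }
  if (cfg$missing_rate > 0) {
    miss <- matrix(runif(n_ind * n_mark) < cfg$missing_rate, n_ind, n_mark)
    idx <- which(miss, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      haps[cbind(2L * (idx[, 1L] - 1L) + 1L, idx[, 2L])] <- NA_integer_
      haps[cbind(2L * idx[, 1L], idx[, 2L])] <- NA_integer_
    }
  }

  phenotypes <- data.frame(
    id = ids,
    status = rep(c("affected", "unaffected"),
                 c(cfg$n_cases, cfg$n_controls)),
    role = rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls)),
    breed = "Fleckvieh",
    sex = sample(c("male", "female"), n_ind, replace = TRUE),
    birth_year = sample(2000:2013, n_ind, replace = TRUE),
    stringsAsFactors = FALSE)

  structure(list(haps = haps, map = map, phenotypes = phenotypes,
                 truth = truth, config = cfg),
            class = "sim_cohort")
}

hap_row_ids <- function(rn) sub("\\|[12]$", "", rn)

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "sim_cohort: %d cases + %d controls, %d markers on %d chromosomes\n",
    x$config$n_cases, x$config$n_controls, nrow(x$map),
    x$config$n_chromosomes))
  cat(sprintf("  planted span %s:%.0f-%.0f (%d markers), %d carrier(s)\n",
              x$truth$chrom, x$truth$span[1], x$truth$span[2],
              length(x$truth$span_markers), length(x$truth$carriers)))
  invisible(x)
}
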