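# End-to-end orchestration: simulate (or load) -> QC -> haplotype scan ->
# autozygosity -> recessive filter + panel exclusion + region triage ->
# consequence prediction -> population statistics, with a consolidated
# machine-readable report.  Stage outputs are pure functions of (inputs,
# config, seed).

#' Pipeline configuration
#'
#' Nested per-stage configs plus run-level settings.  Unknown keys in
#' config files are errors (fail fast).
#'
#' @param sim a \code{\link{simulation_config}}.
#' @param qc a \code{\link{qc_config}}.
#' @param scan a \code{\link{scan_config}}.
#' @param roh a \code{\link{roh_config}}.
#' @param splice_distance_max deep-intronic deprioritization threshold
#'   (bp).
#' @param out_dir output directory (NULL: nothing is written).
#' @param seed run seed; overrides \code{sim$seed} so one flag reseeds
#'   every stochastic stage.
#' @param skip_stages character vector of stage names to skip (from
#'   "scan", "roh", "consequence", "stats").
#' @param verbose print per-stage progress.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            qc = qc_config(),
                            scan = scan_config(),
                            roh = roh_config(),
                            splice_distance_max = 4000,
                            out_dir = NULL,
                            seed = NULL,
                            skip_stages = character(0),
                            verbose = FALSE) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  bad <- setdiff(skip_stages, c("scan", "roh", "consequence", "stats"))
  if (length(bad) > 0L)
    stopf("unknown stage(s) in skip_stages: %s", paste(bad, collapse = ", "))
  structure(list(sim = sim, qc = qc, scan = scan, roh = roh,
                 splice_distance_max = splice_distance_max,
                 out_dir = out_dir, seed = sim$seed,
                 skip_stages = skip_stages, verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a JSON file
#'
#' Sections (\code{sim}, \code{qc}, \code{scan}, \code{roh}, plus
#' run-level keys) are validated against the constructors' argument
#' lists; unknown keys are errors.
#'
#' @param path JSON config path.
#' @return A \code{\link{pipeline_config}}.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("sim", "qc", "scan", "roh", "splice_distance_max",
             "out_dir", "seed", "skip_stages", "verbose")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L)
    stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  build <- function(section, ctor) {
    args <- raw[[section]] %||% list()
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad) > 0L)
      stopf("unknown key(s) in [%s]: %s", section,
            paste(bad, collapse = ", "))
    do.call(ctor, args)
  }
  pipeline_config(sim = build("sim", simulation_config),
                  qc = build("qc", qc_config),
                  scan = build("scan", scan_config),
                  roh = build("roh", roh_config),
                  splice_distance_max = raw$splice_distance_max %||% 4000,
                  out_dir = raw$out_dir,
                  seed = raw$seed,
                  skip_stages = unlist(raw$skip_stages) %||% character(0),
                  verbose = raw$verbose %||% FALSE)
}

#' Run the full mapping pipeline on a synthetic cohort
#'
#' Executes simulate -> QC -> haplotype scan -> autozygosity -> recessive
#' filter (+ cross-population exclusion + region triage) -> consequence
#' prediction -> population statistics, and assembles a run report.  The
#' final candidate list contains the variants that pass the three-sample
#' compatibility filter, do not segregate in the exclusion panel and are
#' not deprioritized as deep-intronic.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return List of class \code{pipeline_run}: per-stage outputs
#'   (\code{cohort}, \code{qc}, \code{scan}, \code{shared_segment},
#'   \code{exclusion}, \code{candidates_final}, \code{consequence},
#'   \code{stats}), timing, and \code{report} (plain-list summary also
#'   written as JSON when \code{out_dir} is set).
#' @export
run_end_to_end <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  say <- function(...) if (config$verbose) message(sprintf(...))
  timing <- list()
  tick <- function(stage, t) {
    timing[[stage]] <<- round(as.numeric(Sys.time()) - as.numeric(t), 3)
  }

  ## stage: simulate ---------------------------------------------------
  t <- Sys.time()
  cohort <- simulate_population(config$sim)
  say("simulate: %d markers, %d individuals", ncol(cohort$haps),
      nrow(cohort$phenotypes))
  tick("simulate", t)

  ## stage: qc ---------------------------------------------------------
  t <- Sys.time()
  qc <- apply_qc(cohort$haps, cohort$map, cohort$phenotypes, config$qc)
  say("qc: %d markers survive, %d removals", ncol(qc$haps),
      nrow(qc$report))
  tick("qc", t)

  ## stage: haplotype scan ---------------------------------------------
  scan <- NULL
  if (!"scan" %in% config$skip_stages) {
    t <- Sys.time()
    scan <- scan_genome(qc$haps, qc$map, cohort$phenotypes, config$scan)
    say("scan: %d tests, threshold %.3g", scan$n_tests, scan$threshold)
    tick("scan", t)
  }

  ## stage: autozygosity ------------------------------------------------
  shared <- NULL; roh_by_case <- NULL
  if (!"roh" %in% config$skip_stages) {
    t <- Sys.time()
    cases <- cohort$phenotypes$id[cohort$phenotypes$status == "affected"]
    cases <- cases[cases %in% hap_row_ids(rownames(qc$haps))]
    geno <- haps_to_genotypes(qc$haps)
    roh_by_case <- lapply(cases, function(id)
      detect_roh(geno, qc$map, id, config$roh))
    names(roh_by_case) <- cases
    hint <- NULL
    if (!is.null(scan)) {
      top <- scan$results[1L, ]
      hint <- list(chrom = top$chrom, start = 0, end = Inf)
    }
    shared <- shared_case_segment(roh_by_case, region_hint = hint)
    say("roh: shared segment %s:%.0f-%.0f", shared$chrom, shared$start,
        shared$end)
    tick("roh", t)
  }

  ## stage: sequence filter ---------------------------------------------
  t <- Sys.time()
  calls <- simulate_sequence_cohort(config$sim, cohort$truth)
  fixture <- attr(calls, "fixture")
  parts <- split_panel(calls)
  roles <- calls$roles
  cand <- recessive_compatibility_filter(
    parts$study,
    case_ids = roles$sample[roles$role == "case"],
    carrier_ids = roles$sample[roles$role == "carrier"],
    control_ids = roles$sample[roles$role == "control"])
  excl <- cross_population_exclusion(cand, parts$panel)
  triage <- lapply(seq_len(nrow(excl$retained)), function(i)
    classify_variant_region(excl$retained[i, ], fixture$gene,
                            config$splice_distance_max))
  retained <- excl$retained
  retained$region <- vapply(triage, `[[`, character(1), "region")
  retained$priority <- vapply(triage, `[[`, character(1), "priority")
  candidates_final <- retained[retained$priority == "candidate", ,
                               drop = FALSE]
  say("filter: %d compatible, %d after panel, %d final",
      sum(cand$compatible), nrow(excl$retained), nrow(candidates_final))
  tick("filter", t)
  if (nrow(cand[cand$compatible, ]) == 0L)
    stopf("pipeline reached the filter stage with zero candidates")

  ## stage: consequence -------------------------------------------------
  consequence <- NULL
  if (!"consequence" %in% config$skip_stages &&
      nrow(candidates_final) > 0L) {
    t <- Sys.time()
    exonic <- candidates_final[candidates_final$region == "exonic", ,
                               drop = FALSE]
    recs <- lapply(seq_len(nrow(exonic)), function(i)
      apply_variant_and_translate(fixture$gene, fixture$genome,
                                  as.list(exonic[i, ])))
    ri <- retained_intron_translate(
      fixture$gene, fixture$genome,
      fixture$info$spec$retained_intron_index,
      upstream_variant = if (nrow(exonic) > 0L) as.list(exonic[1L, ]))
    wt_tx <- splice_transcript(fixture$gene, fixture$genome)
    pcr <- insilico_rtpcr(list(spliced = wt_tx,
                               intron_retained = ri$transcript),
                          fixture$info$forward_primer,
                          fixture$info$reverse_primer)
    consequence <- list(records = recs, intron_retention = ri$record,
                        rtpcr = pcr)
    tick("consequence", t)
  }

  ## stage: population stats ---------------------------------------------
  stats <- NULL
  if (!"stats" %in% config$skip_stages && !is.null(shared) &&
      !shared$empty) {
    t <- Sys.time()
    seg_markers <- qc$map$marker[qc$map$chrom == shared$chrom &
                                 qc$map$pos >= shared$start &
                                 qc$map$pos <= shared$end]
    founder <- cohort$truth$founder_hap[
      match(seg_markers, cohort$truth$span_markers)]
    keep <- !is.na(founder)
    seg_markers <- seg_markers[keep]; founder <- founder[keep]
    hstat <- haplotype_status(qc$haps, seg_markers, founder)
    vgeno <- genotype_validation_cohort(cohort)
    ids <- intersect(names(hstat), names(vgeno))
    ct <- genotype_haplotype_crosstab(vgeno[ids], hstat[ids])
    ph <- cohort$phenotypes[match(ids, cohort$phenotypes$id), ]
    ctrl <- ph$status == "unaffected"
    carr <- haplotype_carrier_stats(qc$haps, seg_markers, founder,
                                    cohort$phenotypes)
    trend <- frequency_trend(hstat[ids][ctrl], ph$birth_year[ctrl],
                             ph$sex[ctrl])
    # LD between the causal variant and the segment haplotype, on phased
    # copies: variant allele imputed from per-individual dosage phase-
    # consistently with the haplotype (carrier copy carries the alt)
    sub <- qc$haps[, match(seg_markers, colnames(qc$haps)), drop = FALSE]
    eq <- sub == rep(founder, each = nrow(sub))
    rs <- rowSums(eq)
    hap_copy <- ifelse(is.na(rs), NA_integer_,
                       as.integer(rs == length(seg_markers)))
    ind_of_copy <- hap_individuals(qc$haps)
    var_copy <- integer(length(hap_copy))
    for (i in seq_along(hap_copy)) {
      dd <- vgeno[ind_of_copy[i]]
      var_copy[i] <- if (is.na(dd)) NA_integer_
        else if (dd == 2L) 1L else if (dd == 0L) 0L else hap_copy[i]
    }
    r2 <- suppressWarnings(ld_r2(hap_copy, var_copy))
    stats <- list(crosstab = ct, carrier = carr, trend = trend, r2 = r2)
    tick("stats", t)
  }

  report <- list(
    seed = config$seed,
    n_markers_post_qc = ncol(qc$haps),
    n_tests = if (!is.null(scan)) scan$n_tests else NA,
    bonferroni_threshold = if (!is.null(scan)) scan$threshold else NA,
    n_significant_windows = if (!is.null(scan))
      sum(scan$results$significant) else NA,
    top_window = if (!is.null(scan)) as.list(
      scan$results[1L, c("chrom", "window_start_bp", "window_end_bp",
                         "log10p")]) else NULL,
    shared_segment = if (!is.null(shared)) list(
      chrom = shared$chrom, start = shared$start, end = shared$end,
      empty = shared$empty) else NULL,
    n_compatible = sum(cand$compatible),
    n_after_panel = nrow(excl$retained),
    candidates_final = candidates_final$id,
    causal_in_final = fixture$info$deletion$id %in% candidates_final$id,
    consequence = if (!is.null(consequence) &&
                      length(consequence$records) > 0L) list(
      protein_hgvs = consequence$records[[1L]]$protein_hgvs,
      mutant_length = consequence$records[[1L]]$mutant_length,
      residues_removed = consequence$records[[1L]]$residues_removed,
      intron_retention_stop =
        consequence$intron_retention$stop_residue,
      rtpcr_spliced = consequence$rtpcr$spliced,
      rtpcr_intron_retained = consequence$rtpcr$intron_retained) else NULL,
    stats = if (!is.null(stats)) list(
      discordant = stats$crosstab$discordant,
      carrier_frequency = stats$carrier$frequency,
      r2 = stats$r2) else NULL,
    timing_s = timing)

  run <- structure(list(cohort = cohort, qc = qc, scan = scan,
                        roh_by_case = roh_by_case,
                        shared_segment = shared, calls = calls,
                        candidates = cand, exclusion = excl,
                        candidates_final = candidates_final,
                        consequence = consequence, stats = stats,
                        fixture = fixture, report = report,
                        config = config),
                   class = "pipeline_run")
  if (!is.null(config$out_dir)) write_pipeline_outputs(run, config$out_dir)
  say("done in %.1f s", as.numeric(Sys.time()) - as.numeric(t0))
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("pipeline_run (seed %d)\n", r$seed))
  cat(sprintf("  scan: %s tests, %s significant\n", r$n_tests,
              r$n_significant_windows))
  if (!is.null(r$shared_segment))
    cat(sprintf("  shared segment: %s:%.0f-%.0f\n",
                r$shared_segment$chrom, r$shared_segment$start,
                r$shared_segment$end))
  cat(sprintf("  candidates: %d compatible -> %d after panel -> final: %s\n",
              r$n_compatible, r$n_after_panel,
              paste(r$candidates_final, collapse = ", ")))
  invisible(x)
}

write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_hap_tsv(run$cohort$haps, p("haplotypes.tsv"))
  write_map_tsv(run$cohort$map, p("markers.tsv"))
  write_pheno_tsv(run$cohort$phenotypes, p("phenotypes.tsv"))
  write_truth_json(run$cohort$truth, p("truth.json"))
  write_qc_report(run$qc, p("qc_report.tsv"))
  if (!is.null(run$scan))
    write_scan_results(run$scan, p("scan.tsv"), p("scan_significant.bed"))
  if (!is.null(run$shared_segment) && !run$shared_segment$empty)
    write_bed(data.frame(chrom = run$shared_segment$chrom,
                         start = run$shared_segment$start,
                         end = run$shared_segment$end,
                         name = "shared_segment"),
              p("shared_segment.bed"))
  write_vcf(run$calls, p("cohort.vcf"))
  write_gff3(run$fixture$gene, p("gene_fixture.gff3"))
  write_fasta(run$fixture$genome, p("gene_fixture.fa"))
  ct <- candidate_table(run$exclusion)
  write.table(ct, p("candidates.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(run$report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(out_dir)
}
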