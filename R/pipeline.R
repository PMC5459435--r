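#' Pipeline configuration
#'
#' Assembles every tunable of the end-to-end run: either a simulation
#' config (fixtures are generated and, when `out_dir` is set, written) or
#' a fixture directory produced by [write_fixtures()].
#'
#' @param sim `simulation_config` used when `fixture_dir` is NULL.
#' @param fixture_dir Optional directory of an existing fixture bundle.
#' @param out_dir Optional output directory for report TSVs.
#' @param window_width Grid width in bp.
#' @param dhmr `dhmr_params` for the exact test.
#' @param promoter_upstream,tts_width Annotation region widths in bp.
#' @param metagene_upstream,metagene_downstream,metagene_bin Metagene
#'   profile extent and bin width in bp.
#' @param saturation_steps Subset steps of the saturation curve.
#' @param seed Seed for the pipeline's own randomness (saturation split).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            fixture_dir = NULL,
                            out_dir = NULL,
                            window_width = 100L,
                            dhmr = dhmr_params(),
                            promoter_upstream = 2000L,
                            tts_width = 1000L,
                            metagene_upstream = 2500L,
                            metagene_downstream = 500L,
                            metagene_bin = 500L,
                            saturation_steps = 10L,
                            seed = 1L) {
  if (!is.null(fixture_dir) && !dir.exists(fixture_dir)) {
    stop(sprintf("fixture directory '%s' does not exist", fixture_dir))
  }
  structure(list(sim = sim, fixture_dir = fixture_dir, out_dir = out_dir,
                 window_width = as.integer(window_width), dhmr = dhmr,
                 promoter_upstream = as.integer(promoter_upstream),
                 tts_width = as.integer(tts_width),
                 metagene_upstream = as.integer(metagene_upstream),
                 metagene_downstream = as.integer(metagene_downstream),
                 metagene_bin = as.integer(metagene_bin),
                 saturation_steps = as.integer(saturation_steps),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Flat keys mirror the [pipeline_config()] arguments; `sim:` and `dhmr:`
#' sections map onto [simulation_config()] and [dhmr_params()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$chrom_sizes)) {
    sim_args$chrom_sizes <- unlist(sim_args$chrom_sizes)
  }
  for (nm in c("gene_part_lengths", "repeat_fraction")) {
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  }
  args <- y[setdiff(names(y), c("sim", "dhmr"))]
  args$sim <- do.call(simulation_config, sim_args)
  args$dhmr <- do.call(dhmr_params, y$dhmr %||% list())
  do.call(pipeline_config, args)
}

#' Compare called DhMRs with the planted truth
#'
#' A planted window is recovered when a called DhMR covers exactly that
#' grid window. Direction accuracy is evaluated over recovered windows.
#'
#' @param dhmrs DhMR data.frame from [call_dhmrs()].
#' @param truth Planted-signal `GRanges` (with `direction`).
#' @return List: n_truth, n_recovered, recall, direction_accuracy,
#'   n_false_calls (called windows not planted).
#' @export
evaluate_recovery <- function(dhmrs, truth) {
  if (length(truth) == 0L) {
    return(list(n_truth = 0L, n_recovered = 0L, recall = NA_real_,
                direction_accuracy = NA_real_, n_false_calls = nrow(dhmrs)))
  }
  key_truth <- paste(as.character(GenomicRanges::seqnames(truth)),
                     GenomicRanges::start(truth))
  key_call <- paste(dhmrs$chrom, dhmrs$start)
  m <- match(key_truth, key_call)
  rec <- !is.na(m)
  dir_ok <- truth$direction[rec] == dhmrs$direction[m[rec]]
  list(n_truth = length(truth),
       n_recovered = sum(rec),
       recall = mean(rec),
       direction_accuracy = if (any(rec)) mean(dir_ok) else NA_real_,
       n_false_calls = sum(!key_call %in% key_truth))
}

#' Run the full windowed 5hmC analysis
#'
#' simulate (or load) -> count -> QC -> coverage profiles -> DhMR calling
#' -> annotation -> gene-set enrichment, with internal consistency checks
#' (hyper + hypo = total DhMR count; affected-gene union arithmetic).
#' Deterministic for a fixed config.
#'
#' @param config `pipeline_config`.
#' @return A `hmedip_report` list with blocks `qc`, `coverage`, `dhmr`,
#'   `annotation`, `enrichment` (plus `recovery` when a truth table is
#'   available) and the `inputs` used.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$fixture_dir)) {
    genome <- build_toy_genome(config$sim)
    signal <- plant_dhmr_signals(genome, config$sim)
    reads_c <- simulate_reads(genome, signal, config$sim, "control")
    reads_e <- simulate_reads(genome, signal, config$sim, "exposed")
    if (!is.null(config$out_dir)) {
      write_fixtures(genome, signal, reads_c, reads_e,
                     file.path(config$out_dir, "fixtures"))
    }
    data <- list(chrom_sizes = genome$chrom_sizes, genes = genome$genes,
                 parts = genome$parts, cgis = genome$cgis,
                 repeats = genome$repeats, cpg = genome$cpg,
                 gene_sets = genome$gene_sets, imprinted = genome$imprinted,
                 truth = signal, reads_control = reads_c,
                 reads_exposed = reads_e)
  } else {
    data <- read_fixture_bundle(config$fixture_dir)
  }
  grid <- make_windows(data$chrom_sizes, config$window_width)
  tc <- count_reads(grid, data$reads_control)
  te <- count_reads(grid, data$reads_exposed)
  rc <- to_rpkm(tc, grid)
  re <- to_rpkm(te, grid)
  cov_c <- covered_windows(tc)
  cov_e <- covered_windows(te)

  qc <- list(
    saturation_control = saturation_analysis(data$reads_control, grid,
                                             config$saturation_steps,
                                             seed = config$seed),
    saturation_exposed = saturation_analysis(data$reads_exposed, grid,
                                             config$saturation_steps,
                                             seed = config$seed + 1L),
    cpg_enrichment_control = cpg_enrichment_score(data$reads_control,
                                                  data$cpg,
                                                  data$chrom_sizes),
    cpg_enrichment_exposed = cpg_enrichment_score(data$reads_exposed,
                                                  data$cpg,
                                                  data$chrom_sizes),
    cpg_coverage_control = cpg_coverage_fraction(data$reads_control,
                                                 data$cpg),
    cpg_coverage_exposed = cpg_coverage_fraction(data$reads_exposed,
                                                 data$cpg),
    library_total_control = tc$library_total,
    library_total_exposed = te$library_total)

  chrom_c <- coverage_by_chromosome(cov_c, grid, data$chrom_sizes)
  chrom_e <- coverage_by_chromosome(cov_e, grid, data$chrom_sizes)
  promoters <- build_promoters(data$genes, data$chrom_sizes,
                               config$promoter_upstream)
  features <- build_feature_index(data$genes, data$parts, data$chrom_sizes,
                                  config$promoter_upstream, config$tts_width)
  part_ratio <- function(cov) {
    rows <- lapply(names(features), function(f) {
      gr <- features[[f]]
      if (length(gr) == 0L) return(NULL)
      coverage_ratio(cov, grid, gr, name = f)
    })
    do.call(rbind, rows)
  }
  repeat_capture <- function(cov) {
    do.call(rbind, lapply(sort(unique(data$repeats$class)), function(cl) {
      cap <- element_capture(cov, grid, data$repeats[data$repeats$class == cl])
      data.frame(class = cl, n_captured = cap$n_captured,
                 n_total = cap$n_total, fraction = cap$fraction)
    }))
  }
  cgi_c <- element_capture(cov_c, grid, data$cgis)
  cgi_e <- element_capture(cov_e, grid, data$cgis)
  prom_c <- promoter_rpkm_summary(rc, cov_c, promoters, grid)
  prom_e <- promoter_rpkm_summary(re, cov_e, promoters, grid)
  metagene <- metagene_profile(re, grid, data$genes,
                               gene_sets = data$gene_sets[c("expressed",
                                                            "repressed")],
                               upstream = config$metagene_upstream,
                               downstream = config$metagene_downstream,
                               bin = config$metagene_bin)
  coverage <- list(
    per_chromosome = coverage_increase_ratio(chrom_c, chrom_e),
    gene_parts_control = part_ratio(cov_c),
    gene_parts_exposed = part_ratio(cov_e),
    cpg_strata_control = cpg_density_strata(grid, data$cpg, cov_c, rc),
    cpg_strata_exposed = cpg_density_strata(grid, data$cpg, cov_e, re),
    cgi_capture = data.frame(condition = c("control", "exposed"),
                             n_captured = c(cgi_c$n_captured,
                                            cgi_e$n_captured),
                             n_total = c(cgi_c$n_total, cgi_e$n_total),
                             fraction = c(cgi_c$fraction, cgi_e$fraction)),
    promoters = data.frame(condition = c("control", "exposed"),
                           n_covered = c(prom_c$n_covered, prom_e$n_covered),
                           n_total = c(prom_c$n_promoters,
                                       prom_e$n_promoters),
                           fraction = c(prom_c$fraction, prom_e$fraction),
                           mean_rpkm = c(prom_c$mean_rpkm,
                                         prom_e$mean_rpkm)),
    repeats_control = repeat_capture(cov_c),
    repeats_exposed = repeat_capture(cov_e),
    metagene = metagene$profiles)

  dhmrs <- call_dhmrs(tc, te, grid, config$dhmr)
  dhmr_block <- list(
    table = dhmrs,
    n_total = nrow(dhmrs),
    n_hyper = sum(dhmrs$direction == "hyper"),
    n_hypo = sum(dhmrs$direction == "hypo"),
    n_tested = attr(dhmrs, "n_tested"),
    mean_rpkm_control = if (nrow(dhmrs)) mean(dhmrs$rpkm_control) else NA_real_,
    mean_rpkm_case = if (nrow(dhmrs)) mean(dhmrs$rpkm_case) else NA_real_)

  assignments <- assign_primary_feature(dhmrs, features)
  gene_table <- dhmrs_to_genes(dhmrs, data$genes, promoters)
  gcounts <- attr(gene_table, "counts")
  imprinted_flags <- if (!is.null(data$imprinted)) {
    flag_imprinted_promoters(dhmrs, promoters, data$imprinted)
  } else NULL
  annotation <- list(
    feature_distribution = as.data.frame(table(
      feature = assignments$primary_feature)),
    assignments = assignments,
    gene_table = gene_table,
    n_hyper_genes = gcounts$n_hyper,
    n_hypo_genes = gcounts$n_hypo,
    n_affected_genes = gcounts$n_union,
    imprinted_flags = imprinted_flags,
    repeat_classes = dhmr_repeat_classes(dhmrs, data$repeats))

  enrichment <- NULL
  if (length(data$gene_sets)) {
    enrichment <- overlap_report(gene_table$gene_id, data$gene_sets,
                                 universe = data$genes$gene_id)
  }

  recovery <- if (!is.null(data$truth)) evaluate_recovery(dhmrs, data$truth)

  # internal consistency: fail loudly rather than emit a wrong report
  stopifnot(dhmr_block$n_hyper + dhmr_block$n_hypo == dhmr_block$n_total)
  stopifnot(gcounts$n_union ==
              length(union(gene_table$gene_id[gene_table$hyper],
                           gene_table$gene_id[gene_table$hypo])))
  stopifnot(nrow(assignments) == dhmr_block$n_total)
  strata_sum <- sum(coverage$cpg_strata_control$n_windows)
  stopifnot(strata_sum == length(grid))

  report <- structure(list(qc = qc, coverage = coverage, dhmr = dhmr_block,
                           annotation = annotation, enrichment = enrichment,
                           recovery = recovery,
                           inputs = list(config = config,
                                         n_windows = length(grid))),
                      class = "hmedip_report")
  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
  }
  report
}

#' Write the tabular blocks of a run report as TSV files
#'
#' @param report `hmedip_report` from [run_pipeline()].
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    wr(report$qc$saturation_control$curve, "qc_saturation_control.tsv"),
    wr(report$qc$saturation_exposed$curve, "qc_saturation_exposed.tsv"),
    wr(report$coverage$per_chromosome, "coverage_per_chromosome.tsv"),
    wr(report$coverage$gene_parts_control, "coverage_gene_parts_control.tsv"),
    wr(report$coverage$gene_parts_exposed, "coverage_gene_parts_exposed.tsv"),
    wr(report$coverage$cpg_strata_control, "cpg_strata_control.tsv"),
    wr(report$coverage$cpg_strata_exposed, "cpg_strata_exposed.tsv"),
    wr(report$coverage$cgi_capture, "cgi_capture.tsv"),
    wr(report$coverage$promoters, "promoter_summary.tsv"),
    wr(report$coverage$repeats_control, "repeat_capture_control.tsv"),
    wr(report$coverage$repeats_exposed, "repeat_capture_exposed.tsv"),
    wr(report$coverage$metagene, "metagene_profiles.tsv"),
    wr(report$dhmr$table, "dhmrs.tsv"),
    wr(report$annotation$assignments, "dhmr_features.tsv"),
    wr(report$annotation$gene_table, "dhmr_genes.tsv"),
    wr(report$annotation$repeat_classes, "dhmr_repeat_classes.tsv"))
  if (!is.null(report$annotation$imprinted_flags)) {
    paths <- c(paths, wr(report$annotation$imprinted_flags,
                         "imprinted_flags.tsv"))
  }
  if (!is.null(report$enrichment)) {
    paths <- c(paths, wr(report$enrichment, "geneset_enrichment.tsv"))
  }
  qc_df <- data.frame(
    metric = c("saturation_estimated_control", "saturation_estimated_exposed",
               "saturation_truncated_control", "saturation_truncated_exposed",
               "cpg_enrichment_control", "cpg_enrichment_exposed",
               "cpg_coverage_control", "cpg_coverage_exposed",
               "library_total_control", "library_total_exposed"),
    value = c(report$qc$saturation_control$estimated,
              report$qc$saturation_exposed$estimated,
              report$qc$saturation_control$truncated,
              report$qc$saturation_exposed$truncated,
              report$qc$cpg_enrichment_control,
              report$qc$cpg_enrichment_exposed,
              report$qc$cpg_coverage_control,
              report$qc$cpg_coverage_exposed,
              report$qc$library_total_control,
              report$qc$library_total_exposed))
  paths <- c(paths, wr(qc_df, "qc_summary.tsv"))
  invisible(paths)
}

#' @export
print.hmedip_report <- function(x, ...) {
  genome_row <- x$coverage$per_chromosome[
    x$coverage$per_chromosome$target == "genome", ]
  cat("<hmedip_report>\n")
  cat(sprintf("  windows: %d; reads: %d control / %d exposed\n",
              x$inputs$n_windows, x$qc$library_total_control,
              x$qc$library_total_exposed))
  cat(sprintf("  genome covered: %.1f%% control / %.1f%% exposed\n",
              100 * genome_row$ratio_control, 100 * genome_row$ratio_case))
  cat(sprintf("  QC: saturation %.3f/%.3f, CpG enrichment %.3f/%.3f\n",
              x$qc$saturation_control$estimated,
              x$qc$saturation_exposed$estimated,
              x$qc$cpg_enrichment_control, x$qc$cpg_enrichment_exposed))
  cat(sprintf("  DhMRs: %d (%d hyper, %d hypo) of %d tested windows\n",
              x$dhmr$n_total, x$dhmr$n_hyper, x$dhmr$n_hypo, x$dhmr$n_tested))
  cat(sprintf("  affected genes: %d (%d hyper, %d hypo)\n",
              x$annotation$n_affected_genes, x$annotation$n_hyper_genes,
              x$annotation$n_hypo_genes))
  if (!is.null(x$recovery) && !is.na(x$recovery$recall)) {
    cat(sprintf("  planted-signal recall: %.1f%% (direction accuracy %.1f%%)\n",
                100 * x$recovery$recall, 100 * x$recovery$direction_accuracy))
  }
  invisible(x)
}
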