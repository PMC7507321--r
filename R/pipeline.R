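# End-to-end pipeline driver: simulate -> detect -> editing -> stats -> mir,
# with a run manifest recording configuration, checksums and exclusions.

#' Pipeline configuration
#'
#' One object holding every stage's parameters. Unknown arguments are
#' rejected, so typos cannot silently fall back to defaults.
#'
#' @param seed Master seed for the run.
#' @param outdir Output directory.
#' @param genome [genome_config()] for the simulated genome.
#' @param n_per_cell,regions,conditions Cohort layout (see
#'   [cohort_samples()]).
#' @param circ_effects,editing_effects,age_slope,age_slope_region,couple_editing
#'   Cohort effects (see [cohort_design()]).
#' @param editing_rate Uniform per-site editing rate for the simulation.
#' @param n_reads,read_len,error_rate,premrna_fraction Read simulation
#'   parameters.
#' @param anchor_len,min_support,max_span,require_gt_ag Detection parameters.
#' @param min_detected,qc_unit Sample QC threshold and its unit.
#' @param tissue_min_reads Per-tissue expression threshold.
#' @param aei_windows,aei_min_coverage,aei_subtract_exons Editing-index
#'   parameters.
#' @param de_method,fdr Statistics parameters.
#' @param mir_min_sites Seed-site report threshold.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            outdir = tempfile("circnigra_run_"),
                            genome = genome_config(
                              chrom_len = 60000L, n_genes = 12L),
                            n_per_cell = 3L,
                            regions = c("SN", "MTG"),
                            conditions = c("CT", "PD"),
                            circ_effects = c(CT = 1, PD = 1.4),
                            editing_effects = c(CT = 1, PD = 0.7),
                            age_slope = 0,
                            age_slope_region = "SN",
                            couple_editing = FALSE,
                            editing_rate = 0.05,
                            n_reads = 15000L,
                            read_len = 100L,
                            error_rate = 0.002,
                            premrna_fraction = 0.08,
                            anchor_len = 20L,
                            min_support = 2L,
                            max_span = 100000L,
                            require_gt_ag = TRUE,
                            min_detected = 5L,
                            qc_unit = "junctions",
                            tissue_min_reads = 5L,
                            aei_windows = c(1000L, 5000L, 10000L),
                            aei_min_coverage = 1L,
                            aei_subtract_exons = TRUE,
                            de_method = "t",
                            fdr = 0.05,
                            mir_min_sites = 3L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
}

#' Run the full pipeline on a seeded simulated cohort
#'
#' Chains the stages in dependency order: simulate a genome and cohort with
#' ground truth, detect and filter back-splice junctions, compute regional
#' editing indices per sample, run cohort statistics (totals, group
#' comparison, age and editing correlations, differential test), and scan
#' detected circles for miR-128 seed sites. Every filter decision is
#' logged; outputs are TSV files under `config$outdir` plus a manifest with
#' configuration hash and file checksums.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `manifest`, `genome`,
#'   `truth`, `counts` (filtered `circ_counts`), `totals`, `aei`,
#'   `group_tests`, `correlations`, `de`, `mir_sites`, `files`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  ## simulate
  sim <- run_stage("simulate", {
    genome <- build_genome(config$genome, seed = config$seed)
    editing <- editing_model(genome, rate = config$editing_rate)
    design <- cohort_design(
      cohort_samples(config$n_per_cell, config$regions, config$conditions,
                     seed = config$seed),
      circ_effects = config$circ_effects,
      editing_effects = config$editing_effects,
      age_slope = config$age_slope,
      age_slope_region = config$age_slope_region,
      couple_editing = config$couple_editing,
      seed = config$seed)
    cohort <- simulate_cohort(
      genome, design, editing = editing, n_reads = config$n_reads,
      read_len = config$read_len, error_rate = config$error_rate,
      premrna_fraction = config$premrna_fraction,
      outdir = file.path(config$outdir, "reads"))
    list(genome = genome, editing = editing, design = design,
         cohort = cohort)
  })
  inform(sprintf("simulate: %d samples, %d true junctions",
                 nrow(sim$design$samples),
                 dplyr::n_distinct(sim$cohort$truth_junctions$junction_id)))

  ## detect
  counts <- run_stage("detect", {
    params <- detect_params(anchor_len = config$anchor_len,
                            max_span = config$max_span,
                            require_gt_ag = config$require_gt_ag)
    raw <- call_junctions(
      setNames(sim$cohort$samples$fastq, sim$cohort$samples$sample_id),
      sim$genome, params = params, min_support = config$min_support,
      meta = sim$design$samples)
    qc <- qc_filter_samples(raw, min_detected = config$min_detected,
                            unit = config$qc_unit)
    filter_by_tissue(qc, min_reads = config$tissue_min_reads)
  })
  inform(sprintf("detect: %d junctions retained over %d samples",
                 nrow(counts$junctions), length(sample_names(counts))))
  counts_tsv <- file.path(config$outdir, "junction_counts.tsv")
  write_junction_tsv(counts, counts_tsv)

  ## editing index
  aei <- run_stage("aei", {
    purrr::map_dfr(seq_len(nrow(sim$cohort$samples)), function(i) {
      regional_editing_report(
        sim$cohort$samples$sam[i], sim$genome, counts$junctions,
        windows = config$aei_windows,
        min_coverage = config$aei_min_coverage,
        subtract_exons = config$aei_subtract_exons) |>
        mutate(sample_id = sim$cohort$samples$sample_id[i])
    })
  })
  aei_tsv <- file.path(config$outdir, "editing_index.tsv")
  readr::write_tsv(aei, aei_tsv)

  ## statistics
  stats_out <- run_stage("stats", {
    totals <- circ_totals_per_sample(counts, mode = "reads",
                                     normalized = TRUE)
    gt <- purrr::map_dfr(unique(totals$region), function(rg) {
      d <- filter(totals, .data$region == rg)
      cond <- sort(unique(d$condition))
      if (length(cond) != 2) return(NULL)
      two_group_test(d$total[d$condition == cond[1]],
                     d$total[d$condition == cond[2]],
                     method = "t", group_a = cond[1], group_b = cond[2],
                     feature = rg)
    })
    if (nrow(gt) > 0) gt$q_value <- bh_adjust(gt$p_value)
    age_cor <- totals |>
      group_by(.data$region, .data$condition) |>
      dplyr::group_modify(function(d, key) {
        if (nrow(d) < 3) return(tibble())
        pearson_correlation(d$age, d$total)
      }) |>
      ungroup()
    aei_global <- aei |>
      filter(.data$region_label == "global", .data$mismatch == "A>G") |>
      select("sample_id", "index_percent")
    joined <- inner_join(totals, aei_global, by = "sample_id")
    edit_cor <- pearson_correlation(joined$index_percent, joined$total)
    de <- simple_de(counts, grouping = "condition",
                    method = config$de_method)
    list(totals = totals, group_tests = gt, age_cor = age_cor,
         edit_cor = edit_cor, de = de)
  })
  readr::write_tsv(stats_out$totals,
                   file.path(config$outdir, "circ_totals.tsv"))
  readr::write_tsv(stats_out$de, file.path(config$outdir, "simple_de.tsv"))

  ## miRNA seed sites on detected circles
  mir_sites <- run_stage("mir", {
    mir <- mir128_record()
    purrr::map_dfr(seq_len(nrow(counts$junctions)), function(i) {
      jn <- counts$junctions[i, ]
      cs <- subseq0(sim$genome$chromosomes[[jn$chrom]], jn$start, jn$end)
      if (jn$strand == "-") cs <- revcomp(cs)
      tibble(junction_id = jn$junction_id,
             n_mir128_sites = nrow(scan_seed_sites(cs, mir)))
    })
  })
  readr::write_tsv(mir_sites, file.path(config$outdir, "mir128_sites.tsv"))

  files <- c(counts = counts_tsv, aei = aei_tsv,
             totals = file.path(config$outdir, "circ_totals.tsv"),
             de = file.path(config$outdir, "simple_de.tsv"),
             mir = file.path(config$outdir, "mir128_sites.tsv"))
  cfg_for_hash <- unclass(config)
  cfg_for_hash$outdir <- NULL   # paths are run-local, not part of identity
  manifest <- list(
    config_hash = rlang::hash(cfg_for_hash),
    config = unclass(config),
    excluded_samples = attr(counts, "excluded_samples") %||% character(),
    checksums = tools::md5sum(unname(files)),
    n_junctions = nrow(counts$junctions),
    created = format(Sys.time(), tz = "UTC")
  )
  structure(list(manifest = manifest, genome = sim$genome,
                 truth = sim$cohort[c("truth_junctions", "truth_editing")],
                 counts = counts, totals = stats_out$totals,
                 aei = aei, group_tests = stats_out$group_tests,
                 correlations = list(age = stats_out$age_cor,
                                     editing = stats_out$edit_cor),
                 de = stats_out$de, mir_sites = mir_sites, files = files),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d junctions, %d samples; outputs in %s\n",
    nrow(x$counts$junctions), length(sample_names(x$counts)),
    dirname(x$files[["counts"]])))
  invisible(x)
}
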