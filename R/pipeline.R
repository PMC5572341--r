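#' Pipeline configuration
#'
#' One structured object holding every tunable of the end-to-end analysis.
#' All defaults are the thresholds used throughout cattle SNP-array CNV work:
#' LRR SD at most 0.30, wave factor at most 0.05, BAF drift at most 0.002,
#' minimum 3 probes per call, V_st above 0.35 over at least 3 consecutive
#' probes. Configurations round-trip through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param signal,calls,meta Optional input paths (signal TSV, `.rawcnv`
#'   calls, sample metadata TSV). When all three are `NULL` the pipeline
#'   simulates a cohort instead.
#' @param genes,segdups Optional BED paths for gene and segmental-duplication
#'   interval sets.
#' @param ref_cnvrs Optional named list of BED paths with published CNVR sets.
#' @param lrr_sd_max,baf_drift_max,wave_factor_max Sample QC thresholds.
#' @param min_probes Minimum probes per CNV call.
#' @param vst_threshold,vst_min_probes Differentiation scan parameters.
#' @param vst_groups Optional character vector of length 2 naming the group
#'   pair to scan; `NULL` scans all pairs with at least 2 samples each.
#' @param outlier_n_sd,outlier_min_breed_size Burden outlier-removal knobs.
#' @param sim Named list of overrides passed to [sim_config()] when
#'   simulating.
#' @param seed Integer seed driving simulation and any randomized step.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(signal = NULL, calls = NULL, meta = NULL,
                            genes = NULL, segdups = NULL, ref_cnvrs = NULL,
                            lrr_sd_max = 0.30, baf_drift_max = 0.002,
                            wave_factor_max = 0.05, min_probes = 3L,
                            vst_threshold = 0.35, vst_min_probes = 3L,
                            vst_groups = NULL, outlier_n_sd = 3,
                            outlier_min_breed_size = 5L,
                            sim = list(), seed = 1L) {
  cfg <- structure(
    list(
      input = list(signal = signal, calls = calls, meta = meta,
                   genes = genes, segdups = segdups, ref_cnvrs = ref_cnvrs),
      qc = list(lrr_sd_max = lrr_sd_max, baf_drift_max = baf_drift_max,
                wave_factor_max = wave_factor_max),
      min_probes = as.integer(min_probes),
      vst = list(threshold = vst_threshold,
                 min_probes = as.integer(vst_min_probes),
                 groups = vst_groups),
      outlier = list(n_sd = outlier_n_sd,
                     min_breed_size = as.integer(outlier_min_breed_size)),
      sim = sim,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
  validate_pipeline_config(cfg)
}

#' @rdname pipeline_config
#' @param cfg A candidate configuration.
#' @export
validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  q <- cfg$qc
  if (q$lrr_sd_max <= 0 || q$baf_drift_max < 0 || q$wave_factor_max < 0) {
    stop("QC thresholds must be positive")
  }
  if (cfg$min_probes < 1L) stop("min_probes must be >= 1")
  if (cfg$vst$threshold < 0 || cfg$vst$threshold > 1) {
    stop("vst threshold must lie in [0, 1]")
  }
  if (cfg$vst$min_probes < 1L) stop("vst min_probes must be >= 1")
  if (!is.null(cfg$vst$groups) && length(cfg$vst$groups) != 2L) {
    stop("vst_groups must name exactly two groups")
  }
  if (cfg$outlier$n_sd <= 0) stop("outlier_n_sd must be positive")
  given <- !vapply(cfg$input[c("signal", "calls", "meta")], is.null, logical(1L))
  if (any(given) && !all(given)) {
    stop("supply signal, calls and meta together, or none (to simulate)")
  }
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  cfg <- validate_pipeline_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(structure(yaml::read_yaml(path),
                                     class = "pipeline_config"))
}

stage_input <- function(stage, path) {
  if (is.null(path) || !file.exists(path)) {
    stop("stage '", stage, "': missing input file: ",
         if (is.null(path)) "<not configured>" else path)
  }
  path
}

#' Run the full CNV population analysis pipeline
#'
#' Runs all stages in dependency order and writes every stage artifact plus a
#' JSON run manifest into `out_dir`: cohort files (when simulating), QC report,
#' PFB track, filtered calls, singleton partition, per-sample burden with
#' outlier screen and group tests, CNVRs (TSV and BED), overlap reports
#' against any configured reference sets, V_st tracks with differentiated
#' runs and sex-artifact flags, and the UPGMA tree in Newick format. Rerunning
#' with the same configuration and seed reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_pipeline_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(
    package = as.character(utils::packageVersion("cnvherd")),
    seed = config$seed,
    stages = list(),
    inputs = list(),
    outputs = list()
  )
  set.seed(config$seed)
  out <- function(name) file.path(out_dir, name)

  # --- stage: inputs (simulate or load) -------------------------------------
  simulate <- is.null(config$input$signal)
  if (simulate) {
    sim_args <- config$sim
    sim_args$seed <- config$seed
    cohort <- simulate_cohort(do.call(sim_config, sim_args))
    write_cohort(cohort, out_dir)
    signal <- cohort$signal
    calls <- cohort$truth
    meta <- cohort$meta
    manifest$stages$simulate <- list(
      n_samples = nrow(meta), n_probes = nrow(signal$probes),
      n_truth_calls = nrow(calls)
    )
  } else {
    signal <- read_signal_tsv(stage_input("load", config$input$signal))
    calls <- read_rawcnv(stage_input("load", config$input$calls))
    meta <- read_sample_meta(stage_input("load", config$input$meta))
    manifest$inputs <- lapply(
      Filter(Negate(is.null), config$input[c("signal", "calls", "meta")]),
      function(p) unname(tools::md5sum(p))
    )
    manifest$stages$load <- list(
      n_samples = nrow(meta), n_probes = nrow(signal$probes),
      n_calls = nrow(calls)
    )
  }
  genes <- if (!is.null(config$input$genes)) {
    read_bed(stage_input("annotate", config$input$genes))
  }
  segdups <- if (!is.null(config$input$segdups)) {
    filter_segdups(read_bed(stage_input("annotate", config$input$segdups)))
  }

  # --- stage: qc ------------------------------------------------------------
  qc <- sample_qc(signal, lrr_sd_max = config$qc$lrr_sd_max,
                  baf_drift_max = config$qc$baf_drift_max,
                  wave_factor_max = config$qc$wave_factor_max)
  utils::write.table(qc, out("qc.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  keep <- qc$sample_id[qc$pass]
  if (length(keep) < 2L) stop("stage 'qc': fewer than 2 samples pass QC")
  manifest$stages$qc <- list(n_pass = length(keep),
                             n_fail = sum(!qc$pass))

  # --- stage: pfb + gc adjustment --------------------------------------------
  write_pfb_tsv(signal, out("pfb.tsv"))
  adj <- if ("gc" %in% names(signal$probes)) gc_adjust_lrr(signal) else signal
  manifest$stages$pfb <- list(n_probes = nrow(signal$probes),
                              gc_adjusted = "gc" %in% names(signal$probes))

  # --- stage: filter calls ----------------------------------------------------
  calls <- calls[calls$sample_id %in% keep, , drop = FALSE]
  calls <- filter_calls(calls, min_probes = config$min_probes)
  write_rawcnv(calls, out("calls_filtered.rawcnv"))
  manifest$stages$filter <- list(n_calls = nrow(calls))

  # --- stage: singletons ------------------------------------------------------
  parts <- identify_singletons(calls)
  manifest$stages$singletons <- list(
    n_singletons = nrow(parts$singletons), n_shared = nrow(parts$shared)
  )

  # --- stage: burden + group tests -------------------------------------------
  meta_keep <- meta[meta$sample_id %in% keep, , drop = FALSE]
  burdens <- per_sample_burden(calls, genes = genes, samples = keep)
  utils::write.table(burdens, out("burdens.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  retained <- remove_outlier_samples(
    burdens, meta_keep[c("sample_id", "breed")],
    n_sd = config$outlier$n_sd,
    min_breed_size = config$outlier$min_breed_size
  )
  burdens_in <- burdens[burdens$sample_id %in% retained, , drop = FALSE]
  grp <- stats::setNames(meta_keep$group, meta_keep$sample_id)[retained]
  tests <- NULL
  if (length(unique(grp)) >= 2L && all(table(grp) >= 2L)) {
    tests <- group_burden_tests(burdens_in, grp)
    jsonlite::write_json(
      list(overall = tests$overall, pairwise = tests$pairwise),
      out("group_tests.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  manifest$stages$burden <- list(
    n_samples = nrow(burdens), n_outliers_removed = nrow(burdens) - length(retained),
    group_tests_run = !is.null(tests)
  )

  # --- stage: cnvr ------------------------------------------------------------
  regions <- build_cnvrs(calls, n_samples_cohort = length(keep))
  write_cnvr_tsv(regions$cnvrs, out("cnvr.tsv"))
  write_cnvr_bed(regions$cnvrs, out("cnvr.bed"))
  manifest$stages$cnvr <- list(
    n_cnvrs = nrow(regions$cnvrs),
    n_singleton_components = nrow(regions$singletons),
    by_class = as.list(table(regions$cnvrs$klass))
  )

  # --- stage: compare reference sets -----------------------------------------
  if (!is.null(config$input$ref_cnvrs) && length(config$input$ref_cnvrs) > 0L) {
    refs <- lapply(config$input$ref_cnvrs,
                   function(p) read_bed(stage_input("compare-refs", p)))
    cmp <- compare_with_reference_sets(regions$cnvrs, refs)
    utils::write.table(cmp$reports, out("overlap_reports.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(cmp$novel, out("novel_cnvrs.txt"))
    manifest$stages$compare_refs <- list(
      n_sets = nrow(cmp$reports), n_novel = length(cmp$novel)
    )
  }
  if (!is.null(segdups)) {
    sd_hits <- annotate_intervals(regions$cnvrs, segdups)
    utils::write.table(sd_hits, out("segdup_hits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$stages$segdups <- list(
      n_cnvrs_hit = length(unique(sd_hits$cnvr_id))
    )
  }

  # --- stage: vst -------------------------------------------------------------
  grp_all <- stats::setNames(meta_keep$group, meta_keep$sample_id)
  grp_sizes <- table(grp_all)
  pairs <- if (!is.null(config$vst$groups)) {
    list(config$vst$groups)
  } else {
    eligible <- names(grp_sizes)[grp_sizes >= 2L]
    if (length(eligible) >= 2L) utils::combn(sort(eligible), 2L, simplify = FALSE)
    else list()
  }
  all_runs <- list()
  for (pr in pairs) {
    a <- names(grp_all)[grp_all == pr[1L]]
    b <- names(grp_all)[grp_all == pr[2L]]
    vst <- per_probe_vst(adj$lrr, a, b)
    tag <- paste0(pr[1L], "_vs_", pr[2L])
    write_vst_tsv(vst, adj$probes, out(paste0("vst_", tag, ".tsv")))
    runs <- scan_differentiated_runs(vst, adj$probes,
                                     threshold = config$vst$threshold,
                                     min_probes = config$vst$min_probes)
    runs <- map_runs_to_cnvs(runs, regions$cnvrs)
    runs <- sex_artifact_filter(runs, adj$lrr, meta_keep)
    runs$group_pair <- if (nrow(runs) > 0L) tag else character()
    all_runs[[tag]] <- runs
  }
  runs_flat <- do.call(rbind, lapply(all_runs, function(r) {
    if (nrow(r) == 0L) return(NULL)
    r$contained_in <- vapply(r$contained_in, paste, character(1L), collapse = ",")
    r
  }))
  if (is.null(runs_flat)) {
    runs_flat <- data.frame(
      chrom = integer(), first_probe = integer(), last_probe = integer(),
      start = integer(), end = integer(), n_probes = integer(),
      min_vst = numeric(), contained_in = character(), sex_p_raw = numeric(),
      sex_p_bonferroni = numeric(), sex_artifact = logical(),
      group_pair = character(), stringsAsFactors = FALSE
    )
  }
  utils::write.table(runs_flat, out("vst_runs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest$stages$vst <- list(
    n_pairs = length(pairs), n_runs = nrow(runs_flat),
    n_sex_artifacts = sum(runs_flat$sex_artifact %in% TRUE)
  )

  # --- stage: cluster ---------------------------------------------------------
  if (nrow(regions$cnvrs) > 0L && length(keep) >= 2L) {
    bm <- binary_cnvr_matrix(regions$cnvrs, keep)
    utils::write.table(bm, out("binary_matrix.tsv"), sep = "\t", quote = FALSE)
    tree <- upgma(jaccard_distance_matrix(bm))
    write_newick(tree, out("tree.nwk"))
    manifest$stages$cluster <- list(n_leaves = length(tree$labels))
  }

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest$outputs <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
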