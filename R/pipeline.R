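#' Configuration of an end-to-end scenario run
#'
#' Bundles everything [run_pipeline()] needs: the synthetic genome
#' configuration, the retention model of the case and control conditions,
#' sequencing coverage, and the analysis parameters (significance level,
#' coverage gate, density window, first-peak bounds). One master seed
#' deterministically derives every per-stage seed via [derive_seed()].
#'
#' @param scenario free-text scenario name recorded in the outputs.
#' @param sim an [simulation_config()].
#' @param case_model,control_model lists with element `model` (a model name
#'   accepted by [assign_retention()]) plus its parameters, e.g.
#'   `list(model = "feature_logistic", b0 = -4, b_len = 3, b_dens = 0.5)`.
#' @param case_label,control_label distinct condition labels.
#' @param coverage sequencing depth (fold) for both conditions.
#' @param alpha,min_reads significance level and coverage gate for
#'   [test_retention()].
#' @param window neighbor-density window, bp.
#' @param first_peak first size-peak interval, bp.
#' @param max_class top-coding bound for density classes.
#' @param case_replicates number of independent case read sets (>= 2 enables
#'   replicate overlap and correlation).
#' @param seed master seed.
#' @param write_reads also write the simulated FASTQ files (off by default;
#'   they are the largest outputs and the pipeline consumes reads in
#'   memory).
#' @return a list of class `ies_pipeline_config`.
#' @export
pipeline_config <- function(scenario = "knockdown",
                            sim = simulation_config(),
                            case_model = list(model = "all_retained"),
                            control_model = list(model = "none_retained"),
                            case_label = "case", control_label = "control",
                            coverage = 30, alpha = 0.05, min_reads = 10,
                            window = 1000, first_peak = c(26, 30),
                            max_class = 8, case_replicates = 1,
                            seed = 1, write_reads = FALSE) {
  if (identical(case_label, control_label))
    stop("case and control labels must be distinct", call. = FALSE)
  stopifnot(inherits(sim, "ies_sim_config"), .is_count(seed),
            .is_count(case_replicates), case_replicates >= 1)
  structure(list(scenario = scenario, sim = sim, case_model = case_model,
                 control_model = control_model, case_label = case_label,
                 control_label = control_label, coverage = coverage,
                 alpha = alpha, min_reads = min_reads, window = window,
                 first_peak = first_peak, max_class = max_class,
                 case_replicates = as.integer(case_replicates),
                 seed = as.integer(seed), write_reads = isTRUE(write_reads)),
            class = "ies_pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

.model_retention <- function(spec, annotations, profile, rng_seed) {
  do.call(assign_retention,
          c(list(annotations = annotations, densities = profile,
                 rng_seed = rng_seed), spec))
}

#' Run a whole simulate-score-test-enrich scenario
#'
#' Executes the full analysis on synthetic data: generate a MAC/germline
#' genome pair, assign per-IES retention truths for the case and control
#' conditions, simulate paired-end reads from the old/new MAC mixture, count
#' IES+/IES- junction-spanning pairs and score every IES, call significantly
#' retained IESs against the control, and characterize the retained set
#' (density enrichment, length peaks, matched random samples, and - with
#' replicates - overlap and Spearman correlation). All outputs are written to
#' `out_dir` as commented TSV/FASTA/GFF3/YAML, and the run is byte-for-byte
#' reproducible from the configuration alone.
#'
#' @param config an [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a summary list: per-condition mean apparent IRS,
#'   number of significant IESs, the enrichment table, first-peak fractions,
#'   matched-sample diagnostics and (with replicates) overlap/correlation.
#' @export
run_pipeline <- function(config, out_dir = tempfile("iesret_run_")) {
  stopifnot(inherits(config, "ies_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  hash <- config_hash(unclass(config))
  meta <- list(scenario = config$scenario, config_hash = hash, seed = seed)

  sim <- config$sim
  sim$rng_seed <- derive_seed(seed, "genome")
  genome <- .stage("simulate_genome", generate_genome_pair(sim))
  profile <- .stage("density", neighbor_density(genome$annotations,
                                                config$window))

  truth_case <- .stage("truth", simulation_truth(
    .model_retention(config$case_model, genome$annotations, profile,
                     derive_seed(seed, "truth_case")), sim$rho))
  truth_ctrl <- .stage("truth", simulation_truth(
    .model_retention(config$control_model, genome$annotations, profile,
                     derive_seed(seed, "truth_control")), sim$rho))

  library <- .stage("junction_library", build_junction_library(
    genome$mac, genome$germline, genome$annotations,
    flank_k = sim$read_length, min_overlap = 10))

  score_condition <- function(truth, label, stage_seed) {
    reads <- simulate_read_pairs(genome, truth, config$coverage,
                                 rng_seed = stage_seed)
    if (config$write_reads)
      write_fastq_pair(reads, file.path(out_dir, paste0("reads_", label)))
    count_and_score(reads, library, condition = label)
  }
  case_scores <- vector("list", config$case_replicates)
  for (i in seq_len(config$case_replicates))
    case_scores[[i]] <- .stage("score_case", score_condition(
      truth_case, sprintf("%s_rep%d", config$case_label, i),
      derive_seed(seed, sprintf("reads_case_%d", i))))
  ctrl_scores <- .stage("score_control", score_condition(
    truth_ctrl, config$control_label, derive_seed(seed, "reads_control")))

  tests <- .stage("test", lapply(case_scores, test_retention,
                                 control = ctrl_scores,
                                 alpha = config$alpha,
                                 min_reads = config$min_reads))
  retained <- lapply(tests, function(tt)
    tt$ies_id[!is.na(tt$significant) & tt$significant])

  ann <- genome$annotations
  enr <- .stage("enrich", enrichment_index(retained[[1]], ann, profile,
                                           config$max_class))
  ls_ret <- length_stats(ann$length[ann$ies_id %in% retained[[1]]],
                         config$first_peak)
  ls_univ <- length_stats(ann$length, config$first_peak)

  samples <- overlap <- correlation <- NULL
  if (length(retained[[1]])) {
    samples <- .stage("sample", list(
      density = matched_random_sample(ann, retained[[1]], "density",
                                      profile,
                                      derive_seed(seed, "sample_density")),
      length = matched_random_sample(ann, retained[[1]], "length",
                                     rng_seed = derive_seed(seed,
                                                            "sample_length"))))
  }
  if (config$case_replicates >= 2L) {
    overlap <- .stage("overlap", set_overlap(retained[[1]], retained[[2]]))
    correlation <- .stage("correlation", replicate_correlation(
      setNames(case_scores[[1]]$irs, case_scores[[1]]$ies_id),
      setNames(case_scores[[2]]$irs, case_scores[[2]]$ies_id)))
  }

  .stage("write_outputs", {
    write_genome_fasta(genome$mac, file.path(out_dir, "mac.fasta"))
    write_genome_fasta(genome$germline, file.path(out_dir, "germline.fasta"))
    write_ies_gff3(ann, file.path(out_dir, "ies.gff3"), meta = meta)
    write_config_yaml(config, file.path(out_dir, "config.yaml"))
    write_truth_tsv(truth_case, ann, profile,
                    file.path(out_dir, "truth_case.tsv"), meta = meta)
    write_truth_tsv(truth_ctrl, ann, profile,
                    file.path(out_dir, "truth_control.tsv"), meta = meta)
    for (i in seq_along(case_scores))
      write_tsv(case_scores[[i]],
                file.path(out_dir, sprintf("scores_%s_rep%d.tsv",
                                           config$case_label, i)), meta)
    write_tsv(ctrl_scores,
              file.path(out_dir, sprintf("scores_%s.tsv",
                                         config$control_label)), meta)
    write_tsv(tests[[1]], file.path(out_dir, "retention_test.tsv"), meta)
    write_tsv(enr, file.path(out_dir, "enrichment.tsv"), meta)
    if (!is.null(samples)) {
      writeLines(samples$density$ids,
                 file.path(out_dir, "sample_density_matched.ids"))
      writeLines(samples$length$ids,
                 file.path(out_dir, "sample_length_matched.ids"))
    }
  })

  summary <- list(
    scenario = config$scenario, config_hash = hash, seed = seed,
    n_ies = nrow(ann),
    mean_irs_case = mean(case_scores[[1]]$irs, na.rm = TRUE),
    mean_irs_control = mean(ctrl_scores$irs, na.rm = TRUE),
    n_tested = sum(tests[[1]]$tested),
    n_significant = length(retained[[1]]),
    frac_significant_tested =
      length(retained[[1]]) / max(1L, sum(tests[[1]]$tested)),
    peak_fraction_retained = ls_ret$peak_fraction,
    peak_fraction_universe = ls_univ$peak_fraction,
    top_class_enrichment_index =
      enr$enrichment_index[nrow(enr)],
    overlap_frac_a = if (is.null(overlap)) NA_real_ else overlap$frac_a,
    replicate_spearman = if (is.null(correlation)) NA_real_ else
      correlation$rho)
  sm <- data.frame(key = names(summary),
                   value = vapply(summary, function(v)
                     paste(format(v, digits = 15), collapse = ","),
                     character(1)))
  write_tsv(sm, file.path(out_dir, "summary.tsv"), meta)
  writeLines(c(.meta_header(meta),
               sprintf("# stages seeded from master seed %d via derive_seed()",
                       seed)),
             file.path(out_dir, "run_info.txt"))

  invisible(c(summary,
              list(tests = tests, enrichment = enr, retained = retained,
                   samples = samples, overlap = overlap,
                   correlation = correlation, annotations = ann,
                   profile = profile, case_scores = case_scores,
                   control_scores = ctrl_scores, out_dir = out_dir)))
}
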