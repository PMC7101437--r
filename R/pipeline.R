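#' Configuration for an end-to-end benchmark run
#'
#' Bundles the simulation settings, the analysis thresholds and the
#' batch-layout scenario of one reproducible pipeline run.
#'
#' @param simulation A [simulation_config()]; its seed is overridden by
#'   `seed`.
#' @param scenario Batch layout, see [simulate_paired_cohort()].
#' @param min_mean_tpm Cross-panel gene filter for matching (strict
#'   `>`), default 0.5.
#' @param detection_tpm Detection threshold for QC counting, default 1.
#' @param pca_tpm Mean/median TPM filter for PCA (inclusive), default 1.
#' @param outlier_z Robust z cutoff for outlier exclusion, default
#'   -2.5.
#' @param max_rounds Matching rounds, default 2.
#' @param min_total_counts Optional minimum library size; pairs with a
#'   shallower library are dropped before analysis (QC mirror of
#'   removing failed libraries). Default 0 = off.
#' @param output_dir Directory for all written artifacts.
#' @param seed Integer master seed of the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            scenario = c("dataset1", "dataset2",
                                         "cross_machine"),
                            min_mean_tpm = 0.5,
                            detection_tpm = 1.0,
                            pca_tpm = 1.0,
                            outlier_z = -2.5,
                            max_rounds = 2L,
                            min_total_counts = 0,
                            output_dir = tempfile("globinmatch_run_"),
                            seed = 1L) {
  scenario <- match.arg(scenario)
  if (min_mean_tpm < 0 || detection_tpm < 0 || pca_tpm < 0) {
    stop("thresholds must be >= 0")
  }
  simulation$seed <- as.integer(seed)
  structure(
    list(simulation = simulation, scenario = scenario,
         min_mean_tpm = min_mean_tpm, detection_tpm = detection_tpm,
         pca_tpm = pca_tpm, outlier_z = outlier_z,
         max_rounds = as.integer(max_rounds),
         min_total_counts = min_total_counts,
         output_dir = output_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the simulate - quantify - match - PCA pipeline
#'
#' Executes the full benchmark on one simulated cohort: generate the
#' paired count data for the configured scenario, write the interchange
#' files, compute per-sample QC and group comparisons, run the scaled
#' Spearman matching with outlier exclusion, and decompose the
#' (globin-free) TPM matrix by PCA. All artifacts are written under
#' `config$output_dir` and listed, with MD5 checksums, in a JSON run
#' manifest. Given the same config and seed the run is fully
#' deterministic.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `manifest` (also written
#'   as `manifest.json`), `cohort`, `qc`, `qc_comparisons`,
#'   `match` (a `match_report`), `pca` (a `pca_result`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  stages_done <- character(0)
  files <- character(0)
  add_file <- function(p) files <<- c(files, p)

  on.exit({
    manifest <- list(
      package_version = as.character(packageVersion("globinmatch")),
      seed = config$seed,
      scenario = config$scenario,
      started = started,
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      stages_completed = stages_done,
      config = strip_classes(config),
      files = lapply(stats::setNames(files, basename(files)),
                     function(p) list(path = basename(p),
                                      md5 = unname(tools::md5sum(p))))
    )
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  # --- simulate ------------------------------------------------------
  cohort <- simulate_paired_cohort(config$simulation, config$scenario)
  if (config$min_total_counts > 0) {
    shallow <- colnames(cohort$counts)[
      colSums(cohort$counts) < config$min_total_counts]
    if (length(shallow)) {
      bad <- cohort$truth$gb_sample %in% shallow |
        cohort$truth$nogb_sample %in% shallow
      drop <- c(cohort$truth$gb_sample[bad], cohort$truth$nogb_sample[bad])
      cohort$counts <- cohort$counts[, !colnames(cohort$counts) %in% drop,
                                     drop = FALSE]
      cohort$samples <- cohort$samples[
        !cohort$samples$sample_id %in% drop, , drop = FALSE]
      cohort$truth <- cohort$truth[!bad, , drop = FALSE]
      if (!nrow(cohort$truth)) {
        stop("all sample pairs removed by the min_total_counts filter")
      }
    }
  }
  add_file(write_count_matrix(cohort$counts, out("counts.tsv")))
  add_file(write_gene_table(cohort$genes, out("genes.tsv")))
  add_file(write_sample_sheet(cohort$samples, out("samples.tsv")))
  add_file(write_pairing(cohort$truth, out("pairing.tsv")))
  add_file(write_config(config, out("config.yaml")))
  stages_done <- c(stages_done, "simulate")

  # --- quantify ------------------------------------------------------
  qc <- qc_summary(cohort$counts, cohort$genes, cohort$samples,
                   detection_tpm = config$detection_tpm)
  gb_ids <- cohort$samples$sample_id[cohort$samples$protocol == "GB"]
  nogb_ids <- cohort$samples$sample_id[cohort$samples$protocol == "noGB"]
  qc_cmp <- if (length(gb_ids) >= 2 && length(nogb_ids) >= 2) {
    do.call(rbind, lapply(
      c("total_counts", "globin_fraction", "n_detected"),
      function(metric) {
        group_metric_report(qc[[metric]][match(gb_ids, qc$sample_id)],
                            qc[[metric]][match(nogb_ids, qc$sample_id)],
                            metric = metric)
      }))
  } else {
    # group t-tests need >= 2 libraries per protocol
    data.frame(metric = character(0))
  }
  write.table(qc, out("qc_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  add_file(out("qc_summary.tsv"))
  write.table(qc_cmp, out("qc_comparisons.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  add_file(out("qc_comparisons.tsv"))
  stages_done <- c(stages_done, "quantify")

  # --- match ---------------------------------------------------------
  counts_gb <- cohort$counts[, gb_ids, drop = FALSE]
  counts_nogb <- cohort$counts[, nogb_ids, drop = FALSE]
  match <- iterative_matching(counts_nogb, counts_gb, cohort$genes,
                              cohort$truth,
                              max_rounds = config$max_rounds,
                              min_mean_tpm = config$min_mean_tpm,
                              outlier_z = config$outlier_z)
  write.table(match$assignments, out("match_assignments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  add_file(out("match_assignments.tsv"))
  jsonlite::write_json(
    list(rounds = match$rounds, n_pairs = match$n_pairs,
         n_correct = match$n_correct, accuracy = match$accuracy,
         accuracy_post_exclusion = match$accuracy_post_exclusion,
         excluded_outliers = match$excluded_outliers),
    out("match_report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  add_file(out("match_report.json"))
  stages_done <- c(stages_done, "match")

  # --- pca -----------------------------------------------------------
  tpm <- compute_tpm(cohort$counts, cohort$genes)
  pca <- run_pca(tpm, genes = pca_gene_filter(tpm, config$pca_tpm),
                 gene_table = cohort$genes, exclude_globin = TRUE)
  var_tab <- data.frame(pc = seq_along(pca$variance_explained),
                        variance_explained = pca$variance_explained)
  write.table(var_tab, out("pca_variance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  add_file(out("pca_variance.tsv"))
  scores <- data.frame(sample_id = rownames(pca$scores),
                       pca$scores[, seq_len(min(3, ncol(pca$scores))),
                                  drop = FALSE],
                       check.names = FALSE)
  write.table(scores, out("pca_scores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  add_file(out("pca_scores.tsv"))
  n_pc <- min(3, ncol(pca$loadings))
  top <- do.call(rbind, lapply(seq_len(n_pc), function(pc) {
    ids <- top_loading_genes(result = pca, pc = pc,
                             k = min(100L, length(pca$genes_used)))
    data.frame(pc = pc, rank = seq_along(ids), gene_id = ids,
               stringsAsFactors = FALSE)
  }))
  write.table(top, out("pca_top_loadings.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  add_file(out("pca_top_loadings.tsv"))
  stages_done <- c(stages_done, "pca")

  structure(
    list(cohort = cohort, qc = qc, qc_comparisons = qc_cmp,
         match = match, pca = pca, output_dir = config$output_dir),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result in", x$output_dir, "\n")
  print(x$match)
  ve <- x$pca$variance_explained
  cat(sprintf("  PC1-3 variance explained: %.1f%%\n",
              100 * sum(ve[seq_len(min(3, length(ve)))])))
  invisible(x)
}
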