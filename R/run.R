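# Directory-level workflow wrappers: simulate -> test -> report, each
# writing plain-text outputs with provenance (tool version, parameters,
# seeds) so a run can be reproduced exactly.

provenance_header <- function(seed = NULL) {
  v <- as.character(utils::packageVersion("meripdiff"))
  paste0("# meripdiff ", v,
         if (!is.null(seed)) paste0("; seed=", seed) else "")
}

write_tsv_with_header <- function(tbl, path, seed = NULL) {
  writeLines(provenance_header(seed), path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Simulate an experiment and write a fixture directory
#'
#' Writes `peak_counts.tsv`, `gene_counts.tsv`, `sample_sheet.tsv`,
#' `peaks.bed`, `peak_gene_map.tsv`, `truth_peaks.tsv`,
#' `truth_genes.tsv`, optionally `sequences.fa` and `coverage.tsv`, plus
#' `provenance.json`. All tables carry a `#`-prefixed provenance header
#' recording the package version and seed; re-running with the same
#' config reproduces the files byte for byte.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory.
#' @param force Overwrite an existing directory.
#' @param sequences Also write planted-motif sequences and coverage
#'   tracks (slower; default `FALSE`).
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(config, out_dir, force = FALSE,
                         sequences = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
    stop("output directory exists; use force = TRUE to overwrite",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_experiment(config)
  exp <- sim$experiment
  sd <- config$seed

  write_tsv_with_header(exp$peak_counts, file.path(out_dir, "peak_counts.tsv"), sd)
  write_tsv_with_header(exp$gene_counts, file.path(out_dir, "gene_counts.tsv"), sd)
  write_tsv_with_header(exp$samples, file.path(out_dir, "sample_sheet.tsv"), sd)
  write_tsv_with_header(sim$peak_truth, file.path(out_dir, "truth_peaks.tsv"), sd)
  write_tsv_with_header(sim$gene_truth, file.path(out_dir, "truth_genes.tsv"), sd)
  write_tsv_with_header(exp$peaks[c("peak_id", "gene_id")],
                        file.path(out_dir, "peak_gene_map.tsv"), sd)

  bed <- exp$peaks
  bed_lines <- c(provenance_header(sd),
                 sprintf("%s\t%d\t%d\t%s\t0\t%s", bed$chrom, bed$start,
                         bed$end, bed$peak_id, bed$strand))
  writeLines(bed_lines, file.path(out_dir, "peaks.bed"))

  if (sequences) {
    sc <- simulate_sequences_and_coverage(sim, seed = config$seed)
    fa <- unlist(lapply(seq_len(nrow(sc$sequences)), function(i) {
      c(paste0(">", sc$sequences$gene_id[i], " start=",
               sc$sequences$gene_start[i]), sc$sequences$seq[i])
    }))
    writeLines(fa, file.path(out_dir, "sequences.fa"))
    write_tsv_with_header(sc$coverage, file.path(out_dir, "coverage.tsv"), sd)
  }

  jsonlite::write_json(
    list(tool = "meripdiff",
         version = as.character(utils::packageVersion("meripdiff")),
         subcommand = "simulate",
         config = config[setdiff(names(config), "")]),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the differential-methylation pipeline on a fixture directory
#'
#' Reads the tables written by [run_simulate()] (or equivalently shaped
#' user data), runs [diffmeth()] and writes one GLM result TSV per
#' variant, the combined calls TSV, a BED of peaks passing all filters,
#' and `provenance.json`.
#'
#' @param input_dir Directory holding `peak_counts.tsv`,
#'   `gene_counts.tsv`, `sample_sheet.tsv`, `peaks.bed`,
#'   `peak_gene_map.tsv`.
#' @param out_dir Output directory.
#' @param force Overwrite an existing directory.
#' @inheritParams diffmeth
#' @return The `merip_diffmeth` object, invisibly.
#' @export
run_diffmeth <- function(input_dir, out_dir, force = FALSE,
                         variants = c("trend_shrink", "common_tagwise"),
                         alpha = 0.05, combine = "union",
                         min_delta = 1, min_count = 10) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
    stop("output directory exists; use force = TRUE to overwrite",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  exp <- read_experiment(
    file.path(input_dir, "peak_counts.tsv"),
    file.path(input_dir, "gene_counts.tsv"),
    file.path(input_dir, "sample_sheet.tsv"),
    file.path(input_dir, "peaks.bed"),
    file.path(input_dir, "peak_gene_map.tsv"))
  fit <- diffmeth(exp, variants = variants, alpha = alpha,
                  combine = combine, min_delta = min_delta,
                  min_count = min_count)
  for (v in names(fit$results)) {
    write_tsv_with_header(fit$results[[v]],
                          file.path(out_dir, paste0("glm_", v, ".tsv")))
  }
  write_tsv_with_header(fit$calls, file.path(out_dir, "calls.tsv"))
  passing <- fit$calls$peak_id[fit$calls$passes_filters]
  if (length(passing)) {
    pk <- exp$peaks[exp$peaks$peak_id %in% passing, ]
    v1 <- names(fit$results)[1]
    pk$fdr <- fit$results[[v1]]$fdr[match(pk$peak_id,
                                          fit$results[[v1]]$peak_id)]
    write_results(pk, file.path(out_dir, "passing_peaks.bed"),
                  format = "bed")
  }
  jsonlite::write_json(
    list(tool = "meripdiff",
         version = as.character(utils::packageVersion("meripdiff")),
         subcommand = "test", input_dir = input_dir,
         params = fit$params),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' Summarize a results directory
#'
#' Recounts significant peaks per variant plus the union, intersect and
#' filtered sets from the written tables, and optionally saves a p-value
#' histogram.
#'
#' @param results_dir Directory written by [run_diffmeth()].
#' @param plot_file Optional path for a p-value histogram (PDF).
#' @return Summary tibble with one row per category (`variant:<name>`,
#'   `union`, `intersect`, `passing_filters`) and a peak count.
#' @export
run_report <- function(results_dir, plot_file = NULL) {
  calls_path <- file.path(results_dir, "calls.tsv")
  if (!file.exists(calls_path)) {
    stop("missing component in results dir: calls.tsv", call. = FALSE)
  }
  calls <- readr::read_tsv(calls_path, comment = "#",
                           show_col_types = FALSE)
  glm_files <- list.files(results_dir, pattern = "^glm_.*\\.tsv$",
                          full.names = TRUE)
  if (!length(glm_files)) {
    stop("missing component in results dir: glm_<variant>.tsv",
         call. = FALSE)
  }
  results <- lapply(glm_files, readr::read_tsv, comment = "#",
                    show_col_types = FALSE)
  names(results) <- sub("^glm_(.*)\\.tsv$", "\\1", basename(glm_files))
  prov <- jsonlite::read_json(file.path(results_dir, "provenance.json"))
  alpha <- prov$params$alpha %||% 0.05

  rows <- lapply(names(results), function(v) {
    tibble::tibble(category = paste0("variant:", v),
                   n_peaks = sum(!is.na(results[[v]]$fdr) &
                                   results[[v]]$fdr < alpha))
  })
  summary <- dplyr::bind_rows(rows) |>
    dplyr::bind_rows(tibble::tibble(
      category = c("union", "intersect", "passing_filters"),
      n_peaks = c(length(combine_calls(results, "union", alpha)),
                  length(combine_calls(results, "intersect", alpha)),
                  sum(calls$passes_filters))))
  if (!is.null(plot_file)) {
    fitlike <- list(results = results)
    p <- plot_pvalue_histogram(fitlike)
    ggplot2::ggsave(plot_file, p, width = 6, height = 3)
  }
  summary
}

`%||%` <- function(a, b) if (is.null(a)) b else a
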