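#' Construct a MeRIP-seq count experiment
#'
#' Bundles per-peak and per-gene read-count tables with peak intervals and a
#' sample sheet into a single validated object, the input to the differential
#' methylation pipeline. Counts are stored as tibbles whose first column is
#' the feature id (`peak_id` / `gene_id`) and whose remaining columns are
#' samples, in the order of the sample sheet.
#'
#' @param peak_counts Tibble of non-negative integer counts, first column
#'   `peak_id`, one column per sample.
#' @param gene_counts Tibble of non-negative integer counts, first column
#'   `gene_id`, one column per sample.
#' @param peaks Tibble of peak intervals with columns `chrom`, `start`
#'   (0-based, inclusive), `end` (exclusive), `strand` (one of `+`, `-`,
#'   `.`), `peak_id`, `gene_id`.
#' @param samples Sample sheet tibble with columns `sample_id`, `fraction`
#'   (`"IP"` or `"input"`), `condition` (`"treated"` or `"control"`),
#'   `replicate` (integer), and optionally `library_size` (positive real;
#'   defaults to the column sum of `peak_counts`).
#'
#' @return An object of class `merip_experiment`: a list with elements
#'   `peak_counts`, `gene_counts`, `peaks`, `samples`.
#'
#' @details
#' Validation enforces the design the statistical model requires: each
#' (fraction, condition, replicate) triple is unique, every IP library has a
#' paired input library with the same condition and replicate, every peak
#' maps to exactly one gene present in `gene_counts`, and all counts are
#' integer-valued and non-negative. Coordinates follow the BED convention
#' (0-based, half-open) throughout.
#'
#' @examples
#' sim <- simulate_experiment(simulation_config(n_genes = 5, seed = 1))
#' sim$experiment
#' @export
merip_experiment <- function(peak_counts, gene_counts, peaks, samples) {
  peak_counts <- tibble::as_tibble(peak_counts)
  gene_counts <- tibble::as_tibble(gene_counts)
  peaks <- tibble::as_tibble(peaks)
  samples <- tibble::as_tibble(samples)

  samples <- validate_sample_sheet(samples)
  validate_peaks(peaks)

  if (names(peak_counts)[1] != "peak_id") {
    stop("first column of `peak_counts` must be `peak_id`", call. = FALSE)
  }
  if (names(gene_counts)[1] != "gene_id") {
    stop("first column of `gene_counts` must be `gene_id`", call. = FALSE)
  }

  for (tbl_name in c("peak_counts", "gene_counts")) {
    tbl <- get(tbl_name)
    ids <- setdiff(names(tbl)[-1], samples$sample_id)
    missing <- setdiff(samples$sample_id, names(tbl)[-1])
    if (length(ids) || length(missing)) {
      stop(
        "sample mismatch in `", tbl_name, "`: ",
        if (length(ids)) paste0("not in sheet: ", toString(ids), "; ") else "",
        if (length(missing)) paste0("missing from table: ", toString(missing)) else "",
        call. = FALSE
      )
    }
    m <- as.matrix(tbl[-1])
    if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
      stop("`", tbl_name, "` must contain non-negative integer counts",
           call. = FALSE)
    }
  }

  # column order follows the sample sheet
  peak_counts <- peak_counts[c("peak_id", samples$sample_id)]
  gene_counts <- gene_counts[c("gene_id", samples$sample_id)]

  if (anyDuplicated(peak_counts$peak_id)) {
    stop("duplicated peak_id in `peak_counts`", call. = FALSE)
  }
  if (anyDuplicated(gene_counts$gene_id)) {
    stop("duplicated gene_id in `gene_counts`", call. = FALSE)
  }
  if (!setequal(peaks$peak_id, peak_counts$peak_id)) {
    stop("`peaks` and `peak_counts` disagree on peak ids", call. = FALSE)
  }
  orphan <- setdiff(peaks$gene_id, gene_counts$gene_id)
  if (length(orphan)) {
    stop("peaks assigned to genes absent from `gene_counts`: ",
         toString(utils::head(orphan, 5)), call. = FALSE)
  }

  if (!"library_size" %in% names(samples)) {
    samples$library_size <- colSums(as.matrix(peak_counts[-1]))
  }
  zero <- samples$sample_id[samples$library_size == 0]
  if (length(zero)) {
    warning("library_size is 0 for sample(s): ", toString(zero), call. = FALSE)
  }

  structure(
    list(peak_counts = peak_counts, gene_counts = gene_counts,
         peaks = peaks, samples = samples),
    class = "merip_experiment"
  )
}

validate_sample_sheet <- function(samples) {
  req <- c("sample_id", "fraction", "condition", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    stop("sample sheet missing column(s): ", toString(miss), call. = FALSE)
  }
  if (!all(samples$fraction %in% c("IP", "input"))) {
    stop("`fraction` must be 'IP' or 'input'", call. = FALSE)
  }
  if (!all(samples$condition %in% c("treated", "control"))) {
    stop("`condition` must be 'treated' or 'control'", call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id", call. = FALSE)
  }
  key <- paste(samples$fraction, samples$condition, samples$replicate)
  if (anyDuplicated(key)) {
    stop("duplicated (fraction, condition, replicate) triple", call. = FALSE)
  }
  ip <- samples[samples$fraction == "IP", ]
  inp <- samples[samples$fraction == "input", ]
  unpaired <- !paste(ip$condition, ip$replicate) %in%
    paste(inp$condition, inp$replicate)
  if (any(unpaired)) {
    stop("IP sample(s) without a matching input library: ",
         toString(ip$sample_id[unpaired]), call. = FALSE)
  }
  samples$replicate <- as.integer(samples$replicate)
  samples
}

validate_peaks <- function(peaks) {
  req <- c("chrom", "start", "end", "strand", "peak_id")
  miss <- setdiff(req, names(peaks))
  if (length(miss)) {
    stop("peak table missing column(s): ", toString(miss), call. = FALSE)
  }
  if (any(peaks$start < 0)) stop("peak start must be >= 0", call. = FALSE)
  if (any(peaks$end <= peaks$start)) {
    stop("peak end must exceed start (0-based half-open intervals)",
         call. = FALSE)
  }
  if (!all(peaks$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  }
  if (anyDuplicated(peaks$peak_id)) {
    stop("duplicated peak_id in peak set", call. = FALSE)
  }
  invisible(peaks)
}

#' @export
print.merip_experiment <- function(x, ...) {
  s <- x$samples
  cat("<merip_experiment>\n")
  cat("  peaks:  ", nrow(x$peak_counts), " x ", nrow(s), " samples\n", sep = "")
  cat("  genes:  ", nrow(x$gene_counts), "\n", sep = "")
  cat("  design: ", sep = "")
  tab <- table(s$fraction, s$condition)
  cat(paste(sprintf("%s/%s: %d", rownames(tab)[row(tab)],
                    colnames(tab)[col(tab)], tab), collapse = ", "), "\n")
  invisible(x)
}

# counts as a numeric matrix, features in rows, samples in sheet order
count_matrix <- function(tbl) {
  m <- as.matrix(tbl[-1])
  rownames(m) <- tbl[[1]]
  storage.mode(m) <- "double"
  m
}
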