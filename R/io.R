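#' Read peak intervals from a BED file
#'
#' Reads BED3 or BED6 peak intervals, preserving the BED convention of
#' 0-based half-open coordinates. Lines starting with `#`, `track` or
#' `browser` are skipped.
#'
#' @param path Path to a BED file.
#' @param dialect `"bed6"` (chrom, start, end, name, score, strand) or
#'   `"bed3"` (chrom, start, end).
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `peak_id`, `gene_id` (`NA` until assigned), in file order. Peaks whose
#'   BED name field is `"."` or empty get generated ids `peak_<n>`.
#' @seealso [assign_peaks_to_genes()] to fill `gene_id`.
#' @export
read_peaks <- function(path, dialect = c("bed6", "bed3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lines <- lines[keep]
  if (!length(lines)) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          peak_id = character(), gene_id = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- if (dialect == "bed6") 6L else 3L
  bad <- which(vapply(fields, length, 1L) < nf)
  if (length(bad)) {
    stop("malformed BED line ", which(keep)[bad[1]], ": fewer than ", nf,
         " tab-separated fields", call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop("malformed BED line ", which(keep)[bad], ": non-integer coordinates",
         call. = FALSE)
  }
  if (any(end <= start)) {
    bad <- which(end <= start)[1]
    stop("invalid interval at BED line ", which(keep)[bad],
         ": end must exceed start", call. = FALSE)
  }
  if (dialect == "bed6") {
    name <- vapply(fields, `[[`, "", 4L)
    strand <- vapply(fields, `[[`, "", 6L)
  } else {
    name <- rep(".", length(chrom))
    strand <- rep(".", length(chrom))
  }
  blank <- name == "." | name == ""
  name[blank] <- paste0("peak_", which(blank))
  out <- tibble::tibble(chrom = chrom, start = start, end = end,
                        strand = strand, peak_id = name,
                        gene_id = NA_character_)
  validate_peaks(out)
  out
}

#' Assign each peak to a single gene
#'
#' A peak overlapping more than one gene is assigned the gene with the
#' longest overlap, with ties broken lexicographically by `gene_id`; the
#' assignment of multi-gene peaks is reported via a message.
#'
#' @param peaks Peak tibble as returned by [read_peaks()].
#' @param genes Tibble of gene intervals with columns `chrom`, `start`,
#'   `end`, `gene_id` (0-based half-open).
#' @return `peaks` with `gene_id` filled (`NA` where no gene overlaps).
#' @export
assign_peaks_to_genes <- function(peaks, genes) {
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  gn <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(pk, gn, minoverlap = 1L)
  if (length(hits)) {
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(pk)[S4Vectors::queryHits(hits)],
      IRanges::ranges(gn)[S4Vectors::subjectHits(hits)]))
    cand <- tibble::tibble(
      peak = S4Vectors::queryHits(hits),
      gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
      overlap = ov
    )
    best <- cand |>
      dplyr::arrange(.data$peak, dplyr::desc(.data$overlap), .data$gene_id) |>
      dplyr::distinct(.data$peak, .keep_all = TRUE)
    multi <- cand |> dplyr::count(.data$peak) |> dplyr::filter(.data$n > 1)
    if (nrow(multi)) {
      message(nrow(multi), " peak(s) overlapped >1 gene; assigned by ",
              "longest overlap (ties broken lexicographically)")
    }
    peaks$gene_id[best$peak] <- best$gene_id
  }
  peaks
}

#' Read a count table against a sample sheet
#'
#' Reads a TSV count table (first column the feature id, remaining columns
#' samples) and a TSV sample sheet, reconciles the two, and validates
#' counts. `library_size` defaults to the table's column sums when the
#' sheet lacks the column.
#'
#' @param path Path to the count TSV.
#' @param sample_sheet_path Path to the sample sheet TSV (columns
#'   `sample_id`, `fraction`, `condition`, `replicate`, optional
#'   `library_size`).
#' @return A list with elements `counts` (tibble) and `samples` (tibble).
#' @export
read_count_table <- function(path, sample_sheet_path) {
  counts <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  samples <- readr::read_tsv(sample_sheet_path, comment = "#",
                             show_col_types = FALSE)
  samples <- validate_sample_sheet(samples)
  sample_cols <- names(counts)[-1]
  extra <- setdiff(sample_cols, samples$sample_id)
  missing <- setdiff(samples$sample_id, sample_cols)
  if (length(extra) || length(missing)) {
    stop(
      "sample reconciliation failed: ",
      if (length(extra)) paste0("in table but not sheet: ", toString(extra), "; ") else "",
      if (length(missing)) paste0("in sheet but not table: ", toString(missing)) else "",
      call. = FALSE
    )
  }
  m <- as.matrix(counts[-1])
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("count table must contain non-negative integers", call. = FALSE)
  }
  counts <- counts[c(names(counts)[1], samples$sample_id)]
  if (!"library_size" %in% names(samples)) {
    samples$library_size <- colSums(as.matrix(counts[-1]))
  }
  zero <- samples$sample_id[samples$library_size == 0]
  if (length(zero)) {
    warning("all-zero column / library_size 0 for sample(s): ",
            toString(zero), call. = FALSE)
  }
  list(counts = counts, samples = samples)
}

#' Read a full experiment from disk
#'
#' Composes [read_count_table()] and [read_peaks()] into a validated
#' [merip_experiment()].
#'
#' @param peak_counts_path,gene_counts_path TSV count tables.
#' @param sample_sheet_path TSV sample sheet.
#' @param peaks_path BED6 file of peaks; the BED name field must carry
#'   `peak_id` and (when `gene_map_path` is absent) gene ids are taken from
#'   a `peak_id<TAB>gene_id` map file.
#' @param gene_map_path TSV with columns `peak_id`, `gene_id`.
#' @return A [merip_experiment()].
#' @export
read_experiment <- function(peak_counts_path, gene_counts_path,
                            sample_sheet_path, peaks_path, gene_map_path) {
  pk <- read_count_table(peak_counts_path, sample_sheet_path)
  gn <- read_count_table(gene_counts_path, sample_sheet_path)
  peaks <- read_peaks(peaks_path, dialect = "bed6")
  map <- readr::read_tsv(gene_map_path, comment = "#", show_col_types = FALSE)
  peaks$gene_id <- map$gene_id[match(peaks$peak_id, map$peak_id)]
  names(pk$counts)[1] <- "peak_id"
  names(gn$counts)[1] <- "gene_id"
  merip_experiment(pk$counts, gn$counts, peaks, pk$samples)
}

#' Write result records to disk
#'
#' @param records A data frame of results (e.g. from [tidy()] on a fitted
#'   object). For `format = "bed"` the records must carry `chrom`, `start`,
#'   `end`, `peak_id`, `strand` and `fdr`; the BED score column encodes
#'   `as.integer(pmin(1000, -10 * log10(fdr)))`.
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  records <- tibble::as_tibble(records)
  if (format == "tsv") {
    readr::write_tsv(records, path)
  } else {
    score <- as.integer(pmin(1000, -10 * log10(pmax(records$fdr, 1e-300))))
    bed <- tibble::tibble(chrom = records$chrom, start = records$start,
                          end = records$end, name = records$peak_id,
                          score = score, strand = records$strand)
    readr::write_tsv(bed, path, col_names = FALSE)
  }
  invisible(path)
}

#' Count aligned reads overlapping peaks
#'
#' Counts, for one BAM file, the reads whose alignment overlaps each peak
#' by at least one base; each read contributes at most once per peak.
#' Duplicate reads are not removed. Strand is ignored unless
#' `stranded = TRUE`.
#'
#' @param alignment_path Path to an indexed BAM file.
#' @param peaks Peak tibble (0-based half-open coordinates).
#' @param stranded Require the read strand to match the peak strand.
#' @return `peaks` with an added integer `count` column.
#' @export
count_reads_in_peaks <- function(alignment_path, peaks, stranded = FALSE) {
  for (pkg in c("Rsamtools", "GenomicAlignments")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("package '", pkg, "' is required for BAM counting", call. = FALSE)
    }
  }
  if (!file.exists(paste0(alignment_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", alignment_path))) {
    stop("BAM index not found; index the file first, e.g. ",
         "Rsamtools::indexBam('", alignment_path, "')", call. = FALSE)
  }
  validate_peaks(peaks)
  hdr <- Rsamtools::scanBamHeader(alignment_path)[[1]]$targets
  unknown <- unique(peaks$chrom[!peaks$chrom %in% names(hdr)])
  if (length(unknown)) {
    warning("peak chromosome(s) absent from BAM header (counted as 0): ",
            toString(unknown), call. = FALSE)
  }
  known <- peaks$chrom %in% names(hdr)
  counts <- integer(nrow(peaks))
  if (any(known)) {
    gr <- GenomicRanges::GRanges(
      peaks$chrom[known],
      IRanges::IRanges(peaks$start[known] + 1L, peaks$end[known]),
      strand = if (stranded) peaks$strand[known] else "*"
    )
    aln <- GenomicAlignments::readGAlignments(alignment_path)
    counts[known] <- GenomicRanges::countOverlaps(
      gr, aln, minoverlap = 1L,
      ignore.strand = !stranded
    )
  }
  peaks$count <- counts
  peaks
}
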