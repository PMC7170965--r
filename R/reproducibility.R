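# Peak-level reproducibility metrics: overlap between experiments,
# replicate saturation/recurrence, coverage saturation, DRAC motif
# enrichment and mean +/- SD coverage summaries.
#
# Peak identity across sets is by >= 1 bp interval overlap (the
# bedtools-style convention), never by id string.

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(peaks$start + 1L, peaks$end))
}

#' Percent of one experiment's peaks recovered in another
#'
#' Computes the percent of peaks from experiment 1 that overlap (by at
#' least one base) a peak from experiment 2, restricted to peaks on genes
#' with mean input coverage of at least `min_cov` in both experiments —
#' peaks on underexpressed genes are excluded from numerator and
#' denominator alike. The measure is asymmetric in its arguments.
#'
#' @param peaks1,peaks2 Peak tibbles carrying `gene_id`.
#' @param coverage1,coverage2 Tibbles `gene_id`, `mean_coverage` (mean
#'   input coverage per gene in each experiment).
#' @param min_cov Expression gate in X coverage (default 10).
#' @return One-row tibble: `n_considered`, `n_overlapping`,
#'   `percent_overlap` (`NA` when no peak passes the gate), `min_cov`.
#' @export
overlap_percent <- function(peaks1, peaks2, coverage1, coverage2,
                            min_cov = 10) {
  ok_genes <- intersect(
    coverage1$gene_id[coverage1$mean_coverage >= min_cov],
    coverage2$gene_id[coverage2$mean_coverage >= min_cov])
  p1 <- peaks1[peaks1$gene_id %in% ok_genes, ]
  p2 <- peaks2[peaks2$gene_id %in% ok_genes, ]
  if (nrow(p1) == 0) {
    return(tibble::tibble(n_considered = 0L, n_overlapping = 0L,
                          percent_overlap = NA_real_, min_cov = min_cov))
  }
  n_ov <- if (nrow(p2) == 0) 0L else {
    sum(IRanges::overlapsAny(peaks_to_granges(p1), peaks_to_granges(p2),
                             minoverlap = 1L))
  }
  tibble::tibble(n_considered = nrow(p1), n_overlapping = n_ov,
                 percent_overlap = 100 * n_ov / nrow(p1),
                 min_cov = min_cov)
}

#' Merge peak sets into a non-overlapping union
#'
#' Intervals overlapping by at least one base are merged into maximal
#' runs; the result is sorted and non-overlapping.
#'
#' @param peak_sets A list of peak tibbles (or a single tibble).
#' @return Peak tibble of merged intervals with generated ids
#'   `merged_<n>`.
#' @export
merge_replicate_peaks <- function(peak_sets) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  all <- dplyr::bind_rows(peak_sets)
  if (nrow(all) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          peak_id = character(), gene_id = character()))
  }
  red <- GenomicRanges::reduce(peaks_to_granges(all))
  red <- GenomicRanges::sort(red)
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    strand = ".",
    peak_id = sprintf("merged_%05d", seq_along(red)),
    gene_id = NA_character_
  )
}

#' Peaks captured as replicates are added (saturation curve)
#'
#' For each subset size k, random k-subsets of the replicate peak sets are
#' drawn and the number of union peaks captured (>= 1 bp overlap with the
#' subset's merged peaks) recorded. Defaults follow the convention of 6
#' subsamples per k for 7-replicate designs and 12 for larger ones; when
#' k equals the number of replicates a single (complete) subset is used.
#'
#' @param peak_sets List of per-replicate peak tibbles (>= 2).
#' @param n_subsamples_per_k Random subsets per k (default 6).
#' @param seed Integer seed.
#' @return Tibble of class `saturation_curve`: `k`, `subsample`,
#'   `n_peaks` (union peaks captured), `percent` (of the full union).
#' @export
replicate_saturation <- function(peak_sets, n_subsamples_per_k = 6,
                                 seed = 1L) {
  stopifnot(length(peak_sets) >= 2)
  n <- length(peak_sets)
  union_peaks <- merge_replicate_peaks(peak_sets)
  total <- nrow(union_peaks)
  ugr <- peaks_to_granges(union_peaks)
  rows <- with_local_seed(seed, {
    out <- list()
    for (k in seq_len(n)) {
      n_sub <- if (k == n) 1L else n_subsamples_per_k
      for (b in seq_len(n_sub)) {
        idx <- sort(sample.int(n, k))
        sub <- dplyr::bind_rows(peak_sets[idx])
        captured <- if (nrow(sub) == 0) 0L else {
          sum(IRanges::overlapsAny(ugr, peaks_to_granges(sub),
                                   minoverlap = 1L))
        }
        out[[length(out) + 1]] <- tibble::tibble(
          k = k, subsample = b, n_peaks = captured,
          percent = if (total > 0) 100 * captured / total else NA_real_)
      }
    }
    dplyr::bind_rows(out)
  })
  class(rows) <- c("saturation_curve", class(rows))
  attr(rows, "metric") <- "replicate_saturation"
  rows
}

#' Percent of union peaks present in at least r replicates
#'
#' Membership of a union peak in a replicate is >= 1 bp overlap with any
#' of that replicate's peaks. The curve is monotone non-increasing in r
#' and equals 100 percent at r = 1 by construction.
#'
#' @param peak_sets List of per-replicate peak tibbles (>= 2).
#' @return Tibble of class `saturation_curve`: `r`, `n_peaks`, `percent`.
#' @export
recurrence_curve <- function(peak_sets) {
  stopifnot(length(peak_sets) >= 2)
  union_peaks <- merge_replicate_peaks(peak_sets)
  ugr <- peaks_to_granges(union_peaks)
  times <- rowSums(vapply(peak_sets, function(p) {
    if (nrow(p) == 0) rep(FALSE, length(ugr)) else
      IRanges::overlapsAny(ugr, peaks_to_granges(p), minoverlap = 1L)
  }, logical(length(ugr))))
  out <- tibble::tibble(
    r = seq_along(peak_sets),
    n_peaks = vapply(seq_along(peak_sets),
                     function(r) sum(times >= r), 0L),
    percent = 100 * vapply(seq_along(peak_sets),
                           function(r) mean(times >= r), 0)
  )
  class(out) <- c("saturation_curve", class(out))
  attr(out, "metric") <- "recurrence"
  out
}

#' Percent of genes with peaks as a function of input coverage
#'
#' Genes are binned by mean input coverage (log-spaced bins over the
#' observed positive range) and, per bin, the percent of genes carrying at
#' least `k` merged peaks is reported for each threshold. The coverage
#' needed for saturation is operationalized as the lower edge of the
#' first bin where the k = 1 curve reaches 90 percent of its plateau.
#'
#' @param gene_coverage Tibble `gene_id`, `chrom`, `start`, `end`,
#'   `mean_coverage` (gene intervals 0-based half-open).
#' @param peak_sets List of peak tibbles (merged internally).
#' @param thresholds Peak-count thresholds (default `c(1, 2, 3)`).
#' @param n_bins Number of log-spaced coverage bins (default 20).
#' @return Tibble of class `saturation_curve`: `threshold`, `bin`,
#'   `bin_lo`, `bin_hi`, `n_genes`, `percent`; the estimated saturation
#'   coverage is attached as attribute `"saturation_coverage"`.
#' @export
coverage_saturation <- function(gene_coverage, peak_sets,
                                thresholds = c(1, 2, 3), n_bins = 20) {
  merged <- merge_replicate_peaks(peak_sets)
  gg <- GenomicRanges::GRanges(
    gene_coverage$chrom,
    IRanges::IRanges(gene_coverage$start + 1L, gene_coverage$end))
  npk <- if (nrow(merged) == 0) rep(0L, length(gg)) else {
    GenomicRanges::countOverlaps(gg, peaks_to_granges(merged),
                                 minoverlap = 1L)
  }
  cov <- gene_coverage$mean_coverage
  pos <- cov[cov > 0]
  if (!length(pos)) pos <- 1
  edges <- exp(seq(log(max(min(pos), 1e-3)), log(max(pos) + 1e-9),
                   length.out = n_bins + 1))
  edges[1] <- 0 # lowest bin absorbs zero-coverage genes
  edges <- unique(edges)
  if (length(edges) < 2) edges <- c(0, max(cov, 1))
  bin <- cut(cov, edges, include.lowest = TRUE, labels = FALSE)
  out <- list()
  for (k in thresholds) {
    for (b in sort(unique(bin))) {
      idx <- bin == b
      out[[length(out) + 1]] <- tibble::tibble(
        threshold = k, bin = b, bin_lo = edges[b], bin_hi = edges[b + 1],
        n_genes = sum(idx), percent = 100 * mean(npk[idx] >= k))
    }
  }
  out <- dplyr::bind_rows(out)
  k1 <- out[out$threshold == thresholds[1], ]
  plateau <- max(k1$percent)
  sat <- if (plateau > 0) {
    min(k1$bin_lo[k1$percent >= 0.9 * plateau])
  } else NA_real_
  class(out) <- c("saturation_curve", class(out))
  attr(out, "metric") <- "coverage_saturation"
  attr(out, "saturation_coverage") <- sat
  out
}

# DRAC motif on DNA alphabet (D in {A,G,T}, R in {A,G}, then A, C);
# RNA input is mapped U -> T before matching
DRAC_PATTERN <- "[AGT][AG]AC"

has_drac <- function(seq) {
  grepl(DRAC_PATTERN, chartr("Uu", "Tt", toupper(seq)))
}

#' DRAC motif enrichment in peaks versus shuffled intervals
#'
#' Fraction of peaks containing the m6A consensus DRAC
#' (`[AGT][AG]AC`) compared against `n_shuffles` backgrounds in which
#' each interval is placed uniformly at random within its own gene's
#' sequence, preserving interval length and gene of origin.
#'
#' @param peaks Peak tibble with `gene_id`, coordinates 0-based half-open
#'   on the same chromosome scale as `sequences$gene_start`.
#' @param sequences Tibble `gene_id`, `seq`, `gene_start` (chromosome
#'   offset of the sequence, as produced by
#'   [simulate_sequences_and_coverage()]).
#' @param n_shuffles Number of shuffled backgrounds (default 100).
#' @param seed Integer seed.
#' @return One-row tibble: `n_peaks`, `observed_fraction`,
#'   `shuffled_fraction` (mean over shuffles), `enrichment_ratio`
#'   (`NA` when both fractions are 0; `Inf` capped at `Inf` with
#'   `degenerate_background = TRUE` when only the background is 0),
#'   `p_value` (empirical, `(1 + #{shuffle >= observed})/(n_shuffles+1)`).
#' @export
drac_enrichment <- function(peaks, sequences, n_shuffles = 100, seed = 1L) {
  stopifnot(all(peaks$gene_id %in% sequences$gene_id))
  gidx <- match(peaks$gene_id, sequences$gene_id)
  rel_start <- peaks$start - sequences$gene_start[gidx]
  width <- peaks$end - peaks$start
  seqs <- sequences$seq[gidx]
  if (any(rel_start < 0 | rel_start + width > nchar(seqs))) {
    stop("peak interval outside its gene's sequence", call. = FALSE)
  }
  obs <- mean(has_drac(substr(seqs, rel_start + 1, rel_start + width)))
  shuf <- with_local_seed(seed, {
    vapply(seq_len(n_shuffles), function(b) {
      max_start <- nchar(seqs) - width
      st <- floor(stats::runif(length(seqs)) * (max_start + 1))
      mean(has_drac(substr(seqs, st + 1, st + width)))
    }, 0)
  })
  mean_shuf <- mean(shuf)
  ratio <- if (obs == 0 && mean_shuf == 0) NA_real_
           else if (mean_shuf == 0) Inf
           else obs / mean_shuf
  tibble::tibble(
    n_peaks = nrow(peaks),
    observed_fraction = obs,
    shuffled_fraction = mean_shuf,
    enrichment_ratio = ratio,
    degenerate_background = is.infinite(ratio),
    p_value = (1 + sum(shuf >= obs)) / (n_shuffles + 1)
  )
}

#' Mean and SD coverage across replicates
#'
#' Per-position mean and sample standard deviation (n - 1 denominator;
#' SD 0 when a single replicate is available) of coverage within each
#' gene, fraction and condition — the summary drawn as a line with a
#' shaded band in coverage plots.
#'
#' @param coverage Long tibble `gene_id`, `fraction`, `condition`,
#'   `replicate`, `position`, `depth`.
#' @return Tibble `gene_id`, `fraction`, `condition`, `position`,
#'   `mean_depth`, `sd_depth`, `n_replicates`.
#' @export
coverage_summary <- function(coverage) {
  coverage |>
    dplyr::summarise(
      mean_depth = mean(.data$depth),
      sd_depth = if (dplyr::n() > 1) stats::sd(.data$depth) else 0,
      n_replicates = dplyr::n(),
      .by = c("gene_id", "fraction", "condition", "position")
    )
}
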