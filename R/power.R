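# Replicate-subsampling power analysis: how many replicates per condition
# statistical detection of a peak change requires.

# subset an experiment to chosen replicates per condition; IP/input pairs
# are never split
subset_replicates <- function(experiment, keep) {
  s <- experiment$samples
  keep_idx <- vapply(seq_len(nrow(s)), function(j) {
    s$replicate[j] %in% keep[[s$condition[j]]]
  }, TRUE)
  samples <- s[keep_idx, ]
  merip_experiment(
    experiment$peak_counts[c("peak_id", samples$sample_id)],
    experiment$gene_counts[c("gene_id", samples$sample_id)],
    experiment$peaks, samples
  )
}

#' Power by replicate subsampling
#'
#' For each replicate count k in `k_grid`, draws `n_subsamples` random
#' subsets of k replicates per condition (without replacement,
#' independently per condition, IP/input pairs kept together), reruns the
#' full differential methylation pipeline on each reduced design, and
#' records per peak the fraction of subsamples in which it was called
#' significant. When k equals the full replicate count a single
#' deterministic run is used. Dispersions are re-estimated within each
#' subsample, as a real k-replicate study would.
#'
#' @param experiment A [merip_experiment()].
#' @param k_grid Replicate counts per condition to evaluate (values below
#'   2 are skipped with a warning).
#' @param n_subsamples Random subsets per k (default 10).
#' @param alpha FDR threshold for detection (default 0.05).
#' @param rule Combine rule across variants (`"union"` or
#'   `"intersect"`).
#' @param variants Dispersion variant(s) to run per subsample; the
#'   default uses `trend_shrink` alone to keep the subsampling loop
#'   affordable.
#' @param seed Integer seed governing all subsample draws.
#' @return Tibble of class `power_curve`: `peak_id`, `k`, `n_subsamples`,
#'   `fraction_detected`.
#' @export
subsample_power <- function(experiment, k_grid, n_subsamples = 10,
                            alpha = 0.05, rule = "union",
                            variants = "trend_shrink", seed = 1L) {
  stopifnot(inherits(experiment, "merip_experiment"))
  s <- experiment$samples
  avail <- tapply(s$replicate[s$fraction == "IP"],
                  s$condition[s$fraction == "IP"], unique, simplify = FALSE)
  n_avail <- min(lengths(avail))
  bad <- k_grid > n_avail
  if (any(bad)) {
    warning("k larger than available replicates skipped: ",
            toString(k_grid[bad]), call. = FALSE)
    k_grid <- k_grid[!bad]
  }
  small <- k_grid < 2
  if (any(small)) {
    warning("k below the GLM minimum of 2 replicates skipped: ",
            toString(k_grid[small]), call. = FALSE)
    k_grid <- k_grid[!small]
  }
  peak_ids <- experiment$peak_counts$peak_id

  rows <- with_local_seed(seed, {
    out <- list()
    for (k in sort(unique(k_grid))) {
      n_sub <- if (k == n_avail) 1L else n_subsamples
      detected <- matrix(FALSE, length(peak_ids), n_sub)
      for (b in seq_len(n_sub)) {
        keep <- lapply(avail, function(r) sort(sample(r, k)))
        sub <- subset_replicates(experiment, keep)
        fit <- diffmeth(sub, variants = variants, alpha = alpha,
                        combine = rule)
        sig <- combine_calls(fit$results, rule = rule, alpha = alpha)
        detected[, b] <- peak_ids %in% sig
      }
      out[[length(out) + 1]] <- tibble::tibble(
        peak_id = peak_ids, k = k, n_subsamples = n_sub,
        fraction_detected = rowMeans(detected))
    }
    dplyr::bind_rows(out)
  })
  class(rows) <- c("power_curve", class(rows))
  attr(rows, "params") <- list(alpha = alpha, rule = rule,
                               variants = variants, seed = seed)
  rows
}

#' Smallest replicate count giving consistent detection
#'
#' Per peak, the smallest k at which the peak was detected in at least
#' `min_fraction` of subsamples (the consistent-detection criterion), or
#' `NA` when never reached; quartiles of the k distribution over peaks
#' that reach it are attached as attribute `"summary"`.
#'
#' @param power_table Output of [subsample_power()] over a contiguous k
#'   grid.
#' @param min_fraction Detection-fraction threshold (default 0.5).
#' @return Tibble `peak_id`, `k_star` (integer or `NA` for "not
#'   reached").
#' @export
consistent_detection_threshold <- function(power_table,
                                           min_fraction = 0.5) {
  out <- power_table |>
    dplyr::filter(.data$fraction_detected >= min_fraction) |>
    dplyr::summarise(k_star = min(.data$k), .by = "peak_id")
  all_ids <- unique(power_table$peak_id)
  out <- tibble::tibble(peak_id = all_ids) |>
    dplyr::left_join(out, by = "peak_id")
  attr(out, "summary") <- stats::quantile(out$k_star, c(0.25, 0.5, 0.75),
                                          na.rm = TRUE)
  out
}
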