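#' Estimate per-sample size factors
#'
#' Library-size normalization factors entering the GLM as offsets. Factors
#' are computed separately within the IP sample group and within the input
#' sample group, then each group is rescaled to geometric mean 1, so that
#' the global IP/input enrichment ratio is absorbed by the model's IP
#' coefficient rather than distorting input normalization.
#'
#' @param experiment A [merip_experiment()].
#' @param method `"median_of_ratios"` (DESeq-style: the median across
#'   features of the ratio of a sample's counts to the per-feature
#'   geometric mean within the group) or `"total_count"` (column sums).
#' @param use Which count table to estimate from (`"peak"` or `"gene"`).
#' @return Tibble with columns `sample_id`, `fraction`, `size_factor`.
#' @examples
#' sim <- simulate_experiment(simulation_config(n_genes = 20, seed = 7))
#' estimate_size_factors(sim$experiment)
#' @export
estimate_size_factors <- function(experiment,
                                  method = c("median_of_ratios",
                                             "total_count"),
                                  use = c("peak", "gene")) {
  method <- match.arg(method)
  use <- match.arg(use)
  stopifnot(inherits(experiment, "merip_experiment"))
  counts <- count_matrix(
    if (use == "peak") experiment$peak_counts else experiment$gene_counts)
  samples <- experiment$samples

  all_zero <- colSums(counts) == 0
  if (any(all_zero)) {
    stop("sample(s) with all-zero counts: ",
         toString(samples$sample_id[all_zero]), call. = FALSE)
  }

  sf <- numeric(ncol(counts))
  for (frac in unique(samples$fraction)) {
    idx <- which(samples$fraction == frac)
    sub <- counts[, idx, drop = FALSE]
    if (method == "total_count") {
      f <- colSums(sub)
    } else {
      log_geo <- rowMeans(log(sub))          # -Inf where any zero
      usable <- is.finite(log_geo)
      if (!any(usable)) {
        stop("median-of-ratios needs >=1 feature with nonzero counts in ",
             "every sample of the ", frac, " group", call. = FALSE)
      }
      f <- apply(sub[usable, , drop = FALSE], 2, function(cnt) {
        stats::median(exp(log(cnt) - log_geo[usable]))
      })
    }
    sf[idx] <- f / exp(mean(log(f)))         # geometric mean 1 within group
  }
  tibble::tibble(sample_id = samples$sample_id,
                 fraction = samples$fraction, size_factor = sf)
}
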