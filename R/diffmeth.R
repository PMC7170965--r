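#' Per-peak GLM likelihood-ratio tests for one dispersion variant
#'
#' Runs the full and reduced NB GLM on every peak with the given
#' per-peak dispersions and tests the interaction term by the chi-squared
#' (df = 1) deviance difference.
#'
#' @param experiment A [merip_experiment()].
#' @param design Output of [glm_design()].
#' @param dispersions Tibble from [estimate_dispersions()].
#' @return Tibble with one row per peak: `peak_id`, the four coefficients
#'   (`beta0`, `beta_ip`, `beta_stim`, `beta_interaction`, natural-log
#'   scale), `dispersion`, `deviance_full`, `deviance_reduced`,
#'   `lrt_stat`, `p_value`, `fdr` (Benjamini-Hochberg over non-missing p),
#'   `converged`. Degenerate (all-zero) peaks carry `NA` p and are never
#'   significant.
#' @export
glm_lrt <- function(experiment, design, dispersions) {
  counts <- count_matrix(experiment$peak_counts)
  phi <- dispersions$phi[match(rownames(counts), dispersions$peak_id)]
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    y <- counts[i, ]
    if (is.na(phi[i]) || all(y == 0)) {
      return(tibble::tibble(
        peak_id = rownames(counts)[i], beta0 = NA_real_, beta_ip = NA_real_,
        beta_stim = NA_real_, beta_interaction = NA_real_,
        dispersion = phi[i], deviance_full = NA_real_,
        deviance_reduced = NA_real_, lrt_stat = NA_real_,
        p_value = NA_real_, converged = FALSE))
    }
    full <- fit_nb_glm(y, design, phi[i], "full")
    red <- fit_nb_glm(y, design, phi[i], "reduced")
    t <- lrt_interaction(full, red)
    tibble::tibble(
      peak_id = rownames(counts)[i],
      beta0 = full$coefficients[["beta0"]],
      beta_ip = full$coefficients[["beta_ip"]],
      beta_stim = full$coefficients[["beta_stim"]],
      beta_interaction = full$coefficients[["beta_interaction"]],
      dispersion = phi[i],
      deviance_full = full$deviance, deviance_reduced = red$deviance,
      lrt_stat = t$lrt_stat, p_value = t$p_value,
      converged = full$converged && red$converged)
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- adjust_fdr(out$p_value)
  out
}

#' Benjamini-Hochberg FDR adjustment tolerating missing p-values
#'
#' @param p_values Numeric vector in \[0, 1\], `NA` allowed (excluded from
#'   the adjustment and returned as `NA`).
#' @return Adjusted values, same length and order.
#' @export
adjust_fdr <- function(p_values) {
  out <- rep(NA_real_, length(p_values))
  ok <- !is.na(p_values)
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Fold-change decomposition of peak and gene changes
#'
#' Computes, per peak, the log2 fold change of IP counts at the peak and
#' of input counts at the host gene (treated over control, means of
#' size-factor-normalized counts with pseudocount 0.5), and their absolute
#' difference `delta_log2fc` — the change in peak enrichment net of gene
#' expression change. `min_peak_count` is the minimum raw peak count
#' across all samples (replicates and conditions).
#'
#' @param experiment A [merip_experiment()].
#' @param size_factors Tibble from [estimate_size_factors()].
#' @param pseudocount Added to normalized means before the ratio.
#' @return Tibble: `peak_id`, `gene_id`, `peak_ip_log2fc`,
#'   `gene_input_log2fc`, `delta_log2fc`, `min_peak_count`,
#'   `low_expression` (gene input all zero in at least one condition).
#' @export
compute_fold_changes <- function(experiment, size_factors,
                                 pseudocount = 0.5) {
  s <- experiment$samples
  sf <- size_factors$size_factor[match(s$sample_id, size_factors$sample_id)]
  pk <- count_matrix(experiment$peak_counts)
  gn <- count_matrix(experiment$gene_counts)
  pk_norm <- sweep(pk, 2, sf, "/")
  gn_norm <- sweep(gn, 2, sf, "/")

  grp <- function(fraction, condition) {
    s$fraction == fraction & s$condition == condition
  }
  mean_or_na <- function(m, idx) {
    if (!any(idx)) rep(NA_real_, nrow(m)) else
      rowMeans(m[, idx, drop = FALSE])
  }
  ip_trt <- mean_or_na(pk_norm, grp("IP", "treated"))
  ip_ctl <- mean_or_na(pk_norm, grp("IP", "control"))
  in_trt <- mean_or_na(gn_norm, grp("input", "treated"))
  in_ctl <- mean_or_na(gn_norm, grp("input", "control"))

  peak_fc <- log2((ip_trt + pseudocount) / (ip_ctl + pseudocount))
  gene_fc <- log2((in_trt + pseudocount) / (in_ctl + pseudocount))

  raw_in_trt <- rowSums(gn[, grp("input", "treated"), drop = FALSE])
  raw_in_ctl <- rowSums(gn[, grp("input", "control"), drop = FALSE])
  low <- raw_in_trt == 0 | raw_in_ctl == 0

  gidx <- match(experiment$peaks$gene_id[
    match(rownames(pk), experiment$peaks$peak_id)], rownames(gn))

  tibble::tibble(
    peak_id = rownames(pk),
    gene_id = rownames(gn)[gidx],
    peak_ip_log2fc = unname(peak_fc),
    gene_input_log2fc = unname(gene_fc[gidx]),
    delta_log2fc = abs(unname(peak_fc) - unname(gene_fc[gidx])),
    min_peak_count = unname(apply(pk, 1, min)),
    low_expression = unname(low[gidx])
  )
}

#' Combine significant peak sets across dispersion variants
#'
#' @param results Named list of [glm_lrt()] tibbles, one per variant.
#' @param rule `"union"` (less conservative) or `"intersect"` (most
#'   probable sites).
#' @param alpha FDR threshold.
#' @return Character vector of significant `peak_id`s.
#' @export
combine_calls <- function(results, rule = c("union", "intersect"),
                          alpha = 0.05) {
  rule <- match.arg(rule)
  stopifnot(length(results) >= 1)
  sets <- lapply(results, function(r) {
    r$peak_id[!is.na(r$fdr) & r$fdr < alpha]
  })
  out <- Reduce(if (rule == "union") union else intersect, sets)
  sort(out)
}

#' Apply the differential-methylation filters
#'
#' Retains peaks that are significant under the combine rule and pass the
#' published thresholds: absolute difference between peak-IP and
#' gene-input log2 fold changes of at least `min_delta`, and a minimum
#' peak read count of `min_count` across all replicates and conditions.
#' Optionally restricts to peaks overlapping a supplied exon set. Filter
#' application is order-independent.
#'
#' @param calls Tibble carrying `peak_id`, `delta_log2fc`,
#'   `min_peak_count` and logical `significant` columns (see
#'   [diffmeth()]).
#' @param min_delta Minimum `delta_log2fc` (default 1).
#' @param min_count Minimum peak read count (default 10).
#' @param exon_peaks Optional character vector of peak ids overlapping
#'   exons; `NULL` disables the exon filter.
#' @return `calls` with a logical `passes_filters` column; rows failing
#'   any enabled threshold get `FALSE`.
#' @export
apply_filters <- function(calls, min_delta = 1, min_count = 10,
                          exon_peaks = NULL) {
  pass <- calls$significant &
    !is.na(calls$delta_log2fc) & calls$delta_log2fc >= min_delta &
    calls$min_peak_count >= min_count
  if (!is.null(exon_peaks)) pass <- pass & calls$peak_id %in% exon_peaks
  calls$passes_filters <- pass & !is.na(pass)
  calls
}

#' Differential m6A peak detection pipeline
#'
#' End-to-end analysis: size-factor normalization, per-peak dispersion
#' estimation (one or two variants), full/reduced NB GLM fits, chi-squared
#' (df = 1) likelihood-ratio test on the IP-by-condition interaction, BH
#' FDR adjustment, fold-change decomposition, ensemble combination across
#' variants and the published filters.
#'
#' @param experiment A [merip_experiment()].
#' @param variants Dispersion variants to run (see
#'   [estimate_dispersions()]).
#' @param norm_method Size-factor method (see [estimate_size_factors()]).
#' @param alpha FDR threshold for significance (default 0.05).
#' @param combine `"union"` or `"intersect"` of variant calls.
#' @param min_delta,min_count Filter thresholds (defaults 1 and 10).
#' @param exon_peaks Optional peak ids overlapping exons (enables the
#'   exon-location filter).
#' @return Object of class `merip_diffmeth`: list with `results` (named
#'   list of per-variant [glm_lrt()] tibbles), `calls` (combined per-peak
#'   tibble with fold changes, per-variant fdr, `significant_by`,
#'   `significant`, `passes_filters`), `size_factors`, `params`.
#' @examples
#' sim <- simulate_experiment(simulation_config(
#'   n_genes = 20, n_replicates_per_condition = 3,
#'   fraction_changed = 0.2, methylation_log2fc = 2, seed = 3))
#' fit <- diffmeth(sim$experiment)
#' glance(fit)
#' @export
diffmeth <- function(experiment,
                     variants = c("trend_shrink", "common_tagwise"),
                     norm_method = "median_of_ratios",
                     alpha = 0.05, combine = "union",
                     min_delta = 1, min_count = 10, exon_peaks = NULL) {
  stopifnot(inherits(experiment, "merip_experiment"))
  variants <- match.arg(variants, c("trend_shrink", "common_tagwise"),
                        several.ok = TRUE)
  sf <- estimate_size_factors(experiment, method = norm_method)
  design <- glm_design(experiment$samples, sf)

  results <- list()
  for (v in variants) {
    disp <- estimate_dispersions(experiment, design, variant = v)
    results[[v]] <- glm_lrt(experiment, design, disp)
  }

  fc <- compute_fold_changes(experiment, sf)
  sig_ids <- combine_calls(results, rule = combine, alpha = alpha)

  calls <- fc
  for (v in variants) {
    calls[[paste0("p_", v)]] <- results[[v]]$p_value[
      match(calls$peak_id, results[[v]]$peak_id)]
    calls[[paste0("fdr_", v)]] <- results[[v]]$fdr[
      match(calls$peak_id, results[[v]]$peak_id)]
  }
  sig_mat <- vapply(variants, function(v) {
    f <- calls[[paste0("fdr_", v)]]
    !is.na(f) & f < alpha
  }, logical(nrow(calls)))
  sig_mat <- matrix(sig_mat, nrow = nrow(calls))
  calls$significant_by <- apply(sig_mat, 1, function(r) {
    paste(variants[r], collapse = ",")
  })
  calls$significant <- calls$peak_id %in% sig_ids
  calls <- apply_filters(calls, min_delta = min_delta,
                         min_count = min_count, exon_peaks = exon_peaks)

  structure(
    list(results = results, calls = calls, size_factors = sf,
         params = list(variants = variants, alpha = alpha,
                       combine = combine, min_delta = min_delta,
                       min_count = min_count,
                       norm_method = norm_method)),
    class = "merip_diffmeth"
  )
}

#' @export
print.merip_diffmeth <- function(x, ...) {
  cat("<merip_diffmeth> ", nrow(x$calls), " peaks, variants: ",
      toString(x$params$variants), "\n", sep = "")
  cat("  significant (", x$params$combine, ", FDR < ", x$params$alpha,
      "): ", sum(x$calls$significant), "\n", sep = "")
  cat("  passing filters: ", sum(x$calls$passes_filters), "\n", sep = "")
  invisible(x)
}

#' Tidy per-peak results of a differential-methylation fit
#'
#' @param x A `merip_diffmeth` object.
#' @param ... Unused.
#' @return The combined per-peak calls tibble (one row per peak).
#' @export
tidy.merip_diffmeth <- function(x, ...) x$calls

#' One-row summary of a differential-methylation fit
#'
#' @param x A `merip_diffmeth` object.
#' @param ... Unused.
#' @return Tibble with peak totals, per-rule significant counts and the
#'   number of peaks passing all filters.
#' @export
glance.merip_diffmeth <- function(x, ...) {
  tibble::tibble(
    n_peaks = nrow(x$calls),
    n_tested = sum(!is.na(x$calls[[paste0("p_", x$params$variants[1])]])),
    n_significant = sum(x$calls$significant),
    n_union = length(combine_calls(x$results, "union", x$params$alpha)),
    n_intersect = length(combine_calls(x$results, "intersect",
                                       x$params$alpha)),
    n_passing_filters = sum(x$calls$passes_filters),
    alpha = x$params$alpha
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
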