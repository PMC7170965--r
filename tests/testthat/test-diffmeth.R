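test_that("fold-change decomposition cancels proportional changes", {
  samples <- make_samples(2)
  base <- c(100L, 200L)
  ip <- samples$fraction == "IP"
  trt <- samples$condition == "treated"

  # treated identical to control: all fold changes zero
  m <- matrix(rep(base, 8), 2)
  exp <- make_experiment(m)
  fc <- compute_fold_changes(exp, estimate_size_factors(exp, "total_count"))
  expect_equal(fc$peak_ip_log2fc, c(0, 0))
  expect_equal(fc$gene_input_log2fc, c(0, 0))
  expect_equal(fc$delta_log2fc, c(0, 0))

  # IP and input both double under treatment: delta stays 0 even though
  # both fold changes are 2-fold (the proportional-change failure mode)
  m2 <- matrix(rep(base, 8), 2)
  m2[, trt] <- m2[, trt] * 2L
  exp2 <- make_experiment(m2)
  sf2 <- tibble::tibble(sample_id = samples$sample_id,
                        fraction = samples$fraction,
                        size_factor = rep(1, 8))
  fc2 <- compute_fold_changes(exp2, sf2)
  expect_equal(fc2$peak_ip_log2fc, fc2$gene_input_log2fc, tolerance = 1e-9)
  expect_equal(fc2$delta_log2fc, c(0, 0), tolerance = 1e-9)

  # IP x4 with input unchanged at large counts: delta ~ 2
  m3 <- matrix(rep(c(4000L, 4000L), 8), 2)
  m3[, ip & trt] <- m3[, ip & trt] * 4L
  exp3 <- make_experiment(m3, gene_mat = matrix(rep(c(4000L, 4000L), 8), 2))
  fc3 <- compute_fold_changes(exp3, sf2)
  expect_equal(fc3$delta_log2fc, c(2, 2), tolerance = 1e-3)
  expect_equal(fc3$min_peak_count, c(4000L, 4000L))
})

test_that("BH adjustment matches hand computations and tolerates missing p", {
  expect_equal(adjust_fdr(0.05), 0.05)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(c(1, 1, 1)), c(1, 1, 1))
  got <- adjust_fdr(c(0.01, NA, 0.04))
  expect_true(is.na(got[2]))
  expect_equal(got[c(1, 3)], p.adjust(c(0.01, 0.04), "BH"))
  # monotone: fdr order preserves p order
  p <- c(0.001, 0.5, 0.01, 0.2)
  expect_equal(order(adjust_fdr(p)), order(p))
})

test_that("ensemble set algebra over variants", {
  mk <- function(ids, fdrs) tibble::tibble(peak_id = ids, fdr = fdrs)
  a <- mk(c("p1", "p2", "p3"), c(0.01, 0.02, 0.9))
  b <- mk(c("p1", "p2", "p3"), c(0.8, 0.03, 0.04))
  expect_equal(combine_calls(list(a, a), "union"),
               combine_calls(list(a, a), "intersect"))
  expect_equal(combine_calls(list(a, b), "union"), c("p1", "p2", "p3"))
  expect_equal(combine_calls(list(a, b), "intersect"), "p2")
  disjoint <- mk(c("p1", "p2", "p3"), c(0.9, 0.9, 0.01))
  expect_equal(combine_calls(list(a, disjoint), "intersect"), character())
  # intersect subseteq each variant set subseteq union
  u <- combine_calls(list(a, b), "union")
  i <- combine_calls(list(a, b), "intersect")
  for (s in list(a, b)) {
    sig <- s$peak_id[s$fdr < 0.05]
    expect_true(all(i %in% sig))
    expect_true(all(sig %in% u))
  }
})

test_that("filters retain exactly the records meeting every threshold", {
  calls <- tibble::tibble(
    peak_id = paste0("p", 1:6),
    significant = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    delta_log2fc = c(1.2, 0.5, 1.2, 1.2, 1.0, 1.2),
    min_peak_count = c(15L, 15L, 9L, 15L, 10L, 10L))
  out <- apply_filters(calls)
  expect_equal(out$passes_filters,
               c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  # order independence: permuting rows permutes verdicts identically
  perm <- c(4, 2, 6, 1, 3, 5)
  out_perm <- apply_filters(calls[perm, ])
  expect_equal(out_perm$passes_filters, out$passes_filters[perm])
  # the exon filter is off unless an exon peak list is supplied
  out_exon <- apply_filters(calls, exon_peaks = c("p1", "p5"))
  expect_equal(out_exon$passes_filters,
               c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
})

test_that("the pipeline recovers strong planted changes and orders variants consistently", {
  sim <- simulate_experiment(simulation_config(
    n_genes = 25, peaks_per_gene = 2, n_replicates_per_condition = 4,
    fraction_changed = 0.2, methylation_log2fc = 2.5, seed = 19))
  fit <- diffmeth(sim$experiment)
  tt <- dplyr::left_join(tidy(fit), sim$peak_truth,
                         by = c("peak_id", "gene_id"))
  # most true changes recovered, few false positives
  expect_gte(sum(tt$significant & tt$changed) / sum(tt$changed), 0.7)
  expect_lte(sum(tt$significant & !tt$changed), 3)
  g <- glance(fit)
  expect_lte(g$n_intersect, g$n_significant)
  expect_gte(g$n_union, g$n_intersect)
  expect_lte(g$n_passing_filters, g$n_union)
  # tidy carries one row per peak with per-variant fdr columns
  expect_equal(nrow(tt), nrow(sim$peak_truth))
  expect_true(all(c("fdr_trend_shrink", "fdr_common_tagwise",
                    "significant_by") %in% names(tt)))
})
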