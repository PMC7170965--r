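test_that("identical seeds give identical experiments, different seeds differ", {
  cfg <- simulation_config(n_genes = 10, seed = 99, fraction_changed = 0.5,
                           methylation_log2fc = 1.5)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a, b)
  cfg$seed <- 100L
  c <- simulate_experiment(cfg)
  expect_false(identical(a$experiment$peak_counts, c$experiment$peak_counts))
})

test_that("null simulation carries no true effects and equal group means", {
  sim <- simulate_null(simulation_config(n_genes = 50, seed = 5,
                                         fraction_changed = 0.4,
                                         methylation_log2fc = 2))
  expect_true(all(!sim$peak_truth$changed))
  expect_true(all(sim$peak_truth$methylation_log2fc == 0))
  expect_true(all(sim$gene_truth$expression_log2fc == 0))
})

test_that("draws reproduce negative-binomial moments", {
  # homogeneous settings: all gene input counts are iid NB(mu=100, phi=0.1)
  cfg <- simulation_config(
    n_genes = 1000, peaks_per_gene = 1, n_replicates_per_condition = 5,
    baseline_gene_mean = 100, baseline_log2_sd = 0,
    dispersion = c(a0 = 0.1, a1 = 0),
    library_size_factors = rep(1, 20), replicate_pair_sd = 0, seed = 21)
  sim <- simulate_experiment(cfg)
  y <- as.numeric(as.matrix(sim$experiment$gene_counts[-1])[
    , sim$experiment$samples$fraction == "input"])
  expect_gt(length(y), 9999)
  expect_lt(abs(mean(y) - 100) / 100, 0.05)
  expect_lt(abs(var(y) - 1100) / 1100, 0.05) # mu + phi mu^2
})

test_that("condition and IP effects enter the mean as specified", {
  cfg <- simulation_config(
    n_genes = 400, peaks_per_gene = 1, n_replicates_per_condition = 4,
    baseline_gene_mean = 200, baseline_log2_sd = 0, ip_enrichment = 4,
    expression_log2fc = 1, methylation_log2fc = rep(2, 400),
    dispersion = c(0.01, 1), library_size_factors = rep(1, 16),
    replicate_pair_sd = 0, seed = 8)
  sim <- simulate_experiment(cfg)
  s <- sim$experiment$samples
  pk <- as.matrix(sim$experiment$peak_counts[-1])
  cell_mean <- function(fr, cond) mean(pk[, s$fraction == fr & s$condition == cond])
  # input: baseline 100 (peak baseline is half the gene baseline), x2 treated
  expect_lt(abs(cell_mean("input", "control") - 100) / 100, 0.1)
  expect_lt(abs(cell_mean("input", "treated") - 200) / 200, 0.1)
  # IP: x4 enrichment, treated additionally x2^2
  expect_lt(abs(cell_mean("IP", "control") - 400) / 400, 0.1)
  expect_lt(abs(cell_mean("IP", "treated") - 3200) / 3200, 0.1)
})

test_that("simulated peak sets follow binomial detection", {
  sets <- simulate_peak_sets(6, 300, detection_prob = 1, seed = 3)
  expect_true(all(vapply(sets, nrow, 0L) == 300))

  sets <- simulate_peak_sets(8, 500, detection_prob = 0.5, seed = 3)
  sizes <- vapply(sets, nrow, 0L)
  # per-replicate size ~ Bin(500, 0.5); allow 4 sd around the mean
  expect_true(all(abs(sizes - 250) < 4 * sqrt(500 * 0.25)))

  # fraction of the universe in >= r of n replicates matches the
  # binomial tail
  universe <- attr(sets, "universe")
  times <- rowSums(vapply(sets, function(s) {
    universe$peak_id %in% s$peak_id
  }, logical(nrow(universe))))
  for (r in c(2, 4, 6)) {
    expected <- pbinom(r - 1, 8, 0.5, lower.tail = FALSE)
    expect_lt(abs(mean(times >= r) - expected), 0.06)
  }
})

test_that("planted motifs and coverage tracks are consistent with counts", {
  cfg <- simulation_config(n_genes = 6, peaks_per_gene = 2,
                           n_replicates_per_condition = 2,
                           fraction_changed = 0.5,
                           methylation_log2fc = 2, seed = 17)
  sim <- simulate_experiment(cfg)
  sc <- simulate_sequences_and_coverage(sim, planting_rate = 1,
                                        read_length = 50L, seed = 2)
  # every methylated peak's sequence contains DRAC
  changed <- sim$peak_truth$peak_id[sim$peak_truth$changed]
  pk <- sim$experiment$peaks
  for (pid in changed) {
    row <- pk[pk$peak_id == pid, ]
    g <- sc$sequences[sc$sequences$gene_id == row$gene_id, ]
    sub <- substr(g$seq, row$start - g$gene_start + 1,
                  row$end - g$gene_start)
    expect_match(sub, "[AGT][AG]AC")
  }

  # adenine-free background with planting rate 0 has no DRAC anywhere
  sc0 <- simulate_sequences_and_coverage(sim, planting_rate = 0,
                                         background = "ct", seed = 2)
  expect_false(any(grepl("[AGT][AG]AC", sc0$sequences$seq)))

  # coverage integral over a peak = count * read_length (reads are
  # deposited fully inside the peak)
  cnt <- as.matrix(sim$experiment$peak_counts[-1])
  rownames(cnt) <- sim$experiment$peak_counts$peak_id
  s1 <- sim$experiment$samples[1, ]
  for (pid in pk$peak_id[1:3]) {
    row <- pk[pk$peak_id == pid, ]
    g0 <- sc$sequences$gene_start[sc$sequences$gene_id == row$gene_id]
    tr <- sc$coverage[sc$coverage$gene_id == row$gene_id &
                        sc$coverage$fraction == s1$fraction &
                        sc$coverage$condition == s1$condition &
                        sc$coverage$replicate == s1$replicate, ]
    inside <- tr$position >= (row$start - g0) & tr$position < (row$end - g0)
    expect_equal(sum(tr$depth[inside]),
                 cnt[pid, s1$sample_id] * 50L)
  }
})

test_that("generated experiments always pass data-model validation", {
  for (seed in 1:3) {
    sim <- simulate_experiment(simulation_config(
      n_genes = 8, peaks_per_gene = c(1, 2, 3), seed = seed,
      fraction_changed = 0.3, methylation_log2fc = 1))
    expect_s3_class(sim$experiment, "merip_experiment")
    expect_setequal(sim$peak_truth$peak_id,
                    sim$experiment$peak_counts$peak_id)
  }
})
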