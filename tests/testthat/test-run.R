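cfg_run <- simulation_config(n_genes = 12, peaks_per_gene = 2,
                             n_replicates_per_condition = 3,
                             fraction_changed = 0.25,
                             methylation_log2fc = 2.5, seed = 77)

test_that("simulate writes a reproducible fixture directory", {
  d1 <- file.path(withr::local_tempdir(), "sim1")
  d2 <- file.path(withr::local_tempdir(), "sim2")
  run_simulate(cfg_run, d1)
  run_simulate(cfg_run, d2)
  for (f in c("peak_counts.tsv", "gene_counts.tsv", "sample_sheet.tsv",
              "peaks.bed", "peak_gene_map.tsv", "truth_peaks.tsv",
              "truth_genes.tsv", "provenance.json")) {
    expect_true(file.exists(file.path(d1, f)), label = f)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # seed recorded in the provenance header lines
  expect_match(readLines(file.path(d1, "peak_counts.tsv"), n = 1), "seed=77")
  # refuse to clobber without force
  expect_error(run_simulate(cfg_run, d1), "force")
  expect_silent(run_simulate(cfg_run, d1, force = TRUE))
})

test_that("the test stage reproduces the in-memory pipeline end to end", {
  dir <- withr::local_tempdir()
  sim_dir <- file.path(dir, "sim")
  res_dir <- file.path(dir, "res")
  run_simulate(cfg_run, sim_dir)
  fit_disk <- run_diffmeth(sim_dir, res_dir)

  sim <- simulate_experiment(cfg_run)
  fit_mem <- diffmeth(sim$experiment)
  expect_equal(fit_disk$calls$p_trend_shrink, fit_mem$calls$p_trend_shrink)
  expect_equal(fit_disk$calls$passes_filters, fit_mem$calls$passes_filters)

  # written tables round-trip
  calls <- readr::read_tsv(file.path(res_dir, "calls.tsv"), comment = "#",
                           show_col_types = FALSE)
  expect_equal(calls$delta_log2fc, fit_disk$calls$delta_log2fc,
               tolerance = 1e-6)
  expect_true(file.exists(file.path(res_dir, "glm_trend_shrink.tsv")))
  expect_true(file.exists(file.path(res_dir, "provenance.json")))
})

test_that("the report recounts set sizes from the written tables", {
  dir <- withr::local_tempdir()
  sim_dir <- file.path(dir, "sim")
  res_dir <- file.path(dir, "res")
  run_simulate(cfg_run, sim_dir)
  fit <- run_diffmeth(sim_dir, res_dir)
  rep <- run_report(res_dir)
  g <- glance(fit)
  expect_equal(rep$n_peaks[rep$category == "union"], g$n_union)
  expect_equal(rep$n_peaks[rep$category == "intersect"], g$n_intersect)
  expect_equal(rep$n_peaks[rep$category == "passing_filters"],
               g$n_passing_filters)

  # a results dir with nothing significant still reports cleanly
  cfg0 <- simulation_config(n_genes = 6, n_replicates_per_condition = 2,
                            seed = 78)
  sim0 <- file.path(dir, "sim0"); res0 <- file.path(dir, "res0")
  run_simulate(cfg0, sim0)
  run_diffmeth(sim0, res0)
  rep0 <- run_report(res0)
  expect_true(all(rep0$n_peaks >= 0))

  # missing components are named
  expect_error(run_report(file.path(dir, "nowhere")), "calls.tsv")
})
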