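# meripdiff

Differential m6A(m) methylation analysis for MeRIP-seq count data.

MeRIP-seq detects mRNA methylation by sequencing antibody-enriched (IP)
and input libraries from the same sample; methylation appears as peaks
of IP-over-input coverage. When two conditions are compared, naive
tests of IP counts confound methylation changes with gene-expression
changes: a peak whose IP signal doubles because its transcript doubled
has not changed methylation. `meripdiff` is for analysts who have peak
intervals and per-peak/per-gene count tables and want peak-change calls
that control for expression.

## The statistic at the core

Counts for peak *i* in library *j* are negative binomial
(Var = μ + φμ²) with log-linear mean

    log μ_ij = β0_i + βIP_i · X_j^IP + βSTIM_i · X_j^STIM
             + βSTIM:IP_i · X_j^STIM X_j^IP + log s_j

where `X^IP` indicates IP libraries, `X^STIM` the treated condition,
and `s_j` is a per-library size factor (median-of-ratios, computed
within the IP and input groups separately). `βSTIM` absorbs expression
change; the interaction `βSTIM:IP` is differential methylation. Each
peak is tested by the deviance difference between this model and the
reduced model without the interaction, referred to chi-squared with
1 df, with BH FDR control. Two dispersion-moderation variants
(`trend_shrink`, `common_tagwise`) are run and combined by union or
intersect, then the published filters applied: |Δlog2FC between peak-IP
and gene-input| ≥ 1 and minimum peak read count ≥ 10 across all
replicates and conditions.

The package also provides Poisson-vs-NB goodness-of-fit assessment by
parametric bootstrap, peak reproducibility and saturation metrics, DRAC
motif enrichment, replicate-subsampling power analysis, and a
ground-truth simulator of paired IP/input NB counts.

## Worked example

Simulate an experiment with known truth (100 peaks, 4 paired
replicates per condition, 15% of peaks with a ±2 log2-unit methylation
change) and analyse it:

```r
library(meripdiff)

cfg <- simulation_config(n_genes = 50, peaks_per_gene = 2,
                         n_replicates_per_condition = 4,
                         fraction_changed = 0.15,
                         methylation_log2fc = 2, seed = 42)
sim <- simulate_experiment(cfg)
fit <- diffmeth(sim$experiment)
fit
#> <merip_diffmeth> 100 peaks, variants: trend_shrink, common_tagwise
#>   significant (union, FDR < 0.05): 15
#>   passing filters: 13
glance(fit)
#> # A tibble: 1 × 7
#>   n_peaks n_tested n_significant n_union n_intersect n_passing_filters alpha
#> 1     100      100            15      15          12                13  0.05
```

`tidy(fit)` returns one row per peak; the peaks passing all filters
show large enrichment changes with flat gene expression:

```r
dplyr::filter(tidy(fit), passes_filters) |>
  dplyr::select(peak_id, peak_ip_log2fc, gene_input_log2fc, delta_log2fc)
#>    peak_id    peak_ip_log2fc gene_input_log2fc delta_log2fc
#>  1 peak_00006           1.75            0.385          1.36
#>  2 peak_00014           1.82           -0.321          2.14
#>  ... (13 rows)
```

`peak_ip_log2fc` is the treated/control change in IP counts at the
peak, `gene_input_log2fc` the change in input counts at its gene, and
`delta_log2fc` their absolute difference — enrichment change net of
expression. Against the simulator's truth this run recovers 13 of 15
planted changes with no false positives:

```r
tt <- dplyr::left_join(tidy(fit), sim$peak_truth,
                       by = c("peak_id", "gene_id"))
table(truth = tt$changed, called = tt$passes_filters)
#>        called
#> truth   FALSE TRUE
#>   FALSE    85    0
#>   TRUE      2   13
```

`autoplot(fit)` draws the peak-vs-gene fold-change plane,
`plot_pvalue_histogram(fit)` the per-variant p-value histograms.
Directory-level wrappers `run_simulate()` / `run_diffmeth()` /
`run_report()` (and the `inst/scripts/meripdiff.R` command-line
wrapper) read and write the TSV/BED formats documented in their help
pages, with provenance headers.

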