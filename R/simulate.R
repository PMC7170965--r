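#' Simulation configuration for paired IP/input MeRIP-seq counts
#'
#' Collects the parameters of the generative model used by
#' [simulate_experiment()]. Counts are negative binomial with a
#' mean-dependent dispersion trend; each replicate owns one IP and one
#' input library sharing a replicate-level lognormal scale factor, which
#' mimics biological pairing.
#'
#' @param n_genes Number of genes.
#' @param peaks_per_gene Peaks per gene: a single integer, or a vector of
#'   length `n_genes`.
#' @param n_replicates_per_condition Paired IP/input replicates per
#'   condition (the design has `4 * n_replicates_per_condition` libraries).
#' @param baseline_gene_mean Expected input count scale for a gene; actual
#'   per-gene baselines are lognormal around this value
#'   (`baseline_log2_sd` log2 units of spread). Peak input baselines are
#'   half the gene baseline.
#' @param baseline_log2_sd Gene-to-gene spread of baselines (log2 sd).
#' @param ip_enrichment Multiplicative IP/input ratio for methylated peaks
#'   (scalar or per-peak vector).
#' @param dispersion Numeric pair `c(a0, a1)` of the trend
#'   `phi(mu) = a0 + a1 / mu` with count variance `mu + phi * mu^2`.
#' @param expression_log2fc Condition effect on gene expression (input
#'   counts): scalar applied to all genes or per-gene vector.
#' @param methylation_log2fc Condition effect on IP enrichment, the true
#'   interaction: a scalar magnitude given to the changed peaks (random
#'   sign) or a per-peak vector.
#' @param fraction_changed Fraction of peaks carrying a true methylation
#'   change (ignored when `methylation_log2fc` is a full vector).
#' @param library_size_factors Per-sample positive scale factors; `NULL`
#'   draws them lognormal (sdlog `0.2`), emulating unequal library sizes.
#' @param replicate_pair_sd sdlog of the replicate-level scale shared by a
#'   replicate's IP and input libraries (default 0.1).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 100,
                              peaks_per_gene = 2,
                              n_replicates_per_condition = 3,
                              baseline_gene_mean = 200,
                              baseline_log2_sd = 1,
                              ip_enrichment = 4,
                              dispersion = c(a0 = 0.05, a1 = 5),
                              expression_log2fc = 0,
                              methylation_log2fc = 0,
                              fraction_changed = 0,
                              library_size_factors = NULL,
                              replicate_pair_sd = 0.1,
                              seed = 1L) {
  stopifnot(n_genes >= 1, n_replicates_per_condition >= 1,
            baseline_gene_mean > 0, all(ip_enrichment > 0),
            length(dispersion) == 2, all(dispersion >= 0),
            fraction_changed >= 0, fraction_changed <= 1,
            replicate_pair_sd >= 0)
  if (!is.null(library_size_factors) && any(library_size_factors <= 0)) {
    stop("library_size_factors must be positive", call. = FALSE)
  }
  structure(as.list(environment()), class = "simulation_config")
}

# run code with a locally-seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Simulate a paired IP/input MeRIP-seq experiment with known truth
#'
#' Draws negative-binomial read counts under the log-linear model the
#' differential methylation test assumes: the expected count of a peak is
#' its baseline, times the IP enrichment ratio for IP libraries, times
#' `2^expression_log2fc` in treated samples (gene expression effect), and
#' additionally times `2^methylation_log2fc` in treated IP samples (the
#' true interaction). Per-observation dispersion follows the trend
#' `phi(mu) = a0 + a1/mu`.
#'
#' @param config A [simulation_config()].
#' @return A list with elements:
#'   * `experiment`: a [merip_experiment()];
#'   * `peak_truth`: tibble `peak_id`, `gene_id`, `methylation_log2fc`,
#'     `changed` (`TRUE` where the effect is nonzero);
#'   * `gene_truth`: tibble `gene_id`, `expression_log2fc`.
#' @examples
#' sim <- simulate_experiment(simulation_config(n_genes = 10, seed = 42,
#'   fraction_changed = 0.3, methylation_log2fc = 2))
#' table(sim$peak_truth$changed)
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(config$seed, simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(cfg) {
  n_rep <- cfg$n_replicates_per_condition
  ppg <- rep_len(cfg$peaks_per_gene, cfg$n_genes)
  n_peaks <- sum(ppg)
  gene_id <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  peak_gene <- rep(gene_id, ppg)
  peak_id <- sprintf("peak_%05d", seq_len(n_peaks))

  # sample sheet: conditions x fractions x replicates, input listed with IP
  samples <- tidyr::expand_grid(
    condition = c("control", "treated"),
    replicate = seq_len(n_rep),
    fraction = c("input", "IP")
  ) |>
    dplyr::mutate(sample_id = paste(.data$condition, .data$fraction,
                                    .data$replicate, sep = "_")) |>
    dplyr::select("sample_id", "fraction", "condition", "replicate")

  n_samp <- nrow(samples)
  sf <- cfg$library_size_factors
  if (is.null(sf)) sf <- stats::rlnorm(n_samp, 0, 0.2)
  sf <- rep_len(sf, n_samp)
  # shared replicate-level scale pairs each IP library with its input
  pair_key <- paste(samples$condition, samples$replicate)
  pair_scale <- stats::rlnorm(length(unique(pair_key)), 0, cfg$replicate_pair_sd)
  names(pair_scale) <- unique(pair_key)
  scale_j <- sf * pair_scale[pair_key]

  gene_base <- cfg$baseline_gene_mean *
    2^stats::rnorm(cfg$n_genes, 0, cfg$baseline_log2_sd)
  names(gene_base) <- gene_id
  peak_base <- 0.5 * gene_base[peak_gene]
  enrich <- rep_len(cfg$ip_enrichment, n_peaks)

  expr_lfc <- rep_len(cfg$expression_log2fc, cfg$n_genes)
  if (length(cfg$methylation_log2fc) == n_peaks) {
    meth_lfc <- cfg$methylation_log2fc
  } else {
    meth_lfc <- numeric(n_peaks)
    n_changed <- round(cfg$fraction_changed * n_peaks)
    if (n_changed > 0) {
      idx <- sample.int(n_peaks, n_changed)
      meth_lfc[idx] <- cfg$methylation_log2fc[1] *
        sample(c(-1, 1), n_changed, replace = TRUE)
    }
  }

  is_ip <- samples$fraction == "IP"
  is_trt <- samples$condition == "treated"
  a0 <- cfg$dispersion[[1]]; a1 <- cfg$dispersion[[2]]

  draw <- function(base, ip_factor, lfc_expr, lfc_meth) {
    # base: per-feature baseline; returns features x samples count matrix
    mu <- outer(base, scale_j) *
      (1 + outer(ip_factor - 1, as.numeric(is_ip))) # ip_factor where IP, 1 else
    mu <- mu * 2^(outer(lfc_expr, as.numeric(is_trt)))
    mu <- mu * 2^(outer(lfc_meth, as.numeric(is_trt & is_ip)))
    phi <- a0 + a1 / mu
    cnt <- stats::rnbinom(length(mu), mu = mu, size = 1 / phi)
    matrix(cnt, nrow = length(base))
  }

  gene_counts <- draw(gene_base, rep(1, cfg$n_genes), expr_lfc,
                      numeric(cfg$n_genes))
  peak_counts <- draw(peak_base, enrich, expr_lfc[match(peak_gene, gene_id)],
                      meth_lfc)

  # lay genes along one chromosome; peaks inside their gene
  gene_len <- 2000L
  gene_start <- (seq_len(cfg$n_genes) - 1L) * (gene_len + 500L)
  peak_width <- 150L
  offset_in_gene <- unlist(lapply(ppg, function(k) {
    seq(200L, gene_len - peak_width - 200L, length.out = max(k, 1))[seq_len(k)]
  }))
  peak_start <- as.integer(gene_start[match(peak_gene, gene_id)] +
                             round(offset_in_gene))
  peaks <- tibble::tibble(
    chrom = "chr1", start = peak_start, end = peak_start + peak_width,
    strand = "+", peak_id = peak_id, gene_id = peak_gene
  )

  pk_tbl <- tibble::as_tibble(as.data.frame(peak_counts))
  names(pk_tbl) <- samples$sample_id
  pk_tbl <- dplyr::bind_cols(tibble::tibble(peak_id = peak_id), pk_tbl)
  gn_tbl <- tibble::as_tibble(as.data.frame(gene_counts))
  names(gn_tbl) <- samples$sample_id
  gn_tbl <- dplyr::bind_cols(tibble::tibble(gene_id = gene_id), gn_tbl)

  samples$library_size <- colSums(as.matrix(pk_tbl[-1])) +
    colSums(as.matrix(gn_tbl[-1]))

  list(
    experiment = merip_experiment(pk_tbl, gn_tbl, peaks, samples),
    peak_truth = tibble::tibble(peak_id = peak_id, gene_id = peak_gene,
                                methylation_log2fc = meth_lfc,
                                changed = meth_lfc != 0),
    gene_truth = tibble::tibble(gene_id = gene_id,
                                expression_log2fc = expr_lfc)
  )
}

#' Simulate a null experiment (no true effects)
#'
#' Identical to [simulate_experiment()] with all expression and methylation
#' effects forced to zero; condition labels are then exchangeable and a
#' well-calibrated test should give uniform p-values downstream.
#'
#' @inheritParams simulate_experiment
#' @return As [simulate_experiment()]; `peak_truth$changed` is all `FALSE`.
#' @export
simulate_null <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  config$expression_log2fc <- 0
  config$methylation_log2fc <- 0
  config$fraction_changed <- 0
  simulate_experiment(config)
}

#' Simulate per-replicate peak sets with imperfect detection
#'
#' A universe of `n_true_sites` non-overlapping genomic intervals is
#' created, and each replicate detects each site independently with
#' probability `detection_prob`; this is the generative model behind
#' replicate saturation and recurrence curves.
#'
#' @param n_replicates Number of replicate peak sets.
#' @param n_true_sites Size of the true site universe.
#' @param detection_prob Per-replicate detection probability in (0, 1].
#' @param seed Integer seed.
#' @return A list of `n_replicates` peak tibbles (subsets of the universe);
#'   the universe itself is attached as attribute `"universe"`.
#' @export
simulate_peak_sets <- function(n_replicates, n_true_sites, detection_prob,
                               seed = 1L) {
  stopifnot(detection_prob > 0, detection_prob <= 1,
            n_replicates >= 1, n_true_sites >= 1)
  with_local_seed(seed, {
    width <- 200L
    gap <- 300L
    start <- (seq_len(n_true_sites) - 1L) * (width + gap)
    universe <- tibble::tibble(
      chrom = "chr1", start = start, end = start + width, strand = ".",
      peak_id = sprintf("site_%05d", seq_len(n_true_sites)),
      gene_id = sprintf("gene_%05d", seq_len(n_true_sites))
    )
    sets <- lapply(seq_len(n_replicates), function(r) {
      detected <- stats::runif(n_true_sites) <= detection_prob
      universe[detected, ]
    })
    attr(sets, "universe") <- universe
    sets
  })
}

#' Simulate gene sequences with planted DRAC motifs and coverage tracks
#'
#' Generates a random DNA sequence per gene and, for peaks flagged as
#' methylated, plants one DRAC motif (`[AGT][AG]AC`) inside the peak with
#' probability `planting_rate`. Per-replicate coverage tracks are built by
#' placing each counted read (of length `read_length`) uniformly within its
#' peak, so the coverage integral over a peak equals `count * read_length`.
#'
#' @param sim Output of [simulate_experiment()].
#' @param planting_rate Probability that a methylated peak receives a
#'   planted motif, in \[0, 1\].
#' @param read_length Read length in bases used for coverage deposition.
#' @param background One of `"acgt"` (uniform DNA) or `"ct"` (C/T-only:
#'   with no adenine a DRAC cannot occur, giving a motif-free background
#'   for negative controls).
#' @param seed Integer seed.
#' @return A list with `sequences` (tibble `gene_id`, `seq`; coordinates of
#'   a peak within its gene are `start - gene_start`) and `coverage` (long
#'   tibble `gene_id`, `fraction`, `condition`, `replicate`, `position`,
#'   `depth`, positions 0-based relative to gene start).
#' @export
simulate_sequences_and_coverage <- function(sim, planting_rate = 1,
                                            read_length = 50L,
                                            background = c("acgt", "ct"),
                                            seed = 1L) {
  stopifnot(planting_rate >= 0, planting_rate <= 1)
  background <- match.arg(background)
  exp <- sim$experiment
  with_local_seed(seed, {
    alphabet <- if (background == "acgt") c("A", "C", "G", "T") else c("C", "T")
    genes <- unique(exp$peaks$gene_id)
    gene_len <- 2000L
    gene_start <- vapply(genes, function(g) {
      min(exp$peaks$start[exp$peaks$gene_id == g]) - 200L
    }, 0L)

    seqs <- vapply(genes, function(g) {
      paste(sample(alphabet, gene_len, replace = TRUE), collapse = "")
    }, "")

    # plant DRAC inside methylated peaks
    meth <- if (any(sim$peak_truth$changed)) {
      sim$peak_truth$peak_id[sim$peak_truth$changed]
    } else {
      sim$peak_truth$peak_id # no changed peaks: treat all as methylated
    }
    for (pid in meth) {
      if (stats::runif(1) > planting_rate) next
      row <- exp$peaks[exp$peaks$peak_id == pid, ]
      g <- row$gene_id
      rel <- row$start - gene_start[[g]]
      pos <- rel + sample.int(row$end - row$start - 4L, 1)
      motif <- paste0(sample(c("A", "G", "T"), 1), sample(c("A", "G"), 1), "AC")
      substr(seqs[[g]], pos + 1, pos + 4) <- motif
    }

    # coverage: deposit each counted read uniformly within its peak
    cnt <- count_matrix(exp$peak_counts)
    cov_rows <- list()
    for (g in genes) {
      prows <- which(exp$peaks$gene_id == g)
      for (j in seq_len(nrow(exp$samples))) {
        depth <- integer(gene_len)
        for (p in prows) {
          k <- cnt[exp$peaks$peak_id[p], j]
          if (k == 0) next
          rel <- exp$peaks$start[p] - gene_start[[g]]
          w <- exp$peaks$end[p] - exp$peaks$start[p]
          starts <- rel + sample.int(w - read_length + 1L, k, replace = TRUE) - 1L
          for (s in starts) {
            idx <- (s + 1):(s + read_length)
            depth[idx] <- depth[idx] + 1L
          }
        }
        cov_rows[[length(cov_rows) + 1]] <- tibble::tibble(
          gene_id = g,
          fraction = exp$samples$fraction[j],
          condition = exp$samples$condition[j],
          replicate = exp$samples$replicate[j],
          position = 0:(gene_len - 1L),
          depth = depth
        )
      }
    }
    list(
      sequences = tibble::tibble(gene_id = genes, seq = unname(seqs),
                                 gene_start = unname(gene_start)),
      coverage = dplyr::bind_rows(cov_rows)
    )
  })
}
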