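# Shared fixture builders. All fixtures are constructed in code; nothing
# is read from disk except files the tests themselves write to tempdirs.

# a minimal paired sample sheet: n_rep replicates per condition,
# IP + input each
make_samples <- function(n_rep = 2) {
  tidyr::expand_grid(
    condition = c("control", "treated"),
    replicate = seq_len(n_rep),
    fraction = c("input", "IP")
  ) |>
    dplyr::mutate(sample_id = paste(condition, fraction, replicate,
                                    sep = "_")) |>
    dplyr::select(sample_id, fraction, condition, replicate)
}

# experiment with explicit count matrices (peaks x samples)
make_experiment <- function(peak_mat, n_rep = 2, gene_mat = NULL) {
  samples <- make_samples(n_rep)
  stopifnot(ncol(peak_mat) == nrow(samples))
  n_peaks <- nrow(peak_mat)
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = (seq_len(n_peaks) - 1L) * 500L,
    end = (seq_len(n_peaks) - 1L) * 500L + 150L,
    strand = "+",
    peak_id = sprintf("peak_%03d", seq_len(n_peaks)),
    gene_id = sprintf("gene_%03d", seq_len(n_peaks))
  )
  if (is.null(gene_mat)) gene_mat <- peak_mat
  pk <- tibble::as_tibble(as.data.frame(peak_mat))
  names(pk) <- samples$sample_id
  pk <- dplyr::bind_cols(tibble::tibble(peak_id = peaks$peak_id), pk)
  gn <- tibble::as_tibble(as.data.frame(gene_mat))
  names(gn) <- samples$sample_id
  gn <- dplyr::bind_cols(tibble::tibble(gene_id = peaks$gene_id), gn)
  merip_experiment(pk, gn, peaks, samples)
}

# peak tibble from a matrix of (start, end) rows, half-open coordinates
make_peaks <- function(coords, chrom = "chr1", gene_id = NULL) {
  n <- nrow(coords)
  tibble::tibble(
    chrom = chrom, start = as.integer(coords[, 1]),
    end = as.integer(coords[, 2]), strand = ".",
    peak_id = sprintf("p%03d", seq_len(n)),
    gene_id = gene_id %||% sprintf("g%03d", seq_len(n))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force per-base union of intervals (oracle for merge)
brute_force_union <- function(peak_sets, max_base = 1e4) {
  all <- dplyr::bind_rows(peak_sets)
  covered <- logical(max_base)
  for (i in seq_len(nrow(all))) {
    covered[(all$start[i] + 1):all$end[i]] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

# brute-force NB log-likelihood maximizer (oracle for the IRLS fit)
optim_nb_fit <- function(y, X, offset, phi) {
  nll <- function(b) {
    mu <- exp(drop(X %*% b) + offset)
    if (phi <= 0) -sum(stats::dpois(y, mu, log = TRUE))
    else -sum(stats::dnbinom(y, mu = mu, size = 1 / phi, log = TRUE))
  }
  init <- rep(0, ncol(X))
  init[1] <- log(mean(y) + 0.5)
  opt <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$par
}
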