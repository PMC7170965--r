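# Poisson vs negative-binomial model assessment by maximum likelihood and
# parametric bootstrap of the mean per-peak log-likelihood.

#' Poisson maximum-likelihood fit for one count vector
#'
#' @param counts Non-negative integer vector (>= 2 observations).
#' @return List with `lambda` (the sample mean — the closed-form MLE) and
#'   `loglik`. The convention `0 * log(0) = 0` applies, so an all-zero
#'   vector has `lambda = 0` and log-likelihood 0.
#' @export
fit_poisson_mle <- function(counts) {
  if (length(counts) < 2) stop("need at least 2 observations", call. = FALSE)
  lambda <- mean(counts)
  list(lambda = lambda,
       loglik = sum(stats::dpois(counts, lambda, log = TRUE)))
}

#' Negative-binomial maximum-likelihood fit for one count vector
#'
#' The mean MLE is the sample mean for any fixed dispersion, so the
#' likelihood is profiled and maximized over the dispersion alone on
#' \[0, 10\] (Brent's method on the log scale). When the sample variance
#' does not exceed the mean the boundary estimate `phi = 0` is returned
#' and the fit equals the Poisson fit.
#'
#' @param counts Non-negative integer vector (>= 3 observations).
#' @return List with `mu`, `phi`, `loglik` and `boundary` (`TRUE` when
#'   `phi` sits at 0).
#' @export
fit_negbin_mle <- function(counts) {
  if (length(counts) < 3) stop("need at least 3 observations", call. = FALSE)
  mu <- mean(counts)
  if (mu == 0 || stats::var(counts) <= mu) {
    return(list(mu = mu, phi = 0,
                loglik = fit_poisson_mle(counts)$loglik, boundary = TRUE))
  }
  obj <- function(log_phi) {
    sum(stats::dnbinom(counts, mu = mu, size = exp(-log_phi), log = TRUE))
  }
  opt <- stats::optimize(obj, c(log(1e-8), log(10)), maximum = TRUE)
  pois_ll <- fit_poisson_mle(counts)$loglik
  if (pois_ll >= opt$objective) {
    return(list(mu = mu, phi = 0, loglik = pois_ll, boundary = TRUE))
  }
  list(mu = mu, phi = exp(opt$maximum), loglik = opt$objective,
       boundary = FALSE)
}

#' Parametric-bootstrap assessment of a count model
#'
#' Fits the chosen model to each peak's counts by maximum likelihood,
#' pooling the samples of each fraction-by-condition cell (so condition
#' effects do not inflate the dispersion), and compares the observed mean
#' per-peak log-likelihood against `n_sim` simulated data sets drawn from
#' the fitted models with parameters held fixed. A percentile near 0 means
#' the observed data are far less likely than data the model itself
#' generates — the model fails to capture the count distribution.
#'
#' @param experiment A [merip_experiment()].
#' @param model `"poisson"` or `"negbin"`.
#' @param n_sim Number of parametric-bootstrap generations (default 500;
#'   fewer than 20 is refused as the percentile is then meaningless).
#' @param seed Integer seed for the bootstrap draws.
#' @return Object of class `fit_report`: list with `model`, `n_sim`,
#'   `seed`, `fits` (per peak-cell tibble of estimates),
#'   `observed_mean_loglik`, `simulated_mean_logliks` (length `n_sim`),
#'   `percentile_of_observed` (percent of simulated means at or below the
#'   observed mean, in \[0, 100\]).
#' @export
bootstrap_loglik_percentile <- function(experiment,
                                        model = c("poisson", "negbin"),
                                        n_sim = 500, seed = 1L) {
  model <- match.arg(model)
  if (n_sim < 20) {
    stop("n_sim < 20: percentile would be meaningless", call. = FALSE)
  }
  counts <- count_matrix(experiment$peak_counts)
  s <- experiment$samples
  cell <- paste(s$fraction, s$condition, sep = ".")
  cells <- split(seq_len(nrow(s)), cell)

  fits <- list()
  for (cn in names(cells)) {
    idx <- cells[[cn]]
    if (length(idx) < 2) next
    for (i in seq_len(nrow(counts))) {
      y <- counts[i, idx]
      f <- if (model == "poisson") {
        fp <- fit_poisson_mle(y)
        list(mu = fp$lambda, phi = NA_real_, loglik = fp$loglik)
      } else {
        fn <- fit_negbin_mle(y)
        list(mu = fn$mu, phi = fn$phi, loglik = fn$loglik)
      }
      fits[[length(fits) + 1]] <- tibble::tibble(
        peak_id = rownames(counts)[i], cell = cn, n_obs = length(idx),
        mu = f$mu, phi = f$phi, loglik = f$loglik)
    }
  }
  fits <- dplyr::bind_rows(fits)

  # observed mean log-likelihood across peaks (per-peak loglik summed
  # over that peak's cells)
  per_peak <- fits |>
    dplyr::summarise(loglik = sum(.data$loglik), .by = "peak_id")
  observed <- mean(per_peak$loglik)

  sim_means <- with_local_seed(seed, {
    vapply(seq_len(n_sim), function(b) {
      ll <- vapply(seq_len(nrow(fits)), function(k) {
        mu <- fits$mu[k]; n <- fits$n_obs[k]
        if (model == "poisson" || fits$phi[k] == 0 || is.na(fits$phi[k])) {
          ysim <- stats::rpois(n, mu)
          sum(stats::dpois(ysim, mu, log = TRUE))
        } else {
          size <- 1 / fits$phi[k]
          ysim <- stats::rnbinom(n, mu = mu, size = size)
          sum(stats::dnbinom(ysim, mu = mu, size = size, log = TRUE))
        }
      }, 0)
      # mean over peaks of per-peak (cell-summed) logliks
      sum(ll) / nrow(per_peak)
    }, 0)
  })

  structure(
    list(model = model, n_sim = n_sim, seed = seed, fits = fits,
         observed_mean_loglik = observed,
         simulated_mean_logliks = sim_means,
         percentile_of_observed = 100 * mean(sim_means <= observed)),
    class = "fit_report"
  )
}

#' @export
print.fit_report <- function(x, ...) {
  cat("<fit_report> model: ", x$model, ", n_sim: ", x$n_sim, "\n", sep = "")
  cat("  observed mean log-likelihood: ",
      format(x$observed_mean_loglik, digits = 6), "\n", sep = "")
  cat("  percentile among simulations: ",
      format(x$percentile_of_observed, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
glance.fit_report <- function(x, ...) {
  tibble::tibble(model = x$model, n_sim = x$n_sim,
                 observed_mean_loglik = x$observed_mean_loglik,
                 percentile_of_observed = x$percentile_of_observed)
}

#' Per-peak mean-variance summary
#'
#' Sample moments of the counts within each fraction-by-condition cell;
#' the fraction of peak-cells with variance exceeding the mean indicates
#' overdispersion (a Poisson model predicts about half under sampling
#' noise, overdispersed data push the fraction toward 1). At least 3
#' replicates per cell are recommended for a stable variance.
#'
#' @param experiment A [merip_experiment()].
#' @return List with `moments` (tibble `peak_id`, `cell`, `mean`,
#'   `variance`, `overdispersed`) and `fraction_overdispersed`.
#' @export
overdispersion_summary <- function(experiment) {
  counts <- count_matrix(experiment$peak_counts)
  s <- experiment$samples
  cell <- paste(s$fraction, s$condition, sep = ".")
  out <- list()
  for (cn in unique(cell)) {
    idx <- cell == cn
    if (sum(idx) < 2) next
    m <- rowMeans(counts[, idx, drop = FALSE])
    v <- apply(counts[, idx, drop = FALSE], 1, stats::var)
    out[[cn]] <- tibble::tibble(peak_id = rownames(counts), cell = cn,
                                mean = m, variance = v,
                                overdispersed = v > m)
  }
  moments <- dplyr::bind_rows(out)
  list(moments = moments,
       fraction_overdispersed = mean(moments$overdispersed))
}
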