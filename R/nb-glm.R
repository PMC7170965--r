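# Negative-binomial GLM with log link, fixed dispersion and offsets.
# Parameterization: Var(Y) = mu + phi * mu^2 (phi = 0 is Poisson).

nb_loglik <- function(y, mu, phi) {
  if (phi <= 0) return(sum(stats::dpois(y, mu, log = TRUE)))
  sum(stats::dnbinom(y, mu = mu, size = 1 / phi, log = TRUE))
}

# unit deviance summed over observations; Poisson limit at phi = 0
nb_deviance <- function(y, mu, phi) {
  term <- ifelse(y > 0, y * log(y / mu), 0)
  if (phi <= 0) {
    2 * sum(term - (y - mu))
  } else {
    2 * sum(term - (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu)))
  }
}

# IRLS fit; X must have full column rank
nb_irls <- function(y, X, offset = NULL, phi = 0, max_iter = 100L,
                    tol = 1e-8, beta_init = NULL) {
  n <- length(y)
  if (is.null(offset)) offset <- numeric(n)
  if (all(y == 0)) {
    return(list(beta = rep(NA_real_, ncol(X)), mu = rep(0, n),
                deviance = 0, loglik = 0, converged = FALSE,
                degenerate = TRUE, iter = 0L))
  }
  if (is.null(beta_init)) {
    # initialize from log of shifted response
    z0 <- log(pmax(y, 0.5)) - offset
    beta <- stats::lm.fit(X, z0)$coefficients
  } else {
    beta <- beta_init
  }
  beta[is.na(beta)] <- 0
  eta <- drop(X %*% beta) + offset
  mu <- pmin(exp(eta), 1e12)
  dev <- nb_deviance(y, mu, phi)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    w <- mu / (1 + phi * mu)          # working weights for log link
    z <- (eta - offset) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    beta_new[is.na(beta_new)] <- 0
    # step-halving if deviance worsens
    step <- 1
    repeat {
      b <- beta + step * (beta_new - beta)
      eta_try <- drop(X %*% b) + offset
      mu_try <- pmin(exp(pmin(eta_try, 30)), 1e12)
      dev_try <- nb_deviance(y, mu_try, phi)
      if (is.finite(dev_try) && dev_try <= dev + 1e-12) break
      step <- step / 2
      if (step < 1e-8) { b <- beta; eta_try <- eta; mu_try <- mu
        dev_try <- dev; break }
    }
    rel <- abs(dev - dev_try) / (abs(dev_try) + 0.1)
    beta <- b; eta <- eta_try; mu <- mu_try
    if (rel < tol) { converged <- TRUE; dev <- dev_try; break }
    dev <- dev_try
  }
  list(beta = beta, mu = mu, deviance = dev,
       loglik = nb_loglik(y, mu, phi), converged = converged,
       degenerate = FALSE, iter = iter)
}

#' Build the GLM design for a paired IP/input two-condition experiment
#'
#' Full model: `log mu = b0 + b_IP X_IP + b_STIM X_STIM + b_STIM:IP
#' X_STIM X_IP`; the reduced model drops the interaction. The per-sample
#' offset is the log size factor.
#'
#' @param samples Sample sheet tibble (`fraction`, `condition` columns).
#' @param size_factors Tibble from [estimate_size_factors()] or a numeric
#'   vector in sample order.
#' @return List with `X_full`, `X_reduced` (model matrices) and `offset`.
#' @export
glm_design <- function(samples, size_factors = NULL) {
  x_ip <- as.numeric(samples$fraction == "IP")
  x_stim <- as.numeric(samples$condition == "treated")
  cells <- table(x_ip, x_stim)
  if (length(cells) < 4 || any(cells == 0)) {
    stop("design is not full rank: need at least one sample in each of the ",
         "four IP/input x treated/control cells", call. = FALSE)
  }
  X_full <- cbind(beta0 = 1, beta_ip = x_ip, beta_stim = x_stim,
                  beta_interaction = x_ip * x_stim)
  X_reduced <- X_full[, 1:3, drop = FALSE]
  offset <- if (is.null(size_factors)) {
    numeric(nrow(samples))
  } else if (is.data.frame(size_factors)) {
    log(size_factors$size_factor[match(samples$sample_id,
                                       size_factors$sample_id)])
  } else {
    log(size_factors)
  }
  list(X_full = X_full, X_reduced = X_reduced, offset = offset)
}

#' Fit the negative-binomial GLM to one peak's counts
#'
#' Maximizes the NB log-likelihood with log link, fixed dispersion and
#' per-sample offsets by iteratively reweighted least squares with
#' step-halving. The fit is flagged non-converged when the relative
#' deviance change still exceeds `1e-8` after 100 iterations.
#'
#' @param counts Integer count vector for one peak (samples in design
#'   order).
#' @param design Output of [glm_design()].
#' @param dispersion Dispersion `phi >= 0` (0 gives the Poisson fit).
#' @param model `"full"` (with interaction) or `"reduced"`.
#' @return A list with `coefficients` (named, natural-log scale),
#'   `deviance`, `loglik`, `fitted`, `converged`, `degenerate`.
#' @export
fit_nb_glm <- function(counts, design, dispersion = 0,
                       model = c("full", "reduced")) {
  model <- match.arg(model)
  stopifnot(dispersion >= 0)
  X <- if (model == "full") design$X_full else design$X_reduced
  fit <- nb_irls(counts, X, design$offset, dispersion)
  names(fit$beta) <- colnames(X)
  list(coefficients = fit$beta, deviance = fit$deviance,
       loglik = fit$loglik, fitted = fit$mu, converged = fit$converged,
       degenerate = fit$degenerate)
}

#' Likelihood-ratio test for the interaction term
#'
#' The statistic is the difference in deviances between the reduced and
#' full model (equivalently twice the log-likelihood difference when both
#' use the same dispersion), referred to a chi-squared distribution with
#' one degree of freedom. Negative differences arising from numerical
#' noise are clipped at zero (tolerance `1e-6`).
#'
#' @param full,reduced Fits from [fit_nb_glm()] on the same counts with
#'   the same dispersion.
#' @return List with `lrt_stat` and `p_value`; `p_value` is `NA` when
#'   either fit failed to converge or is degenerate.
#' @export
lrt_interaction <- function(full, reduced) {
  stat <- reduced$deviance - full$deviance
  if (is.finite(stat) && stat < 0 && stat > -1e-6) stat <- 0
  ok <- isTRUE(full$converged) && isTRUE(reduced$converged) &&
    !isTRUE(full$degenerate) && !isTRUE(reduced$degenerate)
  p <- if (ok) stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
       else NA_real_
  list(lrt_stat = max(stat, 0), p_value = p)
}
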