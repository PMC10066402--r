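#' Highest-density interval of a sample
#'
#' The narrowest contiguous interval containing `ceiling(prob * n)` of the
#' draws: all sorted windows of that size are scanned and the shortest one
#' returned (first on ties).
#'
#' @param x Numeric vector of at least 100 draws.
#' @param prob Interval mass, strictly inside (0, 1). Default 0.80, the
#'   relevance threshold used throughout.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(x, prob = 0.80) {
  if (length(x) < 100) abort("hdi needs at least 100 draws")
  if (prob <= 0 || prob >= 1) abort("`prob` must be strictly inside (0, 1)")
  s <- sort(x)
  n <- length(s)
  m <- ceiling(prob * n)
  widths <- s[m:n] - s[1:(n - m + 1)]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + m - 1])
}

#' Summarize a fitted outcome model's posterior
#'
#' Per coefficient: posterior mean (PM) over pooled chains, HDI bounds at
#' `hdi_prob`, the sex stratum for atom slopes, split-Rhat, and the
#' relevance flag — true exactly when the HDI excludes zero.
#'
#' @param fit An `outcome_fit`.
#' @param hdi_prob HDI mass (defaults to the fit's setting, normally 0.80).
#' @return A `posterior_summary` tibble: `term`, `stratum`, `atom`, `pm`,
#'   `sd`, `hdi_lower`, `hdi_upper`, `relevant`, `rhat`.
#' @export
summarize_posterior <- function(fit, hdi_prob = fit$hdi_prob) {
  pool <- pooled_draws(fit)
  terms <- dplyr::bind_rows(
    fit$terms[, c("term", "stratum", "atom")],
    tibble::tibble(term = "sigma", stratum = "model", atom = NA_integer_))
  out <- purrr::map_dfr(seq_len(ncol(pool)), function(j) {
    h <- hdi(pool[, j], hdi_prob)
    tibble::tibble(
      term = colnames(pool)[j],
      pm = mean(pool[, j]),
      sd = stats::sd(pool[, j]),
      hdi_lower = h[["lower"]],
      hdi_upper = h[["upper"]],
      relevant = !(h[["lower"]] <= 0 && h[["upper"]] >= 0),
      rhat = fit$rhat[[j]]
    )
  })
  out <- dplyr::left_join(terms, out, by = "term")
  class(out) <- c("posterior_summary", class(out))
  attr(out, "hdi_prob") <- hdi_prob
  out
}

#' @rdname summarize_posterior
#' @param x An `outcome_fit`.
#' @param ... Passed on.
#' @export
tidy.outcome_fit <- function(x, ...) summarize_posterior(x, ...)

#' One-row model-level summary
#'
#' @param x An `outcome_fit`.
#' @param ... Unused.
#' @return Tibble with sample size, sampler settings, max split-Rhat,
#'   convergence flag, posterior-mean sigma, and the variance-ratio Bayesian
#'   R^2 (secondary fit statistic).
#' @export
glance.outcome_fit <- function(x, ...) {
  pool <- pooled_draws(x)
  if (nrow(pool) > 500) {
    pool <- pool[round(seq(1, nrow(pool), length.out = 500)), , drop = FALSE]
  }
  sig <- pool[, "sigma"]
  beta <- pool[, setdiff(colnames(pool), "sigma"), drop = FALSE]
  mu <- beta %*% t(x$design$X)
  var_mu <- apply(mu, 1, stats::var)
  tibble::tibble(
    n = x$n, n_terms = x$p, chains = x$chains, draws = x$n_draws,
    max_rhat = max(x$rhat, na.rm = TRUE), converged = x$converged,
    sigma = mean(sig),
    bayes_r2 = mean(var_mu / (var_mu + sig^2))
  )
}

#' Posterior-predictive coefficient of determination
#'
#' Simulates replicated outcomes from the fitted model (one replicate per
#' retained posterior draw, including likelihood noise), uses the mean of
#' the replicates per patient as the prediction, and reports
#' `R^2 = 1 - SS_res / SS_tot` against the observed outcome.
#'
#' @param fit An `outcome_fit`.
#' @param seed Integer seed for the replicate noise.
#' @param max_draws Cap on posterior draws used (evenly thinned;
#'   default 2000).
#' @return R^2 as a single number, with the variance-ratio Bayesian R^2
#'   attached as attribute `"bayes_r2"`.
#' @export
posterior_predictive_r2 <- function(fit, seed = 1, max_draws = 2000) {
  y <- fit$design$y
  X <- fit$design$X
  if (stats::var(y) == 0) abort("outcome has zero variance: R^2 undefined")
  pool <- pooled_draws(fit)
  if (nrow(pool) > max_draws) {
    pool <- pool[round(seq(1, nrow(pool), length.out = max_draws)), ,
                 drop = FALSE]
  }
  sig <- pool[, "sigma"]
  beta <- pool[, setdiff(colnames(pool), "sigma"), drop = FALSE]
  set.seed(seed)
  n <- length(y)
  acc <- numeric(n)
  var_mu <- numeric(nrow(pool))
  for (d in seq_len(nrow(pool))) {
    mu <- drop(X %*% beta[d, ])
    acc <- acc + mu + rnorm(n, 0, sig[d])
    var_mu[d] <- stats::var(mu)
  }
  pred <- acc / nrow(pool)
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  attr(r2, "bayes_r2") <- mean(var_mu / (var_mu + sig^2))
  r2
}
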