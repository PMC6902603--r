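#' Sample autocorrelation at given lags
#'
#' Standard sample autocorrelation with overall-mean centering and lag-0
#' normalization. A constant chain has no defined autocorrelation and is
#' reported as `NA`.
#'
#' @param chain numeric vector of draws.
#' @param lags integer lags (each `< length(chain)`).
#' @return Named numeric vector of autocorrelations.
#' @export
autocorr <- function(chain, lags = c(1, 5, 10, 50)) {
  stopifnot(all(lags < length(chain)), all(lags >= 0))
  if (var(chain) == 0) {
    return(setNames(rep(NA_real_, length(lags)), paste0("lag", lags)))
  }
  ac <- acf(chain, lag.max = max(lags), plot = FALSE, demean = TRUE)$acf[, 1, 1]
  setNames(ac[lags + 1], paste0("lag", lags))
}

# Spectral density of the chain at frequency zero, from an autoregressive
# fit with AIC-selected order (the coda::spectrum0.ar approach).
spectrum0_ar <- function(chain) {
  n <- length(chain)
  fit <- ar(chain, aic = TRUE, order.max = min(n - 1L,
                                               floor(10 * log10(n))))
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Effective sample size of an MCMC chain
#'
#' ESS = n * var(chain) / S(0), where S(0) is the spectral density of the
#' chain at frequency zero estimated from an AR fit with AIC-chosen order.
#' The value is not capped at the chain length. A constant chain returns 0.
#'
#' @param chain numeric vector of at least 100 draws.
#' @return Scalar effective sample size.
#' @export
effective_sample_size <- function(chain) {
  if (length(chain) < 100) abort("need at least 100 draws for ESS")
  v <- var(chain)
  if (v == 0) return(0)
  length(chain) * v / spectrum0_ar(chain)
}

#' Batch-means effective sample size (robustness companion)
#'
#' Non-spectral alternative: split the chain into sqrt(n) batches and set
#' ESS = n * var(chain) / (b * var(batch means)). Reported alongside the
#' AR-spectral estimate as a robustness column.
#'
#' @inheritParams effective_sample_size
#' @export
ess_batch_means <- function(chain) {
  n <- length(chain)
  if (n < 100) abort("need at least 100 draws for ESS")
  v <- var(chain)
  if (v == 0) return(0)
  b <- floor(sqrt(n))
  nb <- floor(n / b)
  bm <- vapply(seq_len(nb), function(i) {
    mean(chain[((i - 1) * b + 1):(i * b)])
  }, numeric(1))
  n * v / (b * var(bm))
}

#' Monte Carlo standard error of the posterior mean
#'
#' Posterior SD / sqrt(ESS) — the sampling-error uncertainty of the
#' reported posterior mean.
#'
#' @inheritParams effective_sample_size
#' @param ess optional precomputed effective sample size.
#' @export
mcse <- function(chain, ess = NULL) {
  if (is.null(ess)) ess <- effective_sample_size(chain)
  if (ess <= 0) return(NA_real_)
  sd(chain) / sqrt(ess)
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' G1 = g1 * sqrt(n (n - 1)) / (n - 2), where g1 = m3 / m2^(3/2).
#'
#' @param x numeric vector (length >= 3).
#' @export
sample_skewness <- function(x) {
  n <- length(x)
  stopifnot(n >= 3)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  if (m2 == 0) return(NA_real_)
  (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
}

#' Posterior summary of a scalar chain
#'
#' Mean, SD, adjusted skewness, plus kernel-density points and the trace
#' series for plotting.
#'
#' @inheritParams effective_sample_size
#' @return List with `stats` (one-row tibble), `density` (tibble x, y) and
#'   `trace` (tibble iteration, value).
#' @export
posterior_summary <- function(chain) {
  stopifnot(length(chain) >= 10)
  d <- density(chain)
  list(
    stats = tibble::tibble(mean = mean(chain), sd = sd(chain),
                           skewness = sample_skewness(chain)),
    density = tibble::tibble(x = d$x, y = d$y),
    trace = tibble::tibble(iteration = seq_along(chain), value = chain)
  )
}

#' Accuracy and unbiasedness of estimated breeding values
#'
#' Pearson correlation between true and estimated breeding values, and the
#' ordinary-least-squares regression coefficient of the true value on the
#' estimate (1 = unbiased).
#'
#' @param estimated posterior-mean breeding values.
#' @param truth true breeding values (same length, >= 3 animals).
#' @return Tibble with `correlation` and `regression`.
#' @export
ebv_metrics <- function(estimated, truth) {
  stopifnot(length(estimated) == length(truth), length(truth) >= 3)
  if (var(estimated) == 0) {
    warn("estimated breeding values have zero variance")
    return(tibble::tibble(correlation = NA_real_, regression = NA_real_))
  }
  tibble::tibble(
    correlation = cor(truth, estimated),
    regression = unname(coef(lm(truth ~ estimated))[2])
  )
}

#' MCMC quality diagnostics for a set of chains
#'
#' Per-parameter effective sample size (AR-spectral and batch-means),
#' autocorrelation at the requested lags, posterior mean and SD, Monte
#' Carlo standard error, and skewness.
#'
#' @param draws data frame of post-burn-in draws (one column per parameter)
#'   or an `animal_fit`.
#' @param lags autocorrelation lags (default 1, 5, 10, 50).
#' @param params optional character vector of columns to summarize.
#' @return Tibble with one row per parameter.
#' @export
mcmc_diagnostics <- function(draws, lags = c(1, 5, 10, 50), params = NULL) {
  if (inherits(draws, "animal_fit")) draws <- draws$draws
  stopifnot(is.data.frame(draws))
  if (is.null(params)) params <- names(draws)
  purrr::map_dfr(params, function(nm) {
    x <- draws[[nm]]
    ess <- effective_sample_size(x)
    ac <- autocorr(x, lags)
    out <- tibble::tibble(
      parameter = nm,
      mean = mean(x), sd = sd(x),
      ess = ess, ess_batch = ess_batch_means(x),
      mcse = mcse(x, ess), skewness = sample_skewness(x)
    )
    dplyr::bind_cols(out, tibble::as_tibble(as.list(ac)))
  })
}
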