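#' Replicated simulation study across heritability scenarios
#'
#' Simulates `n_replicates` herds per true heritability, fits each with the
#' requested samplers, and collects per-run posterior summaries of h2
#' (mean, MCSE), breeding-value accuracy (Pearson correlation of true BV
#' with posterior-mean BV) and unbiasedness (regression of truth on
#' estimate), together with sampling-quality metrics (ESS and
#' autocorrelation of the h2 chain at lags 1, 5, 10, 50).
#'
#' @param h2 vector of true heritabilities (default 0.1, 0.3, 0.5).
#' @param n_replicates simulated replicates per scenario (default 5).
#' @param samplers subset of `c("gibbs", "hmc", "nuts")`.
#' @param n_iter,burn_in per-run iteration budget.
#' @param seed master seed; per-replicate seeds are derived from it, so the
#'   whole study is reproducible.
#' @param sim_args extra arguments for [simulate_herd()].
#' @param control sampler control list passed to [fit_animal_model()].
#' @return Tibble with one row per h2 x replicate x sampler and class
#'   `animal_study`.
#' @export
replicate_study <- function(h2 = c(0.1, 0.3, 0.5), n_replicates = 5,
                            samplers = c("gibbs", "nuts"),
                            n_iter = 10000, burn_in = 1000, seed = 1,
                            sim_args = list(), control = list()) {
  samplers <- match.arg(samplers, c("gibbs", "hmc", "nuts"),
                        several.ok = TRUE)
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1,
                             length(h2) * n_replicates),
                  nrow = length(h2))
  rows <- list()
  for (i in seq_along(h2)) {
    for (r in seq_len(n_replicates)) {
      sim <- do.call(simulate_herd,
                     c(list(h2 = h2[i], seed = seeds[i, r]), sim_args))
      rel <- sim$rel
      for (s in samplers) {
        fit <- fit_animal_model(sim$phenotypes, rel,
                                sampler = s, n_iter = n_iter,
                                burn_in = burn_in,
                                seed = seeds[i, r] + match(s, samplers),
                                control = control)
        chain <- fit$draws$h2
        ess <- effective_sample_size(chain)
        ac <- autocorr(chain, c(1, 5, 10, 50))
        em <- ebv_metrics(fit$ebv$ebv, sim$true_bv$bv)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          h2_true = h2[i], replicate = r, sampler = s,
          h2_mean = mean(chain), h2_mcse = mcse(chain, ess),
          ebv_correlation = em$correlation, ebv_regression = em$regression,
          ess = ess, lag1 = ac[["lag1"]], lag5 = ac[["lag5"]],
          lag10 = ac[["lag10"]], lag50 = ac[["lag50"]],
          h2_skewness = sample_skewness(chain),
          epsilon = if (is.null(fit$report$epsilon)) NA_real_
                    else fit$report$epsilon
        )
      }
    }
  }
  structure(dplyr::bind_rows(rows), class = c("animal_study", "tbl_df",
                                              "tbl", "data.frame"))
}

#' Replicate-averaged study summary
#'
#' Averages the per-replicate metrics of [replicate_study()] over
#' replicates, one row per true heritability and sampler: estimates
#' (posterior-mean h2, MCSE, breeding-value correlation and regression)
#' and sampling quality (ESS, lagged autocorrelations).
#'
#' @param study result of [replicate_study()].
#' @return A tibble.
#' @export
study_summary <- function(study) {
  study |>
    dplyr::group_by(.data$h2_true, .data$sampler) |>
    dplyr::summarise(dplyr::across(
      c("h2_mean", "h2_mcse", "ebv_correlation", "ebv_regression",
        "ess", "lag1", "lag5", "lag10", "lag50", "h2_skewness"),
      ~ mean(.x)), .groups = "drop")
}
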