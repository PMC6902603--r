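#' Single-site Gibbs sampler for the animal model
#'
#' Each sweep updates, in order: every fixed effect b_j from its normal
#' full conditional; every breeding value a_i from its single-site normal
#' conditional (mixed-model-equation mean, variance
#' sigma2_e / (z_i'z_i + Ainv_ii sigma2_e / sigma2_a)); then
#' sigma2_a from Inverse-Gamma(q/2 - 1, a' A^{-1} a / 2) and sigma2_e from
#' Inverse-Gamma(n/2 - 1, e'e / 2), the flat-prior conditionals
#' (shape/rate parameterization: density proportional to
#' x^(-shape-1) exp(-rate/x)). A^{-1} is precomputed once from the
#' Cholesky factor.
#'
#' @param data an [animal_model_data()] object.
#' @param n_iter,burn_in iteration budget and discarded prefix.
#' @param init `"default"` (b = 0, a = 0, both variances = var(y)/2) or a
#'   list with `b`, `a`, `sigma2_a`, `sigma2_e`.
#' @param store_a keep all breeding-value draws (memory-heavy for large q;
#'   the posterior mean of a is always accumulated).
#' @param update_locations,update_variances freeze a block (used to check
#'   conditional distributions; both `TRUE` for normal operation).
#' @return List with `draws` (tibble: b columns, sigma2_a, sigma2_e, h2),
#'   `a_mean` (posterior-mean breeding values), optionally `a_draws`.
#' @export
gibbs_sampler <- function(data, n_iter = 10000, burn_in = 1000,
                          init = "default", store_a = FALSE,
                          update_locations = TRUE, update_variances = TRUE) {
  stopifnot(inherits(data, "animal_model_data"), burn_in < n_iter)
  if (update_variances && (data$q <= 2 || data$n <= 2)) {
    abort("flat-prior variance conditionals are improper for q <= 2 or n <= 2")
  }
  if (identical(init, "default")) {
    v0 <- 0.5 * var(data$y)
    init <- list(b = numeric(data$p), a = numeric(data$q),
                 sigma2_a = v0, sigma2_e = v0)
  }
  check_state(init)
  Ainv <- chol2inv(t(data$rel$L))
  ctx <- am_ctx_new(data$y, data$X, data$zidx, data$rel$L)
  res <- am_gibbs(ctx, Ainv, as.integer(n_iter), as.integer(burn_in),
                  init$b, init$a, init$sigma2_a, init$sigma2_e,
                  update_locations, update_variances, store_a)
  b <- res$b
  colnames(b) <- colnames(data$X)
  draws <- tibble::as_tibble(as.data.frame(b))
  draws$sigma2_a <- as.numeric(res$sigma2_a)
  draws$sigma2_e <- as.numeric(res$sigma2_e)
  draws$h2 <- as.numeric(res$h2)
  out <- list(draws = draws, a_mean = as.numeric(res$a_mean))
  if (store_a) out$a_draws <- res$a
  out
}
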