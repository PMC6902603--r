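#' Assemble model matrices for the univariate animal model
#'
#' Builds y, X and the record -> animal incidence map for the model
#' y = Xb + Za + e with a | sigma2_a ~ N(0, A sigma2_a) and
#' e ~ N(0, I sigma2_e). Fixed effects use treatment coding with an
#' intercept; columns that are linearly redundant are dropped so that X has
#' full column rank (a flat prior on b requires identifiability).
#'
#' @param phenotypes data frame with column `animal`, the fixed-effect
#'   columns referenced by `fixed`, and the trait column.
#' @param pedigree pedigree data frame or a [relationship_factor()].
#' @param fixed one-sided formula for the fixed effects, e.g. `~ sex`.
#' @param trait name of the trait column (default `"trait"`).
#' @return Object of class `animal_model_data`: list with `y`, `X`, `zidx`
#'   (1-based animal index per record), `rel` (the relationship factor),
#'   `n`, `p`, `q`, and the animal ids.
#' @export
animal_model_data <- function(phenotypes, pedigree, fixed = ~sex,
                              trait = "trait") {
  stopifnot(is.data.frame(phenotypes))
  rel <- as_rel_factor(pedigree)
  if (!trait %in% names(phenotypes)) {
    abort(paste0("trait column '", trait, "' not found in phenotypes"))
  }
  if (!"animal" %in% names(phenotypes)) abort("phenotypes needs column 'animal'")
  zidx <- match(as.character(phenotypes$animal), rel$ids)
  if (anyNA(zidx)) {
    bad <- unique(phenotypes$animal[is.na(zidx)])
    abort(paste0("phenotyped animals absent from pedigree: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  y <- as.numeric(phenotypes[[trait]])
  if (anyNA(y)) abort("missing trait values")
  X <- model.matrix(fixed, data = phenotypes)
  # drop redundant columns so X has full column rank
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  structure(list(y = y, X = X, zidx = zidx, rel = rel,
                 n = length(y), p = ncol(X), q = rel$q, ids = rel$ids),
            class = "animal_model_data")
}

#' @export
print.animal_model_data <- function(x, ...) {
  cat("<animal_model_data> n =", x$n, "records, p =", x$p,
      "fixed-effect columns, q =", x$q, "animals\n")
  invisible(x)
}

check_state <- function(state) {
  if (!is.list(state) || is.null(state$sigma2_a) || is.null(state$sigma2_e)) {
    abort("state must be a list with b, a, sigma2_a, sigma2_e")
  }
  if (state$sigma2_a <= 0 || state$sigma2_e <= 0) {
    abort("variances must be strictly positive")
  }
  invisible(state)
}

# A^{-1} a via two triangular solves with L
ainv_times <- function(L, a) {
  w <- forwardsolve(L, a)
  backsolve(t(L), w)
}

#' Log posterior of the animal model (constrained scale, up to a constant)
#'
#' log N(y | Xb + Za, I sigma2_e) + log N(a | 0, A sigma2_a), with flat
#' priors on b and on both variances contributing nothing. Additive
#' constants (including -log|A|/2 and the 2*pi terms) are dropped
#' consistently, so only differences between states are meaningful.
#'
#' @param state list with `b` (p-vector), `a` (q-vector), `sigma2_a`,
#'   `sigma2_e`.
#' @param data an [animal_model_data()] object.
#' @return Scalar log density up to an additive constant.
#' @export
log_posterior <- function(state, data) {
  check_state(state)
  r <- data$y - data$X %*% state$b - state$a[data$zidx]
  w <- forwardsolve(data$rel$L, state$a)
  -0.5 * data$n * log(state$sigma2_e) - 0.5 * sum(r^2) / state$sigma2_e -
    0.5 * data$q * log(state$sigma2_a) - 0.5 * sum(w^2) / state$sigma2_a
}

#' Gradient of the log posterior on the constrained scale
#'
#' The four analytic blocks:
#' d/db    = X'(y - Xb - Za) / sigma2_e
#' d/da    = -A^{-1} a / sigma2_a + Z'(y - Xb - Za) / sigma2_e
#' d/ds2a  = -q / (2 sigma2_a) + a' A^{-1} a / (2 sigma2_a^2)
#' d/ds2e  = -n / (2 sigma2_e) + e'e / (2 sigma2_e^2)
#' with A^{-1} a computed by two triangular solves with L.
#'
#' @inheritParams log_posterior
#' @return List with components `b`, `a`, `sigma2_a`, `sigma2_e`.
#' @export
grad_log_posterior <- function(state, data) {
  check_state(state)
  L <- data$rel$L
  r <- as.numeric(data$y - data$X %*% state$b - state$a[data$zidx])
  ainv_a <- ainv_times(L, state$a)
  # rowsum only returns groups present; build the full q-vector explicitly
  ztr <- numeric(data$q)
  tab <- rowsum(r, group = data$zidx)
  ztr[as.integer(rownames(tab))] <- tab[, 1L]
  list(
    b = as.numeric(crossprod(data$X, r)) / state$sigma2_e,
    a = -ainv_a / state$sigma2_a + ztr / state$sigma2_e,
    sigma2_a = -0.5 * data$q / state$sigma2_a +
      0.5 * sum(state$a * ainv_a) / state$sigma2_a^2,
    sigma2_e = -0.5 * data$n / state$sigma2_e +
      0.5 * sum(r^2) / state$sigma2_e^2
  )
}

#' Map between constrained and unconstrained parameterizations
#'
#' The gradient-based samplers work on theta = (b, u, log sigma2_a,
#' log sigma2_e) with a = sigma_a L u — the fully non-centered (whitened)
#' parameterization. The genetic-effect prior becomes standard spherical,
#' u ~ N(0, I), decoupled from sigma2_a (which removes the funnel-shaped
#' prior geometry that cripples gradient samplers in hierarchical models),
#' and the log-variance transform adds Jacobian terms
#' +log sigma2_a +log sigma2_e to the log density.
#'
#' @param state list with `b`, `a`, `sigma2_a`, `sigma2_e`.
#' @param data an [animal_model_data()] object.
#' @return `to_unconstrained()`: numeric vector of length p + q + 2;
#'   `from_unconstrained()`: the state list (with both `a` and `u`).
#' @export
to_unconstrained <- function(state, data) {
  check_state(state)
  u <- forwardsolve(data$rel$L, state$a) / sqrt(state$sigma2_a)
  c(state$b, u, log(state$sigma2_a), log(state$sigma2_e))
}

#' @rdname to_unconstrained
#' @param theta numeric vector as produced by `to_unconstrained()`.
#' @export
from_unconstrained <- function(theta, data) {
  p <- data$p; q <- data$q
  stopifnot(length(theta) == p + q + 2)
  u <- theta[(p + 1):(p + q)]
  s2a <- exp(theta[p + q + 1])
  list(b = theta[seq_len(p)],
       u = u,
       a = sqrt(s2a) * as.numeric(data$rel$L %*% u),
       sigma2_a = s2a,
       sigma2_e = exp(theta[p + q + 2]))
}

#' Unconstrained-scale log density and gradient closures
#'
#' Returns the pair of functions consumed by [hmc_sampler()] and
#' [nuts_sampler()]: the log posterior on the (b, u, log-variance) scale
#' including Jacobian terms, and its gradient. Backed by compiled kernels.
#'
#' @param data an [animal_model_data()] object.
#' @return List with functions `lp(theta)`, `grad(theta)`, a fused
#'   `lp_grad(theta)`, a fused leapfrog `step()`, and the parameter
#'   dimension `dim`. When the relationship factor was built from a
#'   pedigree, products with L use O(q) pedigree recurrences
#'   (A = T D T'); a dense fallback covers raw-matrix factors.
#' @export
animal_model_target <- function(data) {
  rel <- data$rel
  ctx <- if (!is.null(rel$dsqrt)) {
    am_ctx_new_ped(data$y, data$X, data$zidx, as.integer(rel$sire),
                   as.integer(rel$dam), rel$dsqrt)
  } else {
    am_ctx_new(data$y, data$X, data$zidx, rel$L)
  }
  list(
    lp = function(theta) am_logpost(ctx, theta),
    grad = function(theta) as.numeric(am_grad(ctx, theta)),
    lp_grad = function(theta) am_lp_grad(ctx, theta),
    step = function(theta, p, epsilon, g, minv) {
      am_step(ctx, theta, p, epsilon, g, as.numeric(minv))
    },
    dim = data$p + data$q + 2L,
    ctx = ctx
  )
}

#' Per-draw heritability
#'
#' h2 = sigma2_a / (sigma2_a + sigma2_e), strictly inside (0, 1) for
#' positive variances.
#'
#' @param sigma2_a,sigma2_e positive variance draws (vectorized).
#' @return Numeric vector of heritabilities.
#' @export
heritability <- function(sigma2_a, sigma2_e) {
  if (any(sigma2_a <= 0) || any(sigma2_e <= 0)) abort("variances must be > 0")
  sigma2_a / (sigma2_a + sigma2_e)
}
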