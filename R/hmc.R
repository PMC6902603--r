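#' Kinetic energy of a momentum vector
#'
#' K(p) = p' M^{-1} p / 2 with a positive diagonal mass matrix M, given as
#' a scalar or vector of diagonal entries.
#'
#' @param p momentum vector.
#' @param M positive scalar or vector: diagonal of the mass matrix.
#' @return Scalar kinetic energy.
#' @export
kinetic_energy <- function(p, M = 1) {
  if (any(M <= 0)) abort("mass matrix diagonal must be positive")
  0.5 * sum(p^2 / M)
}

draw_momentum <- function(d, M) rnorm(d, 0, sqrt(M))

#' Leapfrog integration of Hamiltonian dynamics
#'
#' Alternates a half step on the momentum, a full step on the position
#' (theta <- theta + eps * M^{-1} p) and a second half momentum step,
#' `n_steps` times, with U(theta) = -log f(theta) so the momentum update is
#' p <- p + (eps/2) * grad log f(theta). The integrator is time-reversible
#' and volume-preserving. A non-finite gradient or position flags the
#' trajectory as divergent instead of raising an error.
#'
#' @param theta,p starting position and momentum.
#' @param epsilon step size (> 0).
#' @param n_steps number of leapfrog steps (>= 1).
#' @param grad gradient of the log target density.
#' @param M diagonal mass matrix (scalar or vector).
#' @return List with `theta`, `p` and logical `divergent`.
#' @export
leapfrog <- function(theta, p, epsilon, n_steps, grad, M = 1) {
  g <- grad(theta)
  if (!all(is.finite(g))) {
    return(list(theta = theta, p = p, divergent = TRUE))
  }
  for (s in seq_len(n_steps)) {
    p <- p + 0.5 * epsilon * g
    theta <- theta + epsilon * p / M
    g <- grad(theta)
    if (!all(is.finite(g)) || !all(is.finite(theta))) {
      return(list(theta = theta, p = p, divergent = TRUE))
    }
    p <- p + 0.5 * epsilon * g
  }
  list(theta = theta, p = p, divergent = FALSE)
}

# Fused leapfrog step: one gradient+density evaluation per step, with the
# gradient at the current point carried in. Targets may supply a compiled
# `step`; otherwise one is assembled from the lp/grad closures.
get_step <- function(target) {
  if (!is.null(target$step)) return(target$step)
  function(theta, p, epsilon, g, minv) {
    ph <- p + 0.5 * epsilon * g
    th <- theta + epsilon * (minv * ph)
    gn <- target$grad(th)
    if (!all(is.finite(gn))) {
      return(list(theta = th, p = ph, grad = gn, lp = -Inf))
    }
    list(theta = th, p = ph + 0.5 * epsilon * gn, grad = gn,
         lp = target$lp(th))
  }
}

#' One Hamiltonian Monte Carlo transition
#'
#' Refreshes the momentum from N(0, M), integrates `n_leapfrog` leapfrog
#' steps of size `epsilon`, and applies the Metropolis correction with
#' acceptance probability alpha = min(1, exp(H(theta, p) - H(theta*, p*))).
#' Divergent trajectories are always rejected.
#'
#' @param theta current position (unconstrained scale).
#' @param target list with `lp` and `grad` functions.
#' @param epsilon,n_leapfrog HMC hyperparameters.
#' @param M diagonal mass matrix.
#' @param lp0,g0 optional cached log density and gradient at `theta`.
#' @return List with `theta`, `lp`, `grad`, `accepted`, `alpha`,
#'   `divergent`.
#' @export
hmc_step <- function(theta, target, epsilon, n_leapfrog, M = 1,
                     lp0 = NULL, g0 = NULL) {
  if (is.null(lp0)) lp0 <- target$lp(theta)
  if (is.null(g0)) g0 <- target$grad(theta)
  stepf <- get_step(target)
  minv <- 1 / M
  p0 <- draw_momentum(length(theta), M)
  H0 <- -lp0 + kinetic_energy(p0, M)
  th <- theta; pp <- p0; g <- g0; lp1 <- lp0
  divergent <- FALSE
  for (s in seq_len(n_leapfrog)) {
    st <- stepf(th, pp, epsilon, g, minv)
    if (!all(is.finite(st$p)) || !all(is.finite(st$theta)) ||
        !is.finite(st$lp)) {
      divergent <- TRUE
      break
    }
    th <- st$theta; pp <- st$p; g <- st$grad; lp1 <- st$lp
  }
  if (!divergent) {
    H1 <- -lp1 + kinetic_energy(pp, M)
    dH <- H0 - H1
    if (!is.finite(dH) || -dH > 1000) divergent <- TRUE  # Stan convention
  }
  if (divergent) {
    return(list(theta = theta, lp = lp0, grad = g0, accepted = FALSE,
                alpha = 0, divergent = TRUE))
  }
  alpha <- min(1, exp(dH))
  if (runif(1) < alpha) {
    list(theta = th, lp = lp1, grad = g, accepted = TRUE, alpha = alpha,
         divergent = FALSE)
  } else {
    list(theta = theta, lp = lp0, grad = g0, accepted = FALSE,
         alpha = alpha, divergent = FALSE)
  }
}

#' Fixed-hyperparameter Hamiltonian Monte Carlo sampler
#'
#' Runs `n_iter` HMC transitions with fixed step size and step count,
#' discarding `burn_in` iterations. Momentum is fully refreshed every
#' iteration. A post-burn-in acceptance rate below 1% triggers a warning
#' (the typical failure mode of a badly scaled step size).
#'
#' @param target list with `lp(theta)` and `grad(theta)`.
#' @param init initial unconstrained position.
#' @param epsilon,n_leapfrog HMC hyperparameters (paper-style defaults are
#'   supplied by [fit_animal_model()]).
#' @param n_iter,burn_in iteration budget and discarded prefix.
#' @param M diagonal mass matrix (scalar or vector), identity by default.
#' @return List with `draws` (kept iterations x dim), `accept_rate`,
#'   `divergences`, `alphas`.
#' @export
hmc_sampler <- function(target, init, epsilon, n_leapfrog,
                        n_iter = 10000, burn_in = 1000, M = 1) {
  stopifnot(epsilon > 0, n_leapfrog >= 1, burn_in < n_iter)
  d <- length(init)
  keep <- n_iter - burn_in
  draws <- matrix(NA_real_, keep, d)
  alphas <- numeric(n_iter)
  acc <- logical(n_iter)
  ndiv <- 0L
  theta <- init
  lp <- target$lp(theta)
  g <- target$grad(theta)
  for (it in seq_len(n_iter)) {
    st <- hmc_step(theta, target, epsilon, n_leapfrog, M, lp0 = lp, g0 = g)
    theta <- st$theta; lp <- st$lp; g <- st$grad
    alphas[it] <- st$alpha
    acc[it] <- st$accepted
    if (st$divergent) ndiv <- ndiv + 1L
    if (it > burn_in) draws[it - burn_in, ] <- theta
  }
  rate <- mean(acc[(burn_in + 1):n_iter])
  if (rate < 0.01) {
    warn(sprintf(
      "HMC post-burn-in acceptance rate %.3f%% — step size likely too large",
      100 * rate))
  }
  list(draws = draws, accept_rate = rate, divergences = ndiv,
       alphas = alphas)
}
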