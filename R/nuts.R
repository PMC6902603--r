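# No-U-Turn Sampler: slice-based tree doubling with dual-averaging step-size
# adaptation. The building blocks are plain functions over (lp, grad)
# closures so they can be exercised on analytic targets.

# log joint density of (theta, p): log f(theta) - p' M^{-1} p / 2
log_joint <- function(lp_theta, p, M) lp_theta - kinetic_energy(p, M)

# Slice variable: u | theta, p ~ Uniform(0, exp(log joint)). Stored on the
# log scale, log u = log joint + log Uniform(0,1), to avoid underflow.
draw_slice <- function(log_joint_val) {
  if (!is.finite(log_joint_val)) abort("non-finite joint density")
  log_joint_val + log(runif(1))
}

# U-turn stopping rule: stop iff the span has begun contracting at either
# end, (theta+ - theta-)'p- < 0 or (theta+ - theta-)'p+ < 0.
uturn_stop <- function(theta_plus, theta_minus, p_plus, p_minus) {
  dt <- theta_plus - theta_minus
  (sum(dt * p_minus) < 0) || (sum(dt * p_plus) < 0)
}

# Transition kernel T between doublings: with probability min(1, n_new/n_old)
# adopt the new subtree's proposal (itself uniform over its valid states).
transition_select <- function(n_new, n_old) {
  if (n_new == 0) return(FALSE)
  runif(1) < n_new / n_old
}

# alpha_j statistic: mean over the states explored in the final doubling of
# min(1, exp(joint - joint at the iteration start)).
accept_statistic <- function(tree) {
  if (tree$n_alpha < 1) abort("empty acceptance accumulator")
  tree$alpha_sum / tree$n_alpha
}

new_dual_averaging <- function(epsilon1, delta = 0.6, gamma = 0.05,
                               j0 = 10, kappa = 0.75) {
  list(mu = log(10 * epsilon1), delta = delta, gamma = gamma, j0 = j0,
       kappa = kappa, sum_delta_alpha = 0, log_eps = log(epsilon1),
       log_eps_bar = log(epsilon1))
}

# Printed dual-averaging recursions:
#   log eps_{j+1}    = mu - sqrt(j)/gamma * 1/(j + j0) * sum_{i<=j}(delta - alpha_i)
#   log epsbar_{j+1} = j^{-kappa} log eps_{j+1} + (1 - j^{-kappa}) log epsbar_j
# After warm-up, eps is frozen at exp(log epsbar).
dual_averaging_update <- function(da, alpha_j, j) {
  stopifnot(j >= 1)
  da$sum_delta_alpha <- da$sum_delta_alpha + (da$delta - alpha_j)
  da$log_eps <- da$mu -
    sqrt(j) / da$gamma * da$sum_delta_alpha / (j + da$j0)
  eta <- j^(-da$kappa)
  da$log_eps_bar <- eta * da$log_eps + (1 - eta) * da$log_eps_bar
  da
}

# Coarse initial step-size search: double/halve eps until the one-step
# acceptance probability crosses 1/2 (started from the initial state).
find_reasonable_epsilon <- function(target, theta, M = 1, eps = 1) {
  p <- draw_momentum(length(theta), M)
  j0 <- log_joint(target$lp(theta), p, M)
  one <- function(eps) {
    lf <- leapfrog(theta, p, eps, 1L, target$grad, M)
    if (lf$divergent) return(-Inf)
    log_joint(target$lp(lf$theta), lf$p, M) - j0
  }
  lr <- one(eps)
  while (!is.finite(lr)) {
    eps <- eps / 2
    lr <- one(eps)
    if (eps < 1e-12) abort("could not find a workable initial step size")
  }
  a <- if (lr > log(0.5)) 1 else -1
  while (a * lr > -a * log(2)) {
    eps <- eps * 2^a
    lr <- one(eps)
    if (!is.finite(lr)) lr <- -Inf
    if (eps > 1e7 || eps < 1e-12) break
  }
  eps
}

# Recursive tree doubling. Depth 0 takes a single leapfrog step in
# `direction` (one fused gradient+density evaluation, gradient carried
# between leaves); depth k builds two depth-(k-1) subtrees and applies the
# U-turn check to the merged span (in-trajectory checks at every merge).
# States count into the candidate set when log u <= log joint; a slice
# violation by more than 1000 on the log scale stops the tree as divergent.
# `mech` bundles the fused step, M and 1/M.
build_tree <- function(theta, p, g, log_u, direction, depth, epsilon,
                       joint0, mech) {
  if (depth == 0L) {
    lf <- mech$step(theta, p, direction * epsilon, g, mech$minv)
    bad <- !all(is.finite(lf$p)) || !all(is.finite(lf$theta)) ||
      !is.finite(lf$lp)
    joint <- if (bad) -Inf else log_joint(lf$lp, lf$p, mech$M)
    if (!is.finite(joint)) joint <- -Inf
    n_valid <- as.integer(log_u <= joint)
    divergent <- (log_u - joint) > 1000
    alpha <- min(1, exp(joint - joint0))
    list(theta_minus = lf$theta, p_minus = lf$p, g_minus = lf$grad,
         theta_plus = lf$theta, p_plus = lf$p, g_plus = lf$grad,
         proposal = if (n_valid == 1L) lf$theta else NULL,
         log_joint_prop = joint,
         n_valid = n_valid, stop = divergent, divergent = divergent,
         alpha_sum = alpha, n_alpha = 1L)
  } else {
    t1 <- build_tree(theta, p, g, log_u, direction, depth - 1L, epsilon,
                     joint0, mech)
    if (t1$stop) return(t1)
    if (direction == -1L) {
      t2 <- build_tree(t1$theta_minus, t1$p_minus, t1$g_minus, log_u,
                       direction, depth - 1L, epsilon, joint0, mech)
      theta_minus <- t2$theta_minus; p_minus <- t2$p_minus
      g_minus <- t2$g_minus
      theta_plus <- t1$theta_plus; p_plus <- t1$p_plus
      g_plus <- t1$g_plus
    } else {
      t2 <- build_tree(t1$theta_plus, t1$p_plus, t1$g_plus, log_u,
                       direction, depth - 1L, epsilon, joint0, mech)
      theta_minus <- t1$theta_minus; p_minus <- t1$p_minus
      g_minus <- t1$g_minus
      theta_plus <- t2$theta_plus; p_plus <- t2$p_plus
      g_plus <- t2$g_plus
    }
    n_total <- t1$n_valid + t2$n_valid
    proposal <- t1$proposal
    log_joint_prop <- t1$log_joint_prop
    if (t2$n_valid > 0L && n_total > 0L &&
        runif(1) < t2$n_valid / n_total) {
      proposal <- t2$proposal
      log_joint_prop <- t2$log_joint_prop
    }
    stop <- t2$stop ||
      uturn_stop(theta_plus, theta_minus, p_plus, p_minus)
    list(theta_minus = theta_minus, p_minus = p_minus, g_minus = g_minus,
         theta_plus = theta_plus, p_plus = p_plus, g_plus = g_plus,
         proposal = proposal, log_joint_prop = log_joint_prop,
         n_valid = n_total, stop = stop,
         divergent = t1$divergent || t2$divergent,
         alpha_sum = t1$alpha_sum + t2$alpha_sum,
         n_alpha = t1$n_alpha + t2$n_alpha)
  }
}

# One NUTS transition at fixed epsilon. Returns the next position, the
# alpha_j statistic of the final doubling, tree depth and divergence flag.
nuts_step <- function(theta, target, epsilon, M = 1, max_depth = 10L,
                      lp0 = NULL, g0 = NULL) {
  if (is.null(lp0)) lp0 <- target$lp(theta)
  if (is.null(g0)) g0 <- target$grad(theta)
  mech <- list(step = get_step(target), M = M, minv = 1 / M)
  p0 <- draw_momentum(length(theta), M)
  joint0 <- log_joint(lp0, p0, M)
  log_u <- draw_slice(joint0)
  theta_minus <- theta; theta_plus <- theta
  p_minus <- p0; p_plus <- p0
  g_minus <- g0; g_plus <- g0
  proposal <- theta
  prop_joint <- joint0
  n <- 1L; depth <- 0L; stop <- FALSE
  divergent <- FALSE
  alpha_j <- NA_real_
  while (!stop && depth < max_depth) {
    direction <- sample(c(-1L, 1L), 1L)
    if (direction == -1L) {
      sub <- build_tree(theta_minus, p_minus, g_minus, log_u, direction,
                        depth, epsilon, joint0, mech)
      theta_minus <- sub$theta_minus; p_minus <- sub$p_minus
      g_minus <- sub$g_minus
    } else {
      sub <- build_tree(theta_plus, p_plus, g_plus, log_u, direction,
                        depth, epsilon, joint0, mech)
      theta_plus <- sub$theta_plus; p_plus <- sub$p_plus
      g_plus <- sub$g_plus
    }
    if (!sub$stop && transition_select(sub$n_valid, n)) {
      proposal <- sub$proposal
      prop_joint <- sub$log_joint_prop
    }
    n <- n + sub$n_valid
    stop <- sub$stop ||
      uturn_stop(theta_plus, theta_minus, p_plus, p_minus)
    divergent <- divergent || isTRUE(sub$divergent)
    alpha_j <- accept_statistic(sub)
    depth <- depth + 1L
  }
  list(theta = proposal, alpha = alpha_j, depth = depth,
       divergent = divergent, max_depth_hit = (depth >= max_depth && !stop),
       log_joint_prop = prop_joint, log_u = log_u)
}

#' No-U-Turn Sampler with dual-averaging step-size adaptation
#'
#' Per iteration: refresh the momentum from N(0, M), draw the slice
#' variable, expand the trajectory by tree doubling with the memory-light
#' transition kernel (adopt the new subtree's proposal with probability
#' min(1, |C_new|/|C_old|)), stop on a U-turn or slice violation, and —
#' during warm-up only — adapt log epsilon by dual averaging driving the
#' mean acceptance statistic alpha_j toward `delta`. After warm-up the step
#' size is frozen at its averaged value. The initial step size is found by
#' a coarse doubling search and mu is set to log(10 epsilon_1).
#'
#' @param target list with `lp(theta)` and `grad(theta)`.
#' @param init initial unconstrained position.
#' @param n_iter total iterations; `warmup` of them are discarded.
#' @param warmup warm-up (adaptation) iterations.
#' @param delta target mean acceptance statistic (default 0.6).
#' @param max_depth maximum tree depth (default 10).
#' @param M diagonal mass matrix used when `adapt_mass = FALSE`.
#' @param adapt_mass estimate a diagonal mass matrix from warm-up draws
#'   (off by default; when on, M is refreshed twice during warm-up from the
#'   empirical variance of the warm-up draws).
#' @return List with `draws` (kept x dim), `epsilon` (frozen step size),
#'   `eps_trace`, `depths`, `divergences`, `max_depth_hits`, `mean_alpha`,
#'   `M`.
#' @export
nuts_sampler <- function(target, init, n_iter = 10000, warmup = 1000,
                         delta = 0.6, max_depth = 10L, M = 1,
                         adapt_mass = FALSE) {
  stopifnot(warmup < n_iter, delta > 0, delta < 1)
  d <- length(init)
  theta <- init
  eps1 <- find_reasonable_epsilon(target, theta, M)
  da <- new_dual_averaging(eps1, delta = delta)
  epsilon <- eps1
  keep <- n_iter - warmup
  draws <- matrix(NA_real_, keep, d)
  depths <- integer(n_iter)
  eps_trace <- numeric(n_iter)
  alphas <- numeric(n_iter)
  ndiv_warm <- 0L; ndiv <- 0L; nmax <- 0L
  warm_buf <- if (adapt_mass) matrix(NA_real_, warmup, d) else NULL
  mass_updates <- if (adapt_mass) {
    unique(pmax(2L, floor(warmup * c(0.5, 0.85))))
  } else integer(0)

  lp_grad <- if (!is.null(target$lp_grad)) target$lp_grad else
    function(th) list(lp = target$lp(th), grad = target$grad(th))
  for (it in seq_len(n_iter)) {
    cur <- lp_grad(theta)
    st <- nuts_step(theta, target, epsilon, M, max_depth,
                    lp0 = cur$lp, g0 = cur$grad)
    theta <- st$theta
    depths[it] <- st$depth
    alphas[it] <- st$alpha
    if (st$divergent) {
      if (it <= warmup) ndiv_warm <- ndiv_warm + 1L else ndiv <- ndiv + 1L
    }
    if (st$max_depth_hit) nmax <- nmax + 1L
    if (it <= warmup) {
      da <- dual_averaging_update(da, st$alpha, it)
      epsilon <- exp(da$log_eps)
      if (adapt_mass) {
        warm_buf[it, ] <- theta
        if (it %in% mass_updates) {
          v <- apply(warm_buf[max(1, it - 199):it, , drop = FALSE], 2, var)
          v[v < 1e-10] <- 1e-10
          M <- 1 / v
          eps1 <- find_reasonable_epsilon(target, theta, M, eps = epsilon)
          da <- new_dual_averaging(eps1, delta = delta)
          epsilon <- eps1
        }
      }
      if (it == warmup) epsilon <- exp(da$log_eps_bar)
    } else {
      draws[it - warmup, ] <- theta
    }
    eps_trace[it] <- epsilon
  }
  if (ndiv > 0.1 * keep) {
    warn(sprintf("NUTS: %d of %d post-warm-up iterations divergent", ndiv, keep))
  }
  list(draws = draws, epsilon = epsilon, eps_trace = eps_trace,
       depths = depths, divergences = ndiv, warmup_divergences = ndiv_warm,
       max_depth_hits = nmax, mean_alpha = mean(alphas[(warmup + 1):n_iter]),
       alphas = alphas, M = M)
}
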