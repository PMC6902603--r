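std_normal <- function(d = 1) {
  list(lp = function(th) -0.5 * sum(th^2), grad = function(th) -th)
}

test_that("slice draws are uniform under the joint density", {
  set.seed(1)
  lj <- -3.7
  lu <- replicate(1e5, pedmcmc:::draw_slice(lj))
  expect_true(all(lu <= lj))                  # u never exceeds the density
  ratio <- exp(lu - lj)                        # u / density ~ U(0,1)
  ks <- suppressWarnings(stats::ks.test(ratio, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_error(pedmcmc:::draw_slice(NaN), "non-finite")
})

test_that("the U-turn criterion fires only on contracting spans", {
  u <- pedmcmc:::uturn_stop
  # identical endpoints: both products zero, strict inequality -> no stop
  expect_false(u(c(1, 2), c(1, 2), c(1, 0), c(0, 1)))
  # aligned momenta at both ends -> no stop
  expect_false(u(c(1, 0), c(0, 0), c(1, 0), c(1, 0)))
  # left end moving away from the span -> stop
  expect_true(u(c(1, 0), c(0, 0), c(1, 0), c(-1, 0)))
  # right end reversed -> stop
  expect_true(u(c(1, 0), c(0, 0), c(-1, 0), c(1, 0)))
})

test_that("the transition kernel accepts with probability min(1, n_new/n_old)", {
  ts <- pedmcmc:::transition_select
  expect_false(ts(0, 5))                       # empty new subtree: keep old
  set.seed(2)
  expect_true(all(replicate(50, ts(4, 2))))    # n_new >= n_old: always move
  freq <- mean(replicate(1e5, ts(1, 2)))
  expect_lt(abs(freq - 0.5), 0.005)
})

test_that("the acceptance statistic averages the per-state ratios", {
  expect_equal(pedmcmc:::accept_statistic(list(alpha_sum = 3, n_alpha = 3)), 1)
  expect_equal(pedmcmc:::accept_statistic(
    list(alpha_sum = 4 * exp(-1), n_alpha = 4)), exp(-1))
  expect_equal(pedmcmc:::accept_statistic(list(alpha_sum = 0.5, n_alpha = 1)),
               0.5)
  expect_error(pedmcmc:::accept_statistic(list(alpha_sum = 0, n_alpha = 0)),
               "empty")
})

test_that("dual averaging follows the printed recursions", {
  da <- pedmcmc:::new_dual_averaging(0.5, delta = 0.6)
  # alpha == delta forever: shrinkage sum stays 0, log eps pinned at mu
  d2 <- da
  for (j in 1:20) d2 <- pedmcmc:::dual_averaging_update(d2, 0.6, j)
  expect_equal(d2$log_eps, da$mu)
  # alpha == 0: accumulated (delta - alpha) > 0, eps strictly decreasing
  d3 <- da
  eps_seq <- numeric(10)
  for (j in 1:10) {
    d3 <- pedmcmc:::dual_averaging_update(d3, 0, j)
    eps_seq[j] <- d3$log_eps
  }
  expect_true(all(diff(eps_seq) < 0))
})

test_that("dual averaging drives the mean acceptance toward delta", {
  set.seed(3)
  tg <- std_normal(10)
  res <- nuts_sampler(tg, init = rnorm(10), n_iter = 3000, warmup = 1000,
                      delta = 0.6)
  post <- res$alphas[1001:3000]
  expect_lt(abs(mean(post) - 0.6), 0.1)
})

test_that("depth-0 trees respect the slice condition and cardinality bounds", {
  set.seed(4)
  tg <- std_normal(2)
  theta <- c(0.3, -0.2)
  p <- rnorm(2)
  joint0 <- pedmcmc:::log_joint(tg$lp(theta), p, 1)
  mech <- list(step = pedmcmc:::get_step(tg), M = 1, minv = 1)
  g <- tg$grad(theta)
  # log_u far below the joint: the new state is in the slice
  t0 <- pedmcmc:::build_tree(theta, p, g, joint0 - 5, 1L, 0L, 0.1, joint0,
                             mech)
  expect_equal(t0$n_valid, 1L)
  expect_false(t0$stop)
  # depth-k cardinality bound on a Gaussian
  for (k in 1:4) {
    tk <- pedmcmc:::build_tree(theta, p, g, joint0 - 2, 1L, k, 0.3, joint0,
                               mech)
    expect_lte(tk$n_valid, 2^k)
  }
})

test_that("every stored NUTS proposal satisfied its slice condition", {
  set.seed(5)
  tg <- std_normal(2)
  theta <- c(0, 0)
  for (i in 1:200) {
    st <- pedmcmc:::nuts_step(theta, tg, epsilon = 0.4)
    expect_gte(st$log_joint_prop, st$log_u)
    theta <- st$theta
  }
})

test_that("NUTS matches a 1-d standard normal by KS test", {
  set.seed(6)
  tg <- std_normal(1)
  res <- nuts_sampler(tg, init = 0.5, n_iter = 12000, warmup = 1000)
  x <- res$draws[, 1]
  # thin to roughly independent draws before the KS comparison
  idx <- seq(1, length(x), by = 10)
  ks <- stats::ks.test(x[idx], "pnorm")
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(x)), 0.05)
  expect_lt(abs(var(x) - 1), 0.08)
})

test_that("NUTS recovers a correlated 2-d Gaussian covariance within 5%", {
  set.seed(7)
  S <- matrix(c(1, 0.9, 0.9, 1), 2)
  P <- solve(S)
  tg <- list(lp = function(th) -0.5 * sum(th * (P %*% th)),
             grad = function(th) -as.numeric(P %*% th))
  res <- nuts_sampler(tg, init = c(0, 0), n_iter = 27000, warmup = 2000)
  C <- stats::cov(res$draws)
  expect_lt(max(abs(C - S)), 0.05 * max(S))
})

test_that("warm-up mass adaptation yields a positive diagonal and valid draws", {
  set.seed(9)
  # anisotropic Gaussian: coordinate scales 1 and 5
  P <- diag(c(1, 1 / 25))
  tg <- list(lp = function(th) -0.5 * sum(th * (P %*% th)),
             grad = function(th) -as.numeric(P %*% th))
  res <- nuts_sampler(tg, init = c(0, 0), n_iter = 2500, warmup = 600,
                      adapt_mass = TRUE)
  expect_true(all(res$M > 0))
  expect_true(length(res$M) %in% c(1L, 2L))
  expect_lt(abs(mean(res$draws[, 1])), 0.2)
  # the adapted mass should reflect the scale difference
  if (length(res$M) == 2L) expect_gt(res$M[1] / res$M[2], 2)
})

test_that("trees are truncated and counted at max_depth", {
  set.seed(8)
  tg <- std_normal(5)
  res <- nuts_sampler(tg, init = rnorm(5), n_iter = 200, warmup = 100,
                      max_depth = 2L)
  expect_true(all(res$depths <= 2))
  expect_gte(res$max_depth_hits, 0)
})
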