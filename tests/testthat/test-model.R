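test_that("log posterior matches direct two-Gaussian evaluation on differences", {
  d <- small_data()
  set.seed(1)
  mk_state <- function() {
    list(b = rnorm(d$p), a = rnorm(d$q, 0, 0.5),
         sigma2_a = runif(1, 0.2, 1), sigma2_e = runif(1, 0.2, 1))
  }
  direct <- function(st) {
    mu <- as.numeric(d$X %*% st$b) + st$a[d$zidx]
    Sig <- d$rel$A * st$sigma2_a
    ld_lik <- sum(dnorm(d$y, mu, sqrt(st$sigma2_e), log = TRUE))
    ld_pr <- -0.5 * d$q * log(2 * pi * st$sigma2_a) -
      0.5 * determinant(d$rel$A)$modulus[1] -
      0.5 * sum(st$a * solve(d$rel$A, st$a)) / st$sigma2_a
    ld_lik + ld_pr
  }
  s1 <- mk_state(); s2 <- mk_state()
  expect_equal(log_posterior(s1, d) - log_posterior(s2, d),
               direct(s1) - direct(s2), tolerance = 1e-8)
})

test_that("log posterior is invariant to shifting y and the intercept together", {
  d <- small_data()
  set.seed(2)
  st <- list(b = rnorm(d$p), a = rnorm(d$q, 0, 0.5),
             sigma2_a = 0.4, sigma2_e = 0.6)
  lp1 <- log_posterior(st, d)
  d2 <- d
  d2$y <- d$y + 5
  st2 <- st
  st2$b[1] <- st$b[1] + 5   # column 1 is the intercept
  expect_equal(log_posterior(st2, d2), lp1, tolerance = 1e-9)
})

test_that("non-positive variances are rejected", {
  d <- small_data()
  st <- list(b = numeric(d$p), a = numeric(d$q), sigma2_a = -1, sigma2_e = 1)
  expect_error(log_posterior(st, d), "positive")
  expect_error(grad_log_posterior(st, d), "positive")
})

test_that("constrained gradient blocks match their analytic special cases", {
  d <- small_data()
  set.seed(3)
  a <- rnorm(d$q, 0, 0.5)
  b <- rnorm(d$p)
  # y constructed to have zero residual
  d0 <- d
  d0$y <- as.numeric(d0$X %*% b) + a[d0$zidx]
  g <- grad_log_posterior(list(b = b, a = a, sigma2_a = 0.5, sigma2_e = 0.5), d0)
  expect_equal(g$b, numeric(d$p), tolerance = 1e-10)
  # the Z'residual part of d/da vanishes: remaining term is -Ainv a / s2a
  w <- forwardsolve(d$rel$L, a)
  ainv_a <- backsolve(t(d$rel$L), w)
  expect_equal(g$a, -ainv_a / 0.5, tolerance = 1e-9)
  # s2a stationary at a'Ainv a / q
  s2a_hat <- sum(a * ainv_a) / d$q
  g2 <- grad_log_posterior(list(b = b, a = a, sigma2_a = s2a_hat,
                                sigma2_e = 0.5), d0)
  expect_equal(g2$sigma2_a, 0, tolerance = 1e-9)
})

test_that("constrained gradient matches finite differences on a random instance", {
  d <- small_data(seed = 9)
  set.seed(4)
  st <- list(b = rnorm(d$p), a = rnorm(d$q, 0, 0.5),
             sigma2_a = 0.7, sigma2_e = 0.9)
  g <- grad_log_posterior(st, d)
  pack <- function(s) c(s$b, s$a, s$sigma2_a, s$sigma2_e)
  unpack <- function(v) list(b = v[seq_len(d$p)],
                             a = v[d$p + seq_len(d$q)],
                             sigma2_a = v[d$p + d$q + 1],
                             sigma2_e = v[d$p + d$q + 2])
  gf <- fd_grad(function(v) log_posterior(unpack(v), d), pack(st))
  expect_equal(c(g$b, g$a, g$sigma2_a, g$sigma2_e), gf,
               tolerance = 1e-6)
})

test_that("unconstrained target matches finite differences and the chain rule", {
  d <- small_data(seed = 10)
  tg <- animal_model_target(d)
  set.seed(5)
  theta <- runif(tg$dim, -0.5, 0.5)
  g <- tg$grad(theta)
  gf <- fd_grad(tg$lp, theta)
  expect_equal(g, gf, tolerance = 1e-6)
  # chain rule on the residual-variance coordinate:
  # d/dlog s2e = s2e * d/ds2e + 1 (the +1 is the Jacobian term)
  st <- from_unconstrained(theta, d)
  gc <- grad_log_posterior(st, d)
  i_lse <- tg$dim
  expect_equal(g[i_lse], st$sigma2_e * gc$sigma2_e + 1, tolerance = 1e-8)
})

test_that("round trip constrained <-> unconstrained is the identity", {
  d <- small_data()
  set.seed(6)
  theta <- runif(tg_dim <- d$p + d$q + 2, -1, 1)
  st <- from_unconstrained(theta, d)
  expect_equal(to_unconstrained(st, d), theta, tolerance = 1e-12)
  expect_equal(st$a, sqrt(st$sigma2_a) * as.numeric(d$rel$L %*% st$u),
               tolerance = 1e-12)
  # u = 0 maps to a = 0
  th0 <- theta
  th0[d$p + seq_len(d$q)] <- 0
  expect_equal(from_unconstrained(th0, d)$a, numeric(d$q))
})

test_that("whitened prior equivalence holds numerically", {
  # log N(a | 0, A s2a) + log|det L| = log N(u | 0, I s2a) for u = L^{-1} a
  d <- small_data()
  set.seed(7)
  a <- rnorm(d$q, 0, 0.8)
  s2a <- 0.6
  L <- d$rel$L
  u <- forwardsolve(L, a)
  lhs <- -0.5 * d$q * log(2 * pi * s2a) -
    0.5 * determinant(d$rel$A)$modulus[1] -
    0.5 * sum(a * solve(d$rel$A, a)) / s2a +
    sum(log(diag(L)))
  rhs <- sum(dnorm(u, 0, sqrt(s2a), log = TRUE))
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("gradient-density consistency holds across random states", {
  d <- small_data(seed = 11)
  tg <- animal_model_target(d)
  set.seed(8)
  for (k in 1:5) {
    theta <- rnorm(tg$dim, 0, 0.7)
    expect_equal(tg$grad(theta), fd_grad(tg$lp, theta), tolerance = 1e-5)
  }
})
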