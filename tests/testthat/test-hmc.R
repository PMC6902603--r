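# analytic standard-normal target in d dimensions
std_normal_target <- function() {
  list(lp = function(th) -0.5 * sum(th^2), grad = function(th) -th)
}

test_that("kinetic energy is p'M^{-1}p/2", {
  expect_equal(kinetic_energy(c(0, 0)), 0)
  expect_equal(kinetic_energy(c(1, 1)), 1)
  expect_equal(kinetic_energy(c(2, 0), M = c(4, 1)), 0.5)
  expect_error(kinetic_energy(1, M = -1), "positive")
})

test_that("one leapfrog step on the standard normal matches hand algebra", {
  tg <- std_normal_target()
  lf <- leapfrog(1, 0, epsilon = 0.1, n_steps = 1, grad = tg$grad)
  # theta1 = 1 - eps^2/2; p1 = -eps (1 - eps^2/4)
  expect_equal(lf$theta, 0.995)
  expect_equal(lf$p, -0.09975)
})

test_that("leapfrog is time-reversible to 1e-10", {
  tg <- std_normal_target()
  set.seed(1)
  theta0 <- rnorm(5); p0 <- rnorm(5)
  fwd <- leapfrog(theta0, p0, 0.15, 20, tg$grad)
  back <- leapfrog(fwd$theta, -fwd$p, 0.15, 20, tg$grad)
  expect_lt(max(abs(back$theta - theta0)), 1e-10)
  expect_lt(max(abs(-back$p - p0)), 1e-10)
})

test_that("energy error scales as O(eps^2)", {
  tg <- std_normal_target()
  set.seed(2)
  theta0 <- rnorm(3); p0 <- rnorm(3)
  H <- function(th, p) -tg$lp(th) + kinetic_energy(p)
  dH <- function(eps) {
    # fixed trajectory length T = 1.2: halving eps doubles the step count
    lf <- leapfrog(theta0, p0, eps, round(1.2 / eps), tg$grad)
    abs(H(lf$theta, lf$p) - H(theta0, p0))
  }
  ratio <- dH(0.1) / dH(0.05)
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})

test_that("leapfrog preserves phase-space volume", {
  # |det Jacobian| of one step = 1, by finite differences on a 2-d target
  S <- matrix(c(1, 0.6, 0.6, 2), 2)
  P <- solve(S)
  tg <- list(lp = function(th) -0.5 * sum(th * (P %*% th)),
             grad = function(th) -as.numeric(P %*% th))
  z0 <- c(0.3, -0.2, 0.5, 0.1)  # (theta, p)
  step <- function(z) {
    lf <- leapfrog(z[1:2], z[3:4], 0.2, 1, tg$grad)
    c(lf$theta, lf$p)
  }
  h <- 1e-6
  J <- vapply(1:4, function(i) {
    zp <- z0; zm <- z0
    zp[i] <- zp[i] + h; zm[i] <- zm[i] - h
    (step(zp) - step(zm)) / (2 * h)
  }, numeric(4))
  expect_equal(abs(det(J)), 1, tolerance = 1e-6)
})

test_that("hmc_step accepts exact integration and rejects divergence", {
  tg <- std_normal_target()
  set.seed(3)
  # epsilon tiny -> dH ~ 0 -> alpha ~ 1
  st <- hmc_step(c(0.5, -0.5), tg, epsilon = 1e-4, n_leapfrog = 1)
  expect_equal(st$alpha, 1, tolerance = 1e-6)
  expect_true(st$accepted)
  # a target with a cliff produces a non-finite gradient -> divergence
  bad <- list(lp = function(th) if (any(abs(th) > 1)) -Inf else 0,
              grad = function(th) if (any(abs(th) > 1)) rep(NaN, length(th))
                                  else rep(0, length(th)))
  st2 <- hmc_step(c(0.99, 0), bad, epsilon = 5, n_leapfrog = 3)
  expect_false(st2$accepted)
  expect_equal(st2$alpha, 0)
  expect_true(st2$divergent)
})

test_that("HMC recovers the moments of a 2-d standard normal", {
  tg <- std_normal_target()
  set.seed(4)
  res <- hmc_sampler(tg, init = c(1, -1), epsilon = 0.2, n_leapfrog = 10,
                     n_iter = 21000, burn_in = 1000)
  for (j in 1:2) {
    x <- res$draws[, j]
    ess <- effective_sample_size(x)
    se_mean <- sd(x) / sqrt(ess)
    expect_lt(abs(mean(x)), 3 * se_mean)
    # variance MCSE ~ sqrt(2/ess) for a Gaussian
    expect_lt(abs(var(x) - 1), 3 * sqrt(2 / ess))
  }
})

test_that("an absurdly large step size triggers the low-acceptance warning", {
  d <- small_data()
  expect_warning(
    fit_animal_model(small_sim()$phenotypes, small_sim()$pedigree,
                     sampler = "hmc", n_iter = 300, burn_in = 100,
                     seed = 5, control = list(epsilon = 10, n_leapfrog = 5)),
    "acceptance"
  )
})

test_that("HMC transitions are reversible in distribution on a 1-d Gaussian", {
  # detailed balance: (x0, x1) pairs from stationarity should be exchangeable;
  # compare the empirical distribution of forward and backward jumps
  tg <- std_normal_target()
  set.seed(6)
  res <- hmc_sampler(tg, init = 0, epsilon = 0.5, n_leapfrog = 3,
                     n_iter = 12000, burn_in = 2000)
  x <- res$draws[, 1]
  jumps <- diff(x)
  ks <- suppressWarnings(stats::ks.test(jumps, -jumps))
  expect_gt(ks$p.value, 0.01)
})
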