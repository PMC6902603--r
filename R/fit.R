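#' Fit the Bayesian animal model by Gibbs sampling, HMC or NUTS
#'
#' Data-frame-first front end: takes the phenotype table and the pedigree,
#' assembles y = Xb + Za + e with a | sigma2_a ~ N(0, A sigma2_a), and runs
#' the requested sampler. Gibbs sampling works on the constrained scale via
#' full conditionals; HMC and NUTS run on the unconstrained scale
#' (b, u, log sigma2_a, log sigma2_e) with a = L u, and their draws are
#' mapped back before storage. Every stored draw carries the derived
#' heritability h2 = sigma2_a / (sigma2_a + sigma2_e).
#'
#' @param phenotypes data frame with `animal`, fixed-effect columns, and
#'   the trait column.
#' @param pedigree pedigree data frame (`animal`, `sire`, `dam`) or a
#'   prebuilt [relationship_factor()].
#' @param fixed one-sided fixed-effects formula (default `~ sex`).
#' @param trait trait column name.
#' @param sampler `"gibbs"`, `"hmc"` or `"nuts"`.
#' @param n_iter total iterations (default 10000).
#' @param burn_in discarded iterations for Gibbs/HMC (default 1000); also
#'   the NUTS warm-up length.
#' @param seed optional RNG seed, recorded in the result.
#' @param control sampler-specific settings: `epsilon` (HMC step size,
#'   default 0.01), `n_leapfrog` (HMC, default 100), `delta` (NUTS target
#'   acceptance, default 0.6), `max_depth` (NUTS, default 10),
#'   `adapt_mass` (NUTS, default FALSE), `M` (diagonal mass), `init`,
#'   `store_a` (Gibbs only).
#' @return Object of class `animal_fit`: list with `draws` (tibble of
#'   post-burn-in b, sigma2_a, sigma2_e, h2), `ebv` (tibble animal,
#'   ebv = posterior-mean breeding value), `sampler`, `report` (adapted
#'   epsilon, divergence and tree-depth counters, acceptance rate), and
#'   the model dimensions.
#' @examples
#' sim <- simulate_herd(h2 = 0.3, n_base_males = 4, n_base_females = 10,
#'                      n_generations = 2, dams_per_sire = 2,
#'                      offspring_per_dam = 4, seed = 1)
#' fit <- fit_animal_model(sim$phenotypes, sim$pedigree, sampler = "gibbs",
#'                         n_iter = 500, burn_in = 100, seed = 1)
#' tidy(fit)
#' @export
fit_animal_model <- function(phenotypes, pedigree, fixed = ~sex,
                             trait = "trait",
                             sampler = c("gibbs", "hmc", "nuts"),
                             n_iter = 10000, burn_in = 1000, seed = NULL,
                             control = list()) {
  sampler <- match.arg(sampler)
  if (!is.null(seed)) set.seed(seed)
  data <- animal_model_data(phenotypes, pedigree, fixed = fixed, trait = trait)
  ctl <- utils::modifyList(
    list(epsilon = 0.01, n_leapfrog = 100, delta = 0.6, max_depth = 10L,
         adapt_mass = FALSE, M = 1, init = NULL, store_a = FALSE),
    control)
  report <- list()

  if (sampler == "gibbs") {
    res <- gibbs_sampler(data, n_iter = n_iter, burn_in = burn_in,
                         init = if (is.null(ctl$init)) "default" else ctl$init,
                         store_a = ctl$store_a)
    draws <- res$draws
    a_mean <- res$a_mean
    if (ctl$store_a) report$a_draws <- res$a_draws
  } else {
    target <- animal_model_target(data)
    init <- if (is.null(ctl$init)) runif(target$dim) else ctl$init
    if (sampler == "hmc") {
      res <- hmc_sampler(target, init, epsilon = ctl$epsilon,
                         n_leapfrog = ctl$n_leapfrog, n_iter = n_iter,
                         burn_in = burn_in, M = ctl$M)
      report <- list(accept_rate = res$accept_rate,
                     divergences = res$divergences,
                     epsilon = ctl$epsilon, n_leapfrog = ctl$n_leapfrog)
    } else {
      res <- nuts_sampler(target, init, n_iter = n_iter, warmup = burn_in,
                          delta = ctl$delta, max_depth = ctl$max_depth,
                          M = ctl$M, adapt_mass = ctl$adapt_mass)
      report <- list(epsilon = res$epsilon, divergences = res$divergences,
                     warmup_divergences = res$warmup_divergences,
                     max_depth_hits = res$max_depth_hits,
                     mean_alpha = res$mean_alpha,
                     depth_table = table(res$depths),
                     eps_trace = res$eps_trace)
    }
    con <- am_constrain_draws(target$ctx, res$draws)
    b <- con$b
    colnames(b) <- colnames(data$X)
    draws <- tibble::as_tibble(as.data.frame(b))
    draws$sigma2_a <- as.numeric(con$sigma2_a)
    draws$sigma2_e <- as.numeric(con$sigma2_e)
    draws$h2 <- as.numeric(con$h2)
    a_mean <- as.numeric(con$a_mean)
  }

  structure(list(
    draws = draws,
    ebv = tibble::tibble(animal = data$ids, ebv = a_mean),
    sampler = sampler, n_iter = n_iter, burn_in = burn_in, seed = seed,
    control = ctl[c("epsilon", "n_leapfrog", "delta", "max_depth",
                    "adapt_mass")],
    report = report,
    n = data$n, p = data$p, q = data$q, trait = trait
  ), class = "animal_fit")
}

#' @export
print.animal_fit <- function(x, ...) {
  cat("<animal_fit>", toupper(x$sampler), "sampler;", x$n, "records,",
      x$q, "animals;", nrow(x$draws), "stored draws\n")
  cat("posterior mean h2 =", sprintf("%.3f", mean(x$draws$h2)), "\n")
  if (!is.null(x$report$epsilon)) {
    cat("step size epsilon =", format(x$report$epsilon, digits = 4), "\n")
  }
  if (!is.null(x$report$divergences) && x$report$divergences > 0) {
    cat("divergent iterations:", x$report$divergences, "\n")
  }
  invisible(x)
}

#' Tidy posterior summaries of an animal-model fit
#'
#' One row per stored parameter (fixed effects, both variances, h2) with
#' posterior mean, SD, Monte Carlo standard error, effective sample size
#' and skewness.
#'
#' @param x an `animal_fit`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.animal_fit <- function(x, ...) {
  d <- mcmc_diagnostics(x$draws, lags = 1)
  tibble::tibble(term = d$parameter, estimate = d$mean,
                 std.error = d$mcse, sd = d$sd, ess = d$ess,
                 skewness = d$skewness)
}

#' One-row summary of an animal-model fit
#'
#' @inheritParams tidy.animal_fit
#' @return A one-row tibble: sampler, iteration counts, posterior mean and
#'   MCSE of h2, its ESS, and divergence count where applicable.
#' @export
glance.animal_fit <- function(x, ...) {
  h2 <- x$draws$h2
  ess <- effective_sample_size(h2)
  tibble::tibble(
    sampler = x$sampler, n_iter = x$n_iter, kept = nrow(x$draws),
    h2_mean = mean(h2), h2_mcse = mcse(h2, ess), h2_ess = ess,
    divergences = if (is.null(x$report$divergences)) NA_integer_
                  else x$report$divergences,
    epsilon = if (is.null(x$report$epsilon)) NA_real_ else x$report$epsilon
  )
}

#' Trace and posterior-density plot for a fitted chain
#'
#' @param object an `animal_fit`.
#' @param pars parameters to show (default `"h2"`).
#' @param ... unused.
#' @return A ggplot object faceted by parameter and panel type.
#' @export
autoplot.animal_fit <- function(object, pars = "h2", ...) {
  stopifnot(all(pars %in% names(object$draws)))
  long <- object$draws |>
    dplyr::mutate(iteration = dplyr::row_number()) |>
    dplyr::select(dplyr::all_of(c("iteration", pars))) |>
    tidyr::pivot_longer(-"iteration", names_to = "parameter")
  trace <- ggplot2::ggplot(long,
             ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "steelblue") +
    ggplot2::facet_grid(parameter ~ ., scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = paste(toupper(object$sampler), "trace"))
  dens <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::facet_grid(parameter ~ ., scales = "free") +
    ggplot2::labs(x = NULL, y = "density", title = "posterior")
  if (requireNamespace("patchwork", quietly = TRUE)) {
    trace + dens
  } else {
    trace
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
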