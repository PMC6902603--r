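#' Simulate a closed herd under the infinitesimal model
#'
#' Emulates the discrete-generation design used throughout the simulation
#' study: a base population of unrelated founders (20 males, 100 females by
#' default), then `n_generations` generations in which a single sire is
#' drawn at random from the previous generation's males and mated to
#' `dams_per_sire` dams drawn without replacement from the previous
#' generation's females; every mating produces `offspring_per_dam`
#' offspring, half male and half female (200 per generation, 1000 over five
#' generations by default, 1120 animals in total).
#'
#' Breeding values follow the infinitesimal model: founders get
#' BV ~ N(0, h2 * sigma2_P); an offspring's BV is the mid-parent value plus
#' a Mendelian-sampling deviation with variance
#' sigma2_a/2 * (1 - (F_s + F_d)/2), using exact inbreeding coefficients
#' from the diagonal of A. Phenotypes are sex mean + BV + residual with
#' residual variance (1 - h2) * sigma2_P.
#'
#' @param h2 true heritability in (0, 1).
#' @param n_base_males,n_base_females founder counts.
#' @param n_generations number of discrete generations after the base.
#' @param dams_per_sire dams mated to the single sire each generation.
#' @param offspring_per_dam offspring per mating (must be even: half of
#'   each sex).
#' @param phenotypic_variance total phenotypic variance sigma2_P.
#' @param sex_effect length-2 vector of fixed sex means (male, female),
#'   in trait units; both zero by default.
#' @param phenotype_base also record phenotypes on founders (default TRUE).
#' @param seed optional RNG seed.
#' @return Object of class `animal_sim`: list with tibbles `pedigree`
#'   (animal, sire, dam, sex, generation), `phenotypes` (animal, sex,
#'   trait), `true_bv` (animal, bv), plus `h2`, `sigma2_a`, `sigma2_e` and
#'   the `relationship_factor` used for the Mendelian-sampling variances.
#' @examples
#' sim <- simulate_herd(h2 = 0.3, seed = 1)
#' nrow(sim$pedigree)
#' @export
simulate_herd <- function(h2 = 0.3, n_base_males = 20, n_base_females = 100,
                          n_generations = 5, dams_per_sire = 10,
                          offspring_per_dam = 20, phenotypic_variance = 1,
                          sex_effect = c(0, 0), phenotype_base = TRUE,
                          seed = NULL) {
  stopifnot(h2 > 0, h2 < 1, phenotypic_variance > 0,
            offspring_per_dam %% 2 == 0, length(sex_effect) == 2)
  if (n_base_males < 1 || n_base_females < dams_per_sire) {
    abort("not enough base animals for the mating design")
  }
  if (!is.null(seed)) set.seed(seed)
  s2a <- h2 * phenotypic_variance
  s2e <- (1 - h2) * phenotypic_variance

  n_base <- n_base_males + n_base_females
  sex <- c(rep("M", n_base_males), rep("F", n_base_females))
  sire <- rep(0L, n_base)
  dam <- rep(0L, n_base)
  gen <- rep(0L, n_base)
  males_prev <- seq_len(n_base_males)
  females_prev <- n_base_males + seq_len(n_base_females)
  next_id <- n_base + 1L
  per_dam_sex <- rep(c("M", "F"), each = offspring_per_dam / 2)

  for (g in seq_len(n_generations)) {
    sire_g <- if (length(males_prev) == 1L) males_prev else sample(males_prev, 1L)
    if (length(females_prev) < dams_per_sire) {
      abort("not enough candidate dams in the previous generation")
    }
    dams_g <- sample(females_prev, dams_per_sire)
    n_off <- dams_per_sire * offspring_per_dam
    ids_g <- seq.int(next_id, length.out = n_off)
    sire <- c(sire, rep(sire_g, n_off))
    dam <- c(dam, rep(dams_g, each = offspring_per_dam))
    sex <- c(sex, rep(per_dam_sex, times = dams_per_sire))
    gen <- c(gen, rep(g, n_off))
    males_prev <- ids_g[rep(per_dam_sex, dams_per_sire) == "M"]
    females_prev <- ids_g[rep(per_dam_sex, dams_per_sire) == "F"]
    next_id <- next_id + n_off
  }
  q <- next_id - 1L
  pedigree <- tibble::tibble(animal = seq_len(q), sire = sire, dam = dam,
                             sex = sex, generation = gen)
  rel <- relationship_factor(pedigree[, c("animal", "sire", "dam")])
  Fi <- diag(rel$A) - 1

  bv <- numeric(q)
  bv[seq_len(n_base)] <- rnorm(n_base, 0, sqrt(s2a))
  # generation by generation so parental BVs exist before use
  for (g in seq_len(n_generations)) {
    og <- which(gen == g)
    ms_sd <- sqrt(0.5 * s2a * (1 - 0.5 * (Fi[sire[og]] + Fi[dam[og]])))
    bv[og] <- 0.5 * (bv[sire[og]] + bv[dam[og]]) + rnorm(length(og), 0, ms_sd)
  }

  keep <- if (phenotype_base) seq_len(q) else which(gen > 0)
  trait <- ifelse(sex[keep] == "M", sex_effect[1], sex_effect[2]) +
    bv[keep] + rnorm(length(keep), 0, sqrt(s2e))
  phenotypes <- tibble::tibble(animal = keep, sex = factor(sex[keep]),
                               trait = trait)
  structure(list(pedigree = pedigree, phenotypes = phenotypes,
                 true_bv = tibble::tibble(animal = seq_len(q), bv = bv),
                 h2 = h2, sigma2_a = s2a, sigma2_e = s2e, rel = rel),
            class = "animal_sim")
}

#' @export
print.animal_sim <- function(x, ...) {
  cat("<animal_sim>", nrow(x$pedigree), "animals,",
      nrow(x$phenotypes), "records, true h2 =", x$h2, "\n")
  invisible(x)
}
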