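# Shared in-code fixtures for the test suite.

# Three founders + one offspring of 1 x 2; used for hand-checkable A.
ped_trio <- function() {
  tibble::tibble(animal = c(1L, 2L, 3L),
                 sire = c(0L, 0L, 1L),
                 dam = c(0L, 0L, 2L))
}

# Sire (1) x own daughter (3, out of dam 2) -> inbred offspring 4 (F = 0.25).
ped_sire_daughter <- function() {
  tibble::tibble(animal = 1:4,
                 sire = c(0L, 0L, 1L, 1L),
                 dam = c(0L, 0L, 2L, 3L))
}

# Small simulated herd for model/sampler tests (26 animals).
small_sim <- function(h2 = 0.4, seed = 42) {
  simulate_herd(h2 = h2, n_base_males = 3, n_base_females = 7,
                n_generations = 2, dams_per_sire = 2, offspring_per_dam = 4,
                seed = seed)
}

small_data <- function(h2 = 0.4, seed = 42) {
  sim <- small_sim(h2, seed)
  animal_model_data(sim$phenotypes, sim$pedigree)
}

# Central finite-difference gradient of f at x.
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Gene-dropping Monte Carlo estimate of relationship coefficients: drop two
# distinct alleles per founder, transmit one uniformly from each parent,
# estimate a_ij as twice the probability that random alleles from i and j
# are identical by descent. Independent oracle for build_A.
gene_drop_A <- function(pedigree, n_rep = 1e5) {
  ped <- ped_validate(pedigree)
  q <- nrow(ped)
  idx <- attr(ped, "id_index")
  si <- ifelse(ped$sire == 0, 0L, idx[as.character(ped$sire)])
  di <- ifelse(ped$dam == 0, 0L, idx[as.character(ped$dam)])
  A1 <- matrix(0L, q, n_rep)   # paternal allele label per replicate
  A2 <- matrix(0L, q, n_rep)   # maternal allele label
  for (i in seq_len(q)) {
    if (si[i] == 0L) A1[i, ] <- 2L * i - 1L
    else {
      pick <- runif(n_rep) < 0.5
      A1[i, ] <- ifelse(pick, A1[si[i], ], A2[si[i], ])
    }
    if (di[i] == 0L) A2[i, ] <- 2L * i
    else {
      pick <- runif(n_rep) < 0.5
      A2[i, ] <- ifelse(pick, A1[di[i], ], A2[di[i], ])
    }
  }
  A <- matrix(0, q, q)
  for (i in seq_len(q)) for (j in i:q) {
    pij <- mean((A1[i, ] == A1[j, ]) + (A1[i, ] == A2[j, ]) +
                (A2[i, ] == A1[j, ]) + (A2[i, ] == A2[j, ])) / 4
    A[i, j] <- A[j, i] <- 2 * pij
  }
  A
}
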