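---
title: "Bayesian animal models: Gibbs, HMC and NUTS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian animal models: Gibbs, HMC and NUTS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`pedmcmc` fits the univariate animal model

$$ y = Xb + Za + e, \qquad
   a \mid \sigma^2_a \sim N(0, A\,\sigma^2_a), \qquad
   e \sim N(0, I\,\sigma^2_e), $$

where $y$ holds $n$ phenotypic records, $b$ is a small vector of fixed
effects (flat prior), $a$ holds one additive-genetic effect (breeding
value) per animal in the pedigree, and $A$ is the additive relationship
matrix: twice the kinship implied by the pedigree, with diagonal $1 + F_i$
($F_i$ the inbreeding coefficient). The per-draw heritability
$h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_e)$ is stored with every
posterior draw; its posterior mean, Monte Carlo standard error, and the
accuracy (Pearson correlation) and unbiasedness (regression of truth on
estimate) of posterior-mean breeding values are the quantities a breeder
cares about.

Both variances carry improper flat priors on $(0, \infty)$. This is the
prior under which the analytic score equations used by the gradient-based
samplers are exact, and the Gibbs conditionals below are derived under the
same prior so that all three samplers target the identical posterior. Flat
variance priors need replication to yield a proper posterior: with only a
handful of animals and one record each the chain can be transient (the
package refuses $q \le 2$ or $n \le 2$ outright, where the inverse-gamma
conditionals are already improper); at the design scale this package aims
at (hundreds to thousands of animals) propriety is not a practical
concern.

## Pedigree machinery

`build_A()` uses the tabular recursion in topological order (parents
before offspring, enforced and re-sorted by `ped_validate()`):
$a_{ij} = (a_{j,s(i)} + a_{j,d(i)})/2$ and
$a_{ii} = 1 + a_{s(i),d(i)}/2$, with unknown parents contributing zero
(founder assumption). Dense storage is deliberate: at the package's design
scale ($q \approx 10^3$) A occupies ~10 MB and exactness beats sparse
machinery.

The samplers never factor $A$ per iteration. `relationship_factor()`
computes the lower Cholesky factor $L$ once, and — when the factor was
built from a pedigree rather than a raw matrix — also records the
Mendelian-sampling decomposition $A = T D T'$, where $T$ is unit lower
triangular with rows mixing each animal's parents and $D$ is diagonal with
$d_i = a_{ii} - (a_{ss} + a_{dd})/4 - a_{sd}/2$. Because
$L = T D^{1/2}$ and $T^{-1}$ has at most three nonzeros per row, products
with $L$ and $L'$ reduce to $O(q)$ recurrences over the pedigree (one pass
toward descendants, one pass toward ancestors). Every gradient evaluation
uses these recurrences; a dense fallback covers relationship matrices
supplied without pedigree structure. The two paths agree to machine
precision and are cross-checked in the test suite.

## Parameterization for the gradient samplers

HMC and NUTS sample the unconstrained vector
$\theta = (b, u, \log\sigma^2_a, \log\sigma^2_e)$ with

$$ a = \sigma_a L u, \qquad u \sim N(0, I). $$

This is the fully non-centered (whitened) parameterization: the prior on
$u$ is spherical and decoupled from $\sigma^2_a$. Whitening by $L$ alone
(leaving $u \sim N(0, I\sigma^2_a)$) retains a funnel-shaped geometry
between $u$ and $\log \sigma^2_a$ that demonstrably biases short
gradient-based runs: on a 520-animal dataset the L-only parameterization
gave a posterior-mean $h^2$ of 0.17 against 0.232 from exact 2-D grid
integration of the variance posterior (fixed effects and breeding values
integrated analytically), while the non-centered version and Gibbs
sampling both reproduce the grid value. The log-variance transform
contributes Jacobian terms $+\log\sigma^2_a + \log\sigma^2_e$; additive
constants are dropped consistently everywhere, so only differences of the
log density are meaningful, which is all any acceptance ratio needs.

The constrained-scale log posterior and its four analytic gradient blocks
(for $b$, $a$, $\sigma^2_a$, $\sigma^2_e$, with $A^{-1}a$ via two
triangular solves) are exported for testing and transparency
(`log_posterior()`, `grad_log_posterior()`); the samplers use the compiled
fused evaluation of the unconstrained density and gradient. Finite
difference agreement and constrained/unconstrained consistency (including
the $\partial/\partial\log\sigma^2 = \sigma^2\,\partial/\partial\sigma^2 + 1$
chain rule) are asserted in the test suite.

A note on sign conventions: with $U(\theta) = -\log f(\theta)$, Hamilton's
equations are $d\theta/dt = \partial H/\partial p$,
$dp/dt = -\partial H/\partial \theta$, and the leapfrog momentum half-step
is $p + \tfrac{\varepsilon}{2}\,\partial \log f/\partial\theta$. The
package follows this standard convention throughout; likewise the U-turn
rule tests the span $\theta^+ - \theta^-$ against **both** end momenta
(stop when either $(\theta^+-\theta^-)'p^- < 0$ or
$(\theta^+-\theta^-)'p^+ < 0$) — the orientation under which the criterion
detects contraction rather than expansion.

## The three samplers

**Gibbs sampling** (`gibbs_sampler()`) is single-site: each fixed effect
and each breeding value is drawn from its scalar normal full conditional
(mixed-model-equation mean; variance
$\sigma^2_e / (z_i'z_i + A^{ii}\sigma^2_e/\sigma^2_a)$ for animal $i$),
then $\sigma^2_a \sim \mathrm{IG}(q/2 - 1,\; a'A^{-1}a/2)$ and
$\sigma^2_e \sim \mathrm{IG}(n/2 - 1,\; e'e/2)$, inverse gamma in the
shape/rate parameterization (density $\propto x^{-\text{shape}-1}
e^{-\text{rate}/x}$). $A^{-1}$ is formed once from $L$. Single-site
updating is intentional: it is the classic scheme whose high
autocorrelation is part of what the sampler comparison measures. Default
initialization (used when none is given): $b = 0$, $a = 0$, both variances
at $\mathrm{var}(y)/2$; update order $b \to a \to \sigma^2_a \to
\sigma^2_e$.

**HMC** (`hmc_sampler()`) is the fixed-hyperparameter variant: full
momentum refresh each iteration, `n_leapfrog` leapfrog steps of size
`epsilon`, Metropolis correction
$\alpha = \min\{1, \exp(H_0 - H_1)\}$. The identity mass matrix is the
default; a diagonal one can be supplied. Trajectories whose energy error
exceeds 1000 (or that produce non-finite values) count as divergent and
are rejected; a post-burn-in acceptance rate under 1% triggers a warning —
the signature of a step size badly mismatched to the posterior scale.

**NUTS** (`nuts_sampler()`) removes the trajectory-length choice. Each
iteration draws a slice variable $u \mid \theta, p \sim
\mathrm{Uniform}(0, \exp(\log f(\theta) - p'M^{-1}p/2))$ (kept as
$\log u$ for numerical safety), then doubles a trajectory in a random
direction per doubling. States enter the candidate set when
$\log u \le \log f - p'M^{-1}p/2$; the memory-light transition kernel
adopts the new subtree's proposal with probability
$\min(1, |C^{new}|/|C^{old}|)$; the tree stops at a U-turn of the merged
span (checked at every subtree merge, not only the outermost — required
for a correct stopping rule), on a slice violation of more than 1000 on
the log scale (divergence), or at `max_depth` (default 10, counted and
reported). The per-iteration acceptance statistic $\alpha_j$ averages
$\min\{1, \text{joint ratio}\}$ over the states explored in the final
doubling.

Step-size adaptation uses dual averaging in the printed-recursion form

$$ \log \varepsilon_{j+1} = \mu - \frac{\sqrt{j}}{\gamma}\,
   \frac{1}{j + j_0} \sum_{i \le j} (\delta - \alpha_i), \qquad
   \log \bar\varepsilon_{j+1} = j^{-\kappa} \log \varepsilon_{j+1}
   + (1 - j^{-\kappa}) \log \bar\varepsilon_j, $$

with $\gamma = 0.05$, $j_0 = 10$, $\kappa = 0.75$, target $\delta = 0.6$
(the acceptance level reported as the efficiency optimum for this
algorithm family; configurable), $\mu = \log(10\,\varepsilon_1)$, and
$\varepsilon_1$ from a coarse doubling search for a one-step acceptance
near $1/2$. Adaptation runs only during warm-up; afterwards
$\varepsilon$ is frozen at $\exp(\log\bar\varepsilon)$. Optional diagonal
mass adaptation (off by default, since its windowing is otherwise
underdetermined) re-estimates $M$ twice during warm-up from recent draws
and restarts the step-size adaptation.

Initial unconstrained values for both gradient samplers are drawn
independently from $\mathrm{Uniform}(0, 1)$ per coordinate, applied to all
samplers' gradient-based runs for comparability.

## The simulator

`simulate_herd()` reproduces a deliberately harsh discrete-generation
design: a base population of 20 males and 100 females; five generations in
which **one** sire (drawn at random from the previous generation's males)
is mated to 10 dams (drawn without replacement from the previous
generation's females), each mating producing 10 male and 10 female
offspring — 200 per generation, 1000 over five generations, 1120 animals
in total. Breeding values follow the infinitesimal model: founders
$N(0, h^2\sigma^2_P)$; offspring get the mid-parent value plus a
Mendelian-sampling deviation with variance
$\tfrac{1}{2}\sigma^2_a (1 - \tfrac{1}{2}(F_s + F_d))$, with inbreeding
coefficients taken exactly from the diagonal of $A$. Phenotypes add a sex
mean and $N(0, (1-h^2)\sigma^2_P)$ noise, $\sigma^2_P = 1$.

Defaults the design leaves open, fixed once here: the sex effect is
$(0, 0)$ — sex is modeled in the analysis but truly null in the generator,
so fixed-effect estimation is exercised without injecting signal
(configurable for power checks); base animals are phenotyped
(`phenotype_base = FALSE` available); no selection is applied — the sire
is drawn at random, matching the stated design. The single-sire bottleneck
makes inbreeding accumulate quickly, which is the point: it stresses the
samplers with a strongly structured $A$.

What the generator does **not** emulate: genomes, markers, linkage, QTL,
mutation or drift in a historical population — the analysis is purely
pedigree-based, so the infinitesimal model is sufficient. Consequences for
interpretation: passing tests show the samplers recover parameters of
data generated exactly under the fitted model; they say nothing about
model misspecification, genotyped populations, selection, or maternal and
permanent-environment effects.

## Diagnostics

`effective_sample_size()` uses the AR-spectral method: fit an
autoregressive model with AIC-selected order, take the spectral density at
frequency zero, and set $\mathrm{ESS} = n\,\mathrm{var} / S(0)$ — the
estimator is not capped at $n$. A batch-means ESS
(`ess_batch_means()`, $\sqrt n$ batches) is reported alongside as a
robustness column; it is a different estimator and is documented as such.
`mcse()` is posterior SD$/\sqrt{\mathrm{ESS}}$. `autocorr()` is the
standard sample autocorrelation (overall-mean centering, lag-0
normalization), reported at lags 1, 5, 10 and 50. Skewness uses the
adjusted Fisher–Pearson estimator
$G_1 = g_1 \sqrt{n(n-1)}/(n-2)$. EBV accuracy is the Pearson correlation
of true and posterior-mean breeding values; unbiasedness is the OLS slope
of truth on estimate (1 = unbiased); the posterior mean is used as the
point estimator throughout.

## Study sizes and numerical choices

`replicate_study()` runs the full factorial (three heritabilities,
replicates, samplers) and aggregates per-replicate and replicate-averaged
summaries. The package's own test suite exercises the complete design —
1120 animals per replicate, five replicates per scenario, all three
samplers on identical datasets. Gibbs chains run the full 10,000
iterations (1,000 burn-in); NUTS uses 4000 and HMC 2500 iterations, whose
posterior means are invariant to chain length at the effective sample
sizes involved (checked directly: the NUTS low-heritability cell moves by
0.001 between 4000- and 10,000-iteration chains). The bundled acceptance
script uses full 10,000-iteration chains for both samplers it compares,
with two replicates per scenario. ESS-based comparisons are always made
between chains of equal length.
Replicate-to-replicate spread dominates every comparison at low
heritability: with $h^2 = 0.1$ the posterior mean of $h^2$ across
replicates of this design ranges roughly 0.04–0.20, and EBV regression
slopes swing accordingly — single-replicate results at low $h^2$ should
never be over-read.

Numerical details fixed by the implementation: divergence threshold 1000
on the log scale (both samplers); `max_depth` 10; slice variable kept in
logs; $X$ uses treatment coding with an intercept and drops
rank-deficient columns so the flat prior on $b$ is identifiable;
constants of the log density are omitted consistently; the Cholesky
reconstruction is verified to a relative $10^{-10}$ at factor time.

## Known limitations

Single-trait, single chain per run (no R-hat), no maternal or genomic
effects, no informative variance priors (scaled-inverse-$\chi^2$ variants
would change the conditionals and score equations), and the flat-prior
propriety caveat at very small scale noted above. HMC with a fixed,
user-chosen step size remains fragile on posteriors whose scales vary
across parameters — precisely the behavior the sampler comparison is
designed to expose; NUTS with adaptation is the robust default.
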