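---
title: "Hierarchical ABC tests of simultaneous divergence and migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical ABC tests of simultaneous divergence and migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The inference problem

Comparative phylogeography asks whether a set of co-distributed taxon-pairs
— sister populations split by the same putative barrier — diverged at the
same time, and whether gene flow continued after divergence. `codiverge`
addresses this with hierarchical approximate Bayesian computation (HABC):
per-taxon demographic parameters and per-locus mutation parameters vary
freely across the `Y` taxon-pairs, conditional on hyper-parameters that
describe the community-level pattern:

* `Psi` — the number of distinct divergence times among the `Y` pairs,
  with a discrete uniform prior on `1..Y`; `Psi = 1` is simultaneous
  divergence;
* `E(tau)` — the mean divergence time;
* `Omega = Var(tau) / E(tau)` — the dispersion index of divergence times,
  0 under simultaneous divergence;
* `Z` — a categorical indicator over candidate post-divergence migration
  models (e.g. strict isolation versus symmetric migration with `Nm` up to
  1 or up to 10 migrants per generation).

Because the likelihood of a multi-taxon, multi-locus coalescent model is
intractable, inference is simulation-based: data sets are simulated from
the joint prior, reduced to a summary-statistic vector, and the draws whose
summaries fall closest to the observed summaries are retained and
regression-adjusted.

## The demographic and mutational model

Each taxon-pair descends from an ancestral population of per-site scaled
size `theta_A` that splits at time `tau` into two populations of sizes
`theta_A1`, `theta_A2` (uniform fractions of `theta_A`), which grow
exponentially to their current sizes `theta_B1`, `theta_B2` beginning at
times `tau_B1`, `tau_B2` (uniform fractions of `tau`, so growth never
predates the split). Between the present and `tau` the two descendants
exchange migrants symmetrically at rate `Nm`. All of these vary
independently across taxon-pairs under uniform priors.

**Units.** Divergence times are in coalescent units of 4N generations
where N is the *sum* of the current effective sizes of the two
descendants. Operationally the simulator sets `theta_ref = theta_B1 +
theta_B2`; a pair of lineages in a deme of size `theta_d` coalesces at
rate `theta_ref / theta_d`, the backward per-lineage migration rate is
`2 Nm theta_ref / theta_d(t)`, and mutation events occur per site at rate
`theta_eff / 2` per unit branch time. This convention is self-consistent
and is pinned by a property test: in the single-population limit the
expected per-site heterozygosity equals `theta`. Other simulators may
differ from it by a constant factor, so times should always be read in
this package's units.

Within an epoch every deme size is constant or exponential in time, so
waiting times are drawn exactly by inverting each event class's integrated
hazard in closed form (no time-stepping); at epoch boundaries the
memorylessness of the jump process justifies redrawing.

**Sequence evolution** is finite-sites: the number of substitution events
is Poisson on total tree length, events land on branches by length and on
sites uniformly, and repeat hits are allowed. Each event replaces the
current base via the model's jump distribution — JC: uniform over the
other three bases; equal-input (F81, the default): proportional to the
equilibrium frequencies of the other three; HKY: transitions additionally
weighted by `kappa`. Drawing the replacement from the *other three* bases
makes the JC chain match the standard closed form
`p = 3/4 (1 - exp(-4/3 mu b))`, which is tested; for unequal frequencies
this jump convention is an approximation to the exact equal-input process
whose stationary distribution deviates slightly from the input
frequencies. The root sequence is drawn from the equilibrium frequencies.

**Rate heterogeneity.** Relative substitution rates vary across loci as
i.i.d. Gamma(shape `alpha`, scale `1/alpha`) scalars (mean 1). One
`alpha` is drawn per simulated data set from a uniform hyper-prior on
(1, 20) and shared across that data set's loci, treating the shape as a
data-set-level uncertainty; per-locus scalars still differ. Loci with
prior rate information can be pinned to fixed scalars, and a per-locus
inheritance scalar (e.g. 0.25 for mtDNA) multiplies the locus `theta`.

**Divergence-time assignment.** A draw of `Psi` is followed by `Psi`
i.i.d. uniform times; a uniformly chosen subset of `Psi` pairs receives
one distinct time each, and the remaining pairs sample from those times
with replacement — so the number of distinct values always equals `Psi`,
and `Omega = 0` exactly when `Psi = 1`. `Omega` uses the population
variance (denominator `Y`) so it is exactly 0 for coincident times
regardless of `Y`; the convention is recorded in the reference-table
manifest.

## Summary statistics, the tensor D and the moment vector D_m

From every locus of every pair the package computes three categories of
statistics: pooled-sample (`pi`, Watterson's `theta_W`, `SD(pi -
theta_W)`, Shannon's index on haplotypes, Wakeley's within-sample
correlation `s`), the same per descendant population, and
between-population statistics (`pi_b`, `pi_net`, and the interpopulation
correlations `s_XY` and `Psi_W`). Choices worth noting:

* everything is on the per-locus *count* scale (not per site): moments and
  the `pi_b` ordering are scale-consistent either way and counts avoid
  length-division conventions; the scale is recorded in the manifest;
* `SD(pi - theta_W)` uses the Tajima (1989) moment estimator
  `e1 S + e2 S (S - 1)` — the standard normalisation of the D statistic's
  numerator — because it depends only on `(n, S)` and is cheap;
* the interpopulation correlations consider cross-population sequence
  pairs sharing exactly one member; `s_XY` normalises the shared-member
  covariance by the variance of the cross differences, `Psi_W` by their
  mean. The cited derivations do not print a formula, so this
  normalisation pair is the package's explicit, documented choice (also
  flagged in the source); both are symmetric under population relabelling
  and both carry the migration signal that motivates them — migration
  decouples coalescent times from the divergence time, deflating the
  shared-member correlation;
* statistics undefined at a locus's sample sizes (e.g. within-population
  diversity with one sequence) are masked, and masks are part of the
  layout so observed and simulated vectors always align; monomorphic
  (zero-variance) correlation cases return 0 rather than a mask so the
  vector layout never depends on the simulated data.

Per class and pair the raw moments `m_k = mean(value^k)` (up to 4) are
taken across loci, collapsing the ragged locus dimension; pairs may have
different numbers of loci. Finally all classes' pair slots are re-ordered
jointly by descending mean `pi_b`. Expected `pi_b` tracks each pair's
divergence time and is exchangeable across sampling configurations, so the
sorting makes Euclidean distances independent of the arbitrary input order
of pairs and concentrates `Omega` information; the validation harness
quantifies the gain and shows it grows with `Y`.

## ABC: rejection and regression adjustment

Reference-table coordinates are scaled to unit variance (zero-variance
coordinates are dropped and logged — dropping is reproducible, unlike
epsilon-inflation). Rejection keeps the `n_accept` rows with the smallest
Euclidean distance, ties broken by row order. Epanechnikov kernel weights
with bandwidth equal to the largest accepted distance (the cited scheme's
standard choice, sending boundary points to weight 0) feed:

* **local-linear adjustment** of continuous hyper-parameters — weighted
  least squares of the target on the summary deviations, each accepted
  value shifted to the regression's prediction at the observed point and
  truncated to the prior support; a singular design falls back to the raw
  values with a warning;
* **polychotomous regression** for `Psi` and the model indicator —
  kernel-weighted multinomial logistic regression evaluated at the
  observed point, with a ridge (weight-decay) penalty of 1e-6 so
  quasi-separated fits remain deterministic; non-convergence falls back to
  weighted accepted frequencies. Both raw accepted frequencies and
  adjusted probabilities are reported; Bayes factors use the adjusted
  values by default, since regression adjustment materially improves
  model-choice calibration in the validation experiments.

Point estimates are kernel-density modes (Gaussian kernel, Silverman
bandwidth) with boundary reflection where support is bounded, so the
`Omega = 0` boundary mode under simultaneous divergence is not smoothed
away. Model-averaged ("mixed") summaries weight the joint accepted set by
`p_z / n_z` per model, which is equivalent to concatenating per-model
accepted draws in proportion to their posterior probabilities.

## Default priors and study conditions

The uniform bounds used by the validation harness are explicit
configuration, chosen once as plausible for intraspecific phylogeographic
data: `tau ~ U(0, 5)` (coalescent units), per-site `theta ~ U(1e-4,
0.01)` for ancestral and current sizes, fractions `U(0, 1)` for split
sizes and growth-onset times, loci of 1100 bp, and five sequences per
descendant population (sample sizes are not dictated by the experiments'
sources, so this is the package's own realistic choice). The three
candidate migration models are isolation and symmetric `Nm` uniform on
(0, 1) and (0, 10).

## The validation harness and what it does (not) show

`generate_pods()` simulates pseudo-observed data sets with recorded truths
under the same sampling configuration as the reference table —
configuration mismatch is the cardinal sin of ABC validation. The three
packaged experiments are:

* `experiment_sorting()` — `Psi = 1` PODS for `Y = 5, 10, 20`; `Omega`
  estimated with `pi_b`-sorted versus sample-size-ordered `D_m` (4 loci,
  varying sample sizes across pairs so size-ordering is a genuine
  alternative); paired per PODS;
* `experiment_loci()` — RMSE of `E(tau)` and `Omega` for 1, 4, 16 and 64
  loci. Rate heterogeneity makes few-locus `E(tau)` estimation *worse*
  than single-locus before enough loci average it out — the
  characteristic non-monotonic dip at 4 loci;
* `experiment_model_choice()` — a joint reference table with the three
  migration models in equal proportion; accuracy of choosing the true
  model per PODS, with and without polychotomous regression, for `D_m` =
  mean `pi_b` versus mean `pi_b` + `Psi_W`. Ties break toward the first
  (isolation) model.

Problem sizes are the package's desk-scale defaults: reference tables of
1e5 rows for model choice and 3e4 rows for the sorting and loci
experiments (6e4 and 2e4 respectively in the acceptance script), 40-50
PODS and 500 accepted draws. The original experimental design at 1.5-3 million rows and 100
PODS is reproducible by passing larger `n_sims`/`n_pods`; at desk scale
RMSE *levels* carry Monte-Carlo noise and should be read as trends
(ordering across locus counts, advantage of sorting), not as absolute
accuracies.

The generator emulates unlinked loci under divergence-with-migration and
growth with finite-sites mutation. It does not emulate intragenic
recombination (simulated loci are non-recombining blocks; recombining
empirical loci should be trimmed accordingly), selection, indels or
alignment error (gapped or ambiguous columns are simply dropped
list-wise), linked loci, or more than two descendant populations. Passing
validation therefore says nothing about robustness to those features.

## Numerical and interface decisions

* All randomness — including inside the C++ simulator — flows through R's
  RNG, so `set.seed()` makes every pipeline stage reproducible, and the
  batch reference-table driver consumes the stream in exactly the same
  order as the single-locus functions (tested).
* The reference table is tab-delimited text with a JSON manifest line:
  diffable, language-neutral, and bit-exact on round trip (`%.17g`).
* FASTA population membership uses a `pop=1|2` description tag — the
  package's own dialect, since none is standard; IM-format input is also
  parsed (model codes `I`/`J` to JC, `F` to F81, `H` to HKY).
* A pair with *no* unmasked locus for a selected statistic class is an
  error naming the pair, not a silent drop.
* Ties in sorting and rejection always break by original index, so runs
  are exactly reproducible across platforms.

## A minimal analysis

```{r example}
library(codiverge)
set.seed(1)

cfg <- sampling_config(config_template(Y = 3, n_loci = 8, n1 = 5, n2 = 5,
                                       L = 600))
prior <- prior_spec(migration_models = tibble::tibble(
  label = c("isolation", "migration"), nm_lo = c(0, 0), nm_hi = c(0, 1)))

# "observed" data: one draw from the prior, simulated and summarised
truth <- draw_hyper(cfg, prior)
obs <- observed_moment_vector(simulate_dataset(truth, cfg),
                              classes = c("pi_b", "psi_w"), n_moments = 1)

ref <- simulate_reference_table(cfg, prior, 2e4,
                                classes = c("pi_b", "psi_w"), n_moments = 1)
fit <- abc_fit(ref, obs, n_accept = 500, prior = prior)
fit
glance(fit)
autoplot(fit)
```
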