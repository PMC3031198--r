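# codiverge

Hierarchical approximate Bayesian computation (HABC) for comparative
phylogeography: given multi-locus DNA sequence data from multiple
codistributed taxon-pairs, `codiverge` tests whether the pairs diverged
simultaneously, estimates how variable their divergence times are, and
chooses among candidate post-divergence migration models.

## The model in brief

Each of `Y` taxon-pairs descends from an ancestral population (per-site
scaled size θ_A) that splits at time τ (coalescent units of 4N
generations, N the sum of the current descendant sizes) into two
populations that grow exponentially to sizes θ_B1, θ_B2 and exchange
migrants symmetrically at rate Nm. Per-taxon parameters vary freely under
uniform priors, governed by community-level hyper-parameters:

- **Ψ** — number of distinct divergence times among the `Y` pairs
  (discrete uniform on 1..Y; Ψ = 1 ⇔ simultaneous divergence),
- **E(τ)** — mean divergence time,
- **Ω = Var(τ)/E(τ)** — dispersion index of divergence times (0 under
  simultaneous divergence),
- **Z** — indicator over candidate migration models.

Sequence data are simulated under a structured coalescent with
finite-sites mutation (JC / equal-input F81 / HKY) and gamma rate
heterogeneity across loci (shape α ~ U(1, 20), mean scalar 1). Each
simulated data set is reduced to **D_m**: per statistic class and
taxon-pair, the first ≤ 4 raw moments across loci, with pair slots sorted
by descending mean between-population divergence π_b so that Euclidean
distances do not depend on the arbitrary ordering of pairs. Implemented
statistic classes include π (pooled/within), Watterson's θ_W,
SD(π − θ_W), Shannon's haplotype index, Wakeley's correlation s, and the
between-population π_b, π_net, s_XY and Ψ_W. Inference is rejection ABC
on unit-variance-scaled coordinates followed by local-linear regression
(continuous hyper-parameters) and ridge-stabilised polychotomous
regression (Ψ, Z), with KDE posterior modes and Bayes factors such as
B(Ψ = 1, Ψ > 1).

A PODS (pseudo-observed data sets) validation harness reproduces the
method's calibration experiments: the advantage of π_b sorting, RMSE
versus number of loci, and migration-model-choice accuracy with and
without Wakeley's Ψ_W.

## Worked example

Simulate an "observed" three-pair, eight-locus data set from a known
history, then infer its hyper-parameters with a 20,000-row reference
table:

```r
library(codiverge)
set.seed(1)

cfg <- sampling_config(config_template(Y = 3, n_loci = 8, n1 = 5, n2 = 5,
                                       L = 600))
prior <- prior_spec(migration_models = tibble::tibble(
  label = c("isolation", "migration"), nm_lo = c(0, 0), nm_hi = c(0, 1)))

truth <- draw_hyper(cfg, prior)
truth
#> hyper_draw: Z = 1, Psi = 3, E(tau) = 3.347, Omega = 0.8172

obs <- observed_moment_vector(simulate_dataset(truth, cfg),
                              classes = c("pi_b", "psi_w"), n_moments = 1)
ref <- simulate_reference_table(cfg, prior, 2e4,
                                classes = c("pi_b", "psi_w"), n_moments = 1)
fit <- abc_fit(ref, obs, n_accept = 500, prior = prior)
fit
#> habc_fit: 500 accepted of 20000 simulations
#>   mode e_tau = 3.198
#>   mode omega = 0.6134
#>   Pr(Psi = 1 | D) = 0.094 (adjusted), B(Psi=1, Psi>1) = 0.208
#>   Pr(Z | D): 1 = 1.000, 2 = 0.000
```

The true history had three distinct divergence times (Ψ = 3,
Ω = 0.82) under isolation: the fit recovers E(τ) (3.20 vs 3.35) and a
clearly positive dispersion (Ω̂ = 0.61), assigns low posterior
probability (0.09) to simultaneous divergence — a Bayes factor of 0.21,
i.e. evidence *against* Ψ = 1 — and picks the isolation model. `tidy()`,
`glance()` and `autoplot()` give the accepted/adjusted draws, a one-row
summary and diagnostic histograms.

Validation experiments are one call each, e.g.:

```r
rep <- experiment_model_choice(
  sampling_config(config_template(5, 16, n1 = 5, n2 = 5, L = 1100)),
  prior_spec(migration_models = tibble::tibble(
    label = c("isolation", "nm1", "nm10"),
    nm_lo = 0, nm_hi = c(0, 1, 10))),
  n_sims = 1e5, n_pods_per_model = 50)
model_choice_summary(rep)
```

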