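# nitratrace

Nitrate pollution source apportionment for surface and ground water from
dual nitrate isotopes (δ¹⁵N–NO₃⁻, δ¹⁸O–NO₃⁻), for hydrologists and
environmental biogeochemists who need a reproducible, testable version of
the cluster-then-mix workflow: group water samples by hierarchical
clustering on their isotope values, quantify per-group source
contributions with a Bayesian isotope mixing model, and screen each
region for the nitrogen-cycle processes (nitrification, denitrification,
mixing) that can distort the source signal.

## The model

Each water sample's isotope value is a proportion-weighted combination of
K nitrate endmembers (chemical fertilizer CF, manure & sewage MS,
atmospheric precipitation NP, soil nitrogen SN) plus error:

```
X_ij = Σ_k P_k (S_jk + C_jk) + ε_ij        j ∈ {δ¹⁵N, δ¹⁸O}
S_jk ~ N(μ_jk, ω_jk²)     source signature
C_jk ~ N(λ_jk, τ_jk²)     fractionation offset (0 for conservative mixing)
ε_ij ~ N(0, σ_j²)         residual
```

with the proportions P on the simplex. Marginalizing the per-observation
latent draws gives the closed-form likelihood used for inference:
`X_ij ~ N(Σ_k P_k (μ_jk + λ_jk), Σ_k P_k² (ω_jk² + τ_jk²) + σ_j²)`.
The prior is Dirichlet(1, …, 1) on P (uniform over the simplex) and
half-Normal(20‰) on each σ_j; the posterior is sampled by seeded
adaptive random-walk Metropolis on an unconstrained parameterization,
with split-R̂ convergence gating.

Around the mixing model the package provides:

* **Clustering** — Ward's minimum-variance linkage on squared Euclidean
  distances over the two tracers, per water type, scored by the goodness
  of variance fit `GVF = 1 − SDCM/SDAM` (SDAM: total squared deviation
  about the grand mean; SDCM: the same about each class mean).
* **Diagnostics** — the theoretical nitrification window
  `δ¹⁸O–NO₃⁻ ∈ ⅓·δ¹⁸O–O₂ + ⅔·δ¹⁸O–H₂O` over the local water range;
  Pearson screens for Rayleigh denitrification (δ¹⁵N vs ln NO₃⁻,
  δ¹⁸O vs δ¹⁵N) and pollution input (conductivity vs NO₃⁻); WHO and
  class-V exceedance flags.
* **Synthetic data** — generators that follow the mixing model's own
  generative story with known true proportions, optional Rayleigh
  denitrification (`δ ← δ + ε·ln f`), and a packaged four-group basin
  scenario, so every stage is testable against ground truth.

## Worked example

```r
library(nitratrace)

ds <- generate_basin_scenario(seed = 1)   # 29 surface + 33 ground samples
ds
#> Synthetic tracer dataset: 62 samples in 4 group(s)
#>   A: n = 13, true P = [CF 0.37, MS 0.12, NP 0.10, SN 0.41]
#>   B: n = 16, true P = [CF 0.18, MS 0.50, NP 0.07, SN 0.25]
#>   C: n = 15, true P = [CF 0.27, MS 0.33, NP 0.06, SN 0.34]
#>   D: n = 18, true P = [CF 0.05, MS 0.80, NP 0.07, SN 0.08]
#>   denitrified samples: 6

cl <- cluster_water_samples(ds$samples)
cl$surface
#> Ward clustering (surface): 29 samples into k = 2 groups
#>   sizes: 13, 16
#>   partition GVF: 0.842
#>   per-group GVF: 1=0.908, 2=0.773
```

The partition GVF says the two-group cut explains 84% of the surface
samples' pooled isotope variance. Fitting the mixing model to the
lowland-well group (true MS proportion 0.80):

```r
ids <- ds$truth$per_sample$sample_id[ds$truth$per_sample$group == "D"]
post <- fit_mixing_model(ds$samples[ds$samples$sample_id %in% ids, ],
                         basin_source_profiles(),
                         mcmc = mcmc_config(n_chains = 3, n_iter = 20000,
                                            n_burn = 10000, rng_seed = 1),
                         group_label = "D")
post
#> Bayesian mixing posterior for group 'D': 3000 retained draws, 3 chains
#>   max split-Rhat: 1.0028 (converged)
#>   contribution rates (mean +/- SD, %):
#>     CF    4.6 +/-  3.1
#>     MS   82.4 +/-  3.8
#>     NP    7.0 +/-  1.1
#>     SN    6.0 +/-  3.9
```

The posterior mean MS contribution (82.4%) recovers the generating 80%
within its posterior SD. The nitrification window for the basin's water
δ¹⁸O range:

```r
nitrification_o18_range(-8.7, -4.8)
#> Nitrification d18O-NO3 window: [+2.03, +4.63] permil
#>   (d18O-O2 = +23.5, d18O-H2O in [-8.7, -4.8])
```

The whole workflow (cluster → per-group mixing → diagnostics → CSV/JSON
outputs plus a run manifest) runs as one call,
`run_cluster_then_mix(samples, sources, config, out_dir)`, or from a
shell via the thin wrapper:

```sh
Rscript inst/scripts/nitratrace-cli.R simulate --scenario basin-demo --seed 1 --out demo
Rscript inst/scripts/nitratrace-cli.R run-all --samples demo/samples.csv \
    --sources demo/sources.csv --out demo/run --seed 1
```

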