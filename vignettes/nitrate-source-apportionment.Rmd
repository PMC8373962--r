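---
title: "Nitrate source apportionment: models, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nitrate source apportionment: models, diagnostics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitratrace)
```

This vignette is the package's own account of the science it implements:
the statistical models, their assumptions, the tunable parameters and
why their defaults are what they are, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the
design was genuinely open.

## 1. The problem

Dissolved nitrate in a basin's surface and ground water carries two
isotopic fingerprints — δ¹⁵N–NO₃⁻ (‰ vs air-N₂) and δ¹⁸O–NO₃⁻ (‰ vs
VSMOW) — that differ systematically between its main anthropogenic and
natural sources: chemical fertilizer (CF), manure and sewage (MS,
treated as one endmember because their nitrogen isotopes overlap),
atmospheric precipitation (NP) and soil nitrogen (SN). Two tracers
cannot resolve source contributions sample by sample, and basin-wide
averages hide spatial structure, so the workflow here first groups
samples by their isotope values (separately for surface and ground
water), then estimates source contributions per group, and finally
screens each region for the nitrogen-cycle processes — nitrification,
denitrification, water mixing — that alter isotope values after the
sources have mixed and would otherwise be misread as source signal.

## 2. Clustering and the GVF score

Samples of one water type are agglomerated by Ward's minimum-variance
criterion on squared Euclidean distances over the raw (δ¹⁵N, δ¹⁸O)
pairs. The tracers are not standardized by default: both share the ‰
scale, and rescaling would silently reweight them. Standardization is
available as an off-by-default option for users who add tracers on
other scales.

Cut quality is scored by the goodness of variance fit,

$$\mathrm{GVF} = 1 - \mathrm{SDCM}/\mathrm{SDAM},$$

where SDAM is the pooled sum of squared deviations of all samples from
the grand per-tracer mean and SDCM the same quantity about each class's
own mean. Tracer dimensions are pooled by summation, consistent with
the squared-Euclidean geometry of the linkage; GVF is therefore
monotone non-decreasing along nested cuts, 0 for a single class and 1
for singletons. A per-group variant is also reported: one minus the
ratio of a group's within-group sum of squares to the sum of squares of
the same members about the grand mean of all samples of that water
type. GVF is classically a partition-level statistic; this per-group
construction is this package's interpretation of per-group quality
reporting and is documented as such rather than as a standard
definition. Degenerate inputs (all samples identical, singleton groups)
are defined to score 1, with a notice.

Implementation notes: the linkage is computed by `stats::hclust`
(`ward.D` on squared distances), whose merge heights equal twice the
increase in within-cluster sum of squares; the package reports the
increase itself as the merge cost and verifies, in its test suite, that
merge costs and flat cuts agree with a from-scratch O(n³) agglomeration
oracle across 100 seeded random instances. Flat cuts number their
clusters 1..k by order of each cluster's first member, so labels are
deterministic under row order; when all pairwise distances are distinct
the partition itself is invariant to row order.

## 3. The Bayesian mixing model

Each observation is modelled as

$$X_{ij} = \sum_{k=1}^{K} P_k\,(S_{jk} + C_{jk}) + \varepsilon_{ij},
\qquad S_{jk} \sim N(\mu_{jk}, \omega_{jk}^2),\;
C_{jk} \sim N(\lambda_{jk}, \tau_{jk}^2),\;
\varepsilon_{ij} \sim N(0, \sigma_j^2),$$

with source and fractionation values drawn independently per
observation. Marginalizing the latents gives the likelihood actually
evaluated:

$$X_{ij} \sim N\!\Big(\textstyle\sum_k P_k(\mu_{jk}+\lambda_{jk}),\;
\sum_k P_k^2(\omega_{jk}^2+\tau_{jk}^2) + \sigma_j^2\Big).$$

The independent-per-observation error structure is one of several used
in mixing-model practice; it has a closed form, and the test suite
checks it against numerical convolution of the latent normal densities.
Fractionation defaults to λ = τ = 0 for all nitrate sources
(conservative mixing, the convention in nitrate studies); nonzero
tables are accepted.

**Priors.** Dirichlet(1, …, 1) on P — uniform over the simplex, so the
posterior is driven by the data and the source geometry — and
independent half-Normal(s₀ = 20 ‰) on each residual scale σ_j, weakly
informative on the ‰ scale of the tracers. Both are configurable.

**Sampler.** Seeded random-walk Metropolis on an unconstrained
parameterization: multinomial-logit coordinates for P (last logit
pinned at zero) and log σ, with the simplex and positivity Jacobians
included. During burn-in only, two things adapt: each block's step
scale (targeting ≈ 0.3 acceptance) and the proposal *shape* for the
proportion block, taken from the empirical covariance of the burn-in
logit draws (adaptive-Metropolis style). Both are frozen at the end of
burn-in, so the retained portion of every chain is a fixed-kernel
Metropolis chain with detailed balance. The shape adaptation matters:
with K = 4 sources and J = 2 tracers the proportion posterior
concentrates on a one-dimensional ridge (see §5), and isotropic
proposals mix poorly along it — in development runs split-R̂ stalled
near 1.5 with isotropic steps and drops to ≈ 1.0 with the adapted
shape at the same chain length.

**Convergence.** Plain split-R̂ per parameter (each chain halved;
Gelman–Rubin ratio over the halves). Fits whose worst R̂ exceeds the
configured threshold (default 1.05) still return their draws but refuse
to auto-summarize, with a warning — reproducibility of a bad fit is
preserved while accidental use of its summary is not. Identical
configurations (including seed) reproduce draws bit for bit; chains are
consumed sequentially from one seeded stream.

**Defaults.** 3 chains × 50,000 iterations, 25,000 burn-in, thinning
10. For the package's own acceptance runs the fits use 3 × 20,000
(burn-in 10,000, thin 10), which the convergence diagnostics show is
sufficient for the packaged scenario's group sizes (R̂ ≤ ≈1.08) while
keeping a full four-group run near ten seconds.

## 4. Screening diagnostics

**Nitrification window.** Nitrate produced by nitrification takes about
one third of its oxygen from dissolved O₂ and two thirds from ambient
water, so its δ¹⁸O should lie in
$[\,\tfrac13\delta^{18}O_{O_2} + \tfrac23\delta^{18}O_{H_2O}^{min},\;
\tfrac13\delta^{18}O_{O_2} + \tfrac23\delta^{18}O_{H_2O}^{max}\,]$
with δ¹⁸O–O₂ = +23.5 ‰ by default. Samples are classified
within/above/below against the closed interval; values above the window
suggest soil-derived nitrate or denitrification enrichment, values
below suggest oxygen exchange with unevaporated soil water.

**Denitrification screen.** Rayleigh consumption of a nitrate pool
enriches the residue, producing a linear δ¹⁵N vs ln NO₃⁻ relation with
slope −ε and a coupled δ¹⁵N–δ¹⁸O rise. The screen computes Pearson r
with two-tailed t-based p-values for (a) δ¹⁵N vs ln NO₃⁻, (b) δ¹⁸O vs
δ¹⁵N and (c) conductivity vs NO₃⁻, dropping incomplete pairs (and, for
(a), non-positive concentrations, whose logarithm is undefined). The
interpretation rule codifies the standard narrative declaratively:
significant negative (a) or significant positive (b) →
`denitrification_signal`; significant negative (b) → `mixing_or_none`
(mixing without heavy-isotope enrichment); significant positive (c) →
`pollution_input_signal` (conductivity tracks sewage/manure input, not
denitrification); otherwise `not_significant`. The default α is 0.01
two-tailed, with 0.05 the documented alternative; the level is a
config value because published practice uses both.

**Exceedance flags.** Strict comparisons against a drinking-water
nitrate guideline (default 50 mg/L as NO₃⁻) and a configurable
total-nitrogen class threshold (shipped default 2.0 mg/L). The TN
threshold is an external-standard constant supplied for convenience
rather than a packaged scientific claim. Missing concentrations yield
not-evaluable flags, never FALSE. Concentrations are stored exactly as
given (mg/L of the stated species) with no nitrogen-equivalent
conversion, because survey tables frequently report NO₃⁻ and TN in
ways that leave the species convention ambiguous; converting silently
would be worse than not converting.

## 5. The synthetic generator and scenario design

`generate_mixture_samples()` follows the mixing model's generative
story exactly — fresh S and C draws per sample, residual noise, group
proportions on the simplex — plus a lognormal NO₃⁻ concentration model
(positivity, so ln NO₃⁻ is always defined), TN = NO₃⁻ + NH₄⁺ + a small
organic remainder, a linear conductivity model, and ambient-water δ¹⁸O
uniform on (−8.7, −4.8) ‰. `apply_rayleigh_denitrification()` then
imposes δ ← δ + ε ln f, NO₃⁻ ← f·NO₃⁻ on an affected subset, with a
2:1 N:O enrichment ratio by default (configurable; the ratio is a
convention, not a law).

The packaged basin scenario fixes the study conditions: 29 surface
samples in two groups (A, n = 13, mid-upper reaches; B, n = 16, lake
and lower reaches) and 33 ground samples in two groups (C, n = 15;
D, n = 18, lowland wells), four sources with the qualitative geometry
of published source boxes (CF low in both isotopes; SN intermediate
δ¹⁵N, low δ¹⁸O; MS high δ¹⁵N; NP very high δ¹⁸O), residual σ = 0.5 ‰,
and six of D's wells denitrified with ε = −10 ‰, f ∈ (0.6, 1).

Two design points deserve emphasis:

* **Identifiability.** With two tracers and four sources, any mixture
  mean inside the source hull is reproduced by a one-dimensional family
  of proportion vectors (the null space of the 2×4 mean matrix plus the
  sum constraint). Under the flat Dirichlet prior the posterior mean
  lands near the middle of the feasible segment of that family, not at
  an arbitrary generating point. The scenario's true proportions were
  therefore chosen (once, at design time, by computing the feasible
  segments) to be approximate fixed points of that map — truths the
  model *can* recover — while keeping the intended qualitative pattern:
  soil nitrogen and fertilizer dominate group A, manure/sewage and
  fertilizer dominate group B, group C is mixed, and group D is
  manure/sewage-dominated at exactly P_MS = 0.80. This is why the
  packaged source table is marked illustrative: its exact values exist
  to preserve that identifiability geometry, not to be cited.
* **Denitrification vs recovery.** Rayleigh enrichment moves a group's
  isotope centroid after mixing, which biases that group's apportionment
  — exactly the confound the diagnostics exist to catch. The scenario
  keeps the denitrified subgroup small and mild (mean δ¹⁵N shift
  ≈ +0.8 ‰ at group level) so that group D's recovery stays within
  ±0.10 of truth, and provides a separate, stronger `rayleigh-demo`
  scenario (n = 30, f ∈ (0.2, 1)) for exercising the screen's power.

What the generator does *not* emulate: spatial autocorrelation,
seasonality, concentration-weighted mixing (contributions here are
isotope-mass proportions, not load proportions), correlated source
signatures, measurement drift, and non-normal source distributions.
Passing tests on synthetic data therefore demonstrate internal
correctness of the estimators — not that a real basin satisfies the
model's assumptions.

A packaged summary fixture (`basin_reference_summary()`) carries
per-region concentration and isotope means ± SD for seven region groups
of a real hilly-basin survey, the only real-data scale information the
package ships; `generate_from_summary()` draws moment-matched samples
from it (normal isotopes, lognormal concentrations solved from mean and
SD) for smoke tests. The ± values are treated as standard deviations.

## 6. Numerical choices and degenerate inputs

* Simplex draws are renormalized at storage so every retained draw sums
  to 1 within 1e−12 (tested on every fit).
* K = 1 fits return P = 1 exactly in every draw; constant parameters
  get R̂ = NA and do not block the convergence gate.
* Zero total variance with data off the mean gives log-likelihood −∞
  (a valid log-density), not an error.
* GVF with SDAM = 0 and per-group GVF for singletons are defined as 1,
  with notices; a single cluster scores 0.
* Ward merge ties (possible only on degenerate geometry such as
  duplicated points) are broken by `stats::hclust`'s deterministic
  internal order, so runs are reproducible; random instances have no
  ties almost surely, which is how the oracle comparison is framed.
* Samples with missing tracer values are excluded from clustering and
  mixing with a notice, never imputed; missing optional fields are NA
  throughout and make the affected flags not-evaluable rather than
  FALSE.
* The acceptance script sizes its problems to run in well under a
  minute: the packaged 62-sample scenario with 3 × 20,000-iteration
  chains per group, a 25-sample two-source grid comparison at 1,000
  grid points, and 200 null replicates for the false-positive
  calibration.

## 7. Known limitations

* Proportions are isotope-balance proportions; concentration-weighted
  (load) apportionment and covariate extensions of the mixing model are
  out of scope.
* Two tracers bound what four sources can tell you: reported posterior
  SDs include genuine non-identifiability, and users should expect
  ridge-shaped posteriors whenever K − 1 exceeds the tracer count.
* The denitrification screen is correlational; it does not estimate an
  enrichment factor from field data or correct the mixing model for
  partial denitrification.
* Per-group GVF is an interpretive construction (see §2).
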