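---
title: "Methods: scoring, variance partitioning and simulation in magxe"
author: "magxe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, variance partitioning and simulation in magxe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magxe)
```

## The measurement model

The pipeline analyses endpoint growth yields: stationary-phase optical
density read on a microplate in milli-OD units at 600 nm (mOD), taken as a
proxy for carrying capacity. It deliberately does not model growth
kinetics — no lag, rate or area-under-curve quantities — because the assay
design it targets reads a single saturated time point.

Raw data is a long-format table with one row per well reading:
`genotype, carbon, temperature_c, replicate, mOD, is_blank`. One genotype
label is reserved for the ancestor; blank rows carry medium-only readings
with an empty genotype. Validation is total and runs before any
computation: unknown labels or temperatures, negative readings, an assay
environment (carbon × temperature) without a blank, or an environment
missing the ancestor all stop the pipeline with a message naming the
offending rows or environments. We treat blanks as per-(carbon,
temperature) rather than per-plate: plate layouts vary by reader and are
not represented here, and allowing one *or more* blank rows per
environment (averaged before subtraction) is a strict generalization of a
single blank well.

## From readings to scores

For each culture, replicate readings are blank-corrected and averaged on
the net mOD scale, and each MA genotype is scored against the ancestor of
the same environment:

$$s_{gc}(T) = \log_{10} \frac{\overline{\mathrm{mOD}}_{g} + 1}
{\overline{\mathrm{mOD}}_{\mathrm{anc}} + 1}$$

Two numerical choices deserve note.

* **Clamping.** Blank subtraction clamps negative nets at zero before the
  +1 offset. With realistic blanks (tens of mOD) against cultures (hundreds
  to thousands of mOD) this changes nothing; it only protects near-empty
  wells from producing negative yields. It is switchable
  (`clamp = FALSE`) for sensitivity re-runs.
* **Average-then-score.** Replicates are averaged on net mOD and the score
  formed once, treating the replicate mean as the measurement being
  scored. The alternative — score each replicate, then average —
  is exposed as `score_then_average = TRUE`; by Jensen's inequality it is
  never larger, and the two coincide exactly when replicates are equal.

The media bookkeeping (`carbon_molarity()`) converts each substrate's mass
concentration to millimolar carbon using conventional atomic weights
(C 12.011, H 1.008, O 15.999): at 0.4 g/L the three hexoses give 13.3 mM C,
glycerol 13.0, and the disaccharides 14.0 (three significant figures for
display; full precision elsewhere). This is why a common mass concentration
across the six substrates is, to a good approximation, a common carbon
supply.

## The variance partition and its conventions

At each temperature the complete G × E matrix of scores (genotypes ×
carbons, replicates already averaged) is partitioned by method of moments:

* genetic component: sample variance (denominator G − 1) of row means;
* environmental component: sample variance (denominator E − 1) of column
  means;
* interaction component: the interaction mean square
  $\sigma^2_{GE} = \mathrm{SS_{int}} / ((G-1)(E-1))$.

The interaction is decomposed into responsiveness and inconsistency,

$$R = \sum_{i \ne j} \frac{(\sigma_{Ei} - \sigma_{Ej})^2}{2G(G-1)},
\qquad
I = \sum_{i \ne j} \frac{\sigma_{Ei}\,\sigma_{Ej}\,(1 - \rho_{EiEj})}
{G(G-1)},$$

with sums over *ordered* pairs (G(G−1) terms, matching the denominators),
σ_Ei the sample standard deviation (E − 1) of genotype i's profile, and ρ
the Pearson correlation between profiles. These conventions are not
arbitrary: they are the unique sample-variance conventions under which
R + I equals the interaction mean square identically, which can be shown by
expanding SS_int in row-centred profiles. `partition_components()` asserts
the identity to 1e-9 (relative to the matrix's variance scale) on every
call, and an explicitly looped `pairwise_oracle()` recomputes R, I and
σ²_GE from the defining formulas in the test suite.

Decisions made where the conventions were genuinely open:

* **Correlation flavour.** ρ is Pearson ("environmental correlation");
  rank correlation would break the R + I identity.
* **Zero-variance profiles.** A genotype with a constant profile has an
  undefined ρ against every other genotype; those entries are stored as
  `NA` with a warning and contribute zero to I (their σ product is zero
  anyway), keeping I well defined.
* **Total variance.** Reported `total` is the *sum* of the three
  components, so the decomposition is additive by construction rather than
  the raw variance of all cells.
* **No replicate-error subtraction.** σ²_GE is estimated from cell means;
  no attempt is made to subtract within-cell replicate error, because the
  analysis operates on replicate means throughout. Measurement noise
  therefore biases the interaction term upward by roughly the squared
  score-scale noise per cell; the simulation study below quantifies how
  small that is under realistic noise.
* Mixed-effects modelling of the raw scores (e.g. incubator as a random
  factor) is deliberately out of scope: with one incubator per temperature
  the random factor is confounded with temperature, and any standard
  mixed-model tool can consume the exported score table.

## Classification and trends

A loss threshold is a retained fraction f of ancestral performance; a
genotype has lost performance on a substrate when s < log10 f, with a
*strict* inequality so a score exactly at the cutoff is not a loss (ties
have measure zero on real data but matter in tests). Counting lost
substrates maps to three categories: resource-independent deleterious (all
E), resource-dependent deleterious (some but not all) and non-deleterious
(none). Proportions always use all G genotypes as denominator.

Component-versus-temperature trends use ordinary least squares on a linear
plus quadratic temperature polynomial. Temperature is centred at its mean
before squaring to decorrelate the two columns; coefficients are
back-transformed to the raw Celsius scale, so fitted values and tests are
invariant to the centring (a tested property). The response is rescaled to
unit magnitude internally — F statistics are scale-invariant and variance
components can be numerically tiny. Term significance uses marginal
(type II) F tests; model simplification removes the quadratic term at
α = 0.05, then the linear term, but never removes the linear term while
the quadratic is retained (marginality). Proportion trends use a binomial
GLM with logit link fitted by IRLS (relative deviance change < 1e-10, at
most 100 iterations) and are summarised by the likelihood-ratio χ² (1 df)
against the intercept-only model; all-zero or all-G counts, or a diverging
slope, raise a separation flag and only the slope sign is reported. A
quadratic term can be added and tested by the same likelihood-ratio route.

## Rank curves

Two table layouts back the usual visualisations: per-genotype ranking
(each genotype's substrates sorted by its own scores, every curve
non-increasing) and fixed-reference ranking (all genotypes share the
substrate order of the genotype with the best mean score). In the fixed
layout, slope differences between curves display responsiveness and
crossings display inconsistency. All ties break by design order so outputs
are deterministic.

## What the synthetic generator emulates

`simulate_experiment()` produces data with the structure the analysis
assumes, plus exact ground truth. The default design is one ancestor + 10
MA genotypes × 6 carbons × 10 temperatures (23–41 °C in 2 °C steps) × 3
technical replicates (2,040 rows including one blank per environment).

The noiseless score surface is

$$s_{gc}(T) = -\delta_g\,\lambda(T) + \eta_g\,x_c\,\psi(T)
+ \varepsilon_{gc}\,\omega(T)$$

* $\delta_g \sim |N(0, \sigma_\delta)|$ are deleterious magnitudes, scaled
  by the deficit multiplier $\lambda(T) = d_0 + d_2 (T - T_{mid})^2$:
  mutational yield loss is smallest at intermediate temperatures.
* $\eta_g \sim N(0, \sigma_\eta)$ are sensitivities to a *fixed* centred,
  unit-variance carbon axis $x_c$, scaled by the ramp
  $\psi(T) = \psi_0 + \psi_1 (T - T_{\min})$ — this is the responsiveness
  knob: the spread of environmental variances grows with temperature.
* $\varepsilon_{gc} \sim N(0,1)$ are idiosyncratic genotype × carbon
  effects scaled by $\omega(T) = \omega_0 + \omega_1 (T - T_{\min})$ — the
  inconsistency knob, decorrelating profiles warmer-ward.

Effects are drawn once per simulated experiment and shared across
temperatures, as for real genotypes. Measurements are generated by
*inverting* the score formula: the ancestor's net yield follows a Gaussian
thermal performance curve $A_c(T) = A_{\max,c}
\exp(-(T - T_{opt,c})^2 / 2w_c^2)$, each MA mean is
$(A_c(T)+1)\,10^{s_{gc}(T)} - 1$, and a per-environment blank offset plus
additive truncated-Normal replicate noise (near-constant in OD at
stationary phase, hence additive rather than multiplicative) complete the
reading. Because the surface is defined on the score scale and inverted
exactly, ground-truth components are exact by construction, which makes
recovery tests sharp: with zero noise the pipeline reproduces the surface
to 1e-9.

**Default parameter values** were fixed once, before any benchmarking, to
encode the qualitative structure the generator is meant to emulate at
effect sizes a microbial MA assay would plausibly show:

* `t_mid = 31` °C and `t_opt` between 34 and 38 °C, inside a thermal niche
  whose components dip at intermediate assay temperatures while yields peak
  somewhat below the hot end of the range; `a_max` 700–1400 mOD and
  breadths 10–12 °C keep every environment's yield in the hundreds of mOD.
* `sigma_delta = 0.30` makes the genetic component dominate the partition
  (typical mean scores around −0.1 to −0.15), consistent with MA panels
  where among-line variation dwarfs substrate effects on the relative
  scale.
* `d0 = 0.5`, `d2 = 5e-4`: a shallow, symmetric deficit minimum at 31 °C.
* `psi = 0.02 + 0.006 (T - 23)` and `omega = 0.008 + 0.0015 (T - 23)`:
  both G×E channels roughly quadruple across the temperature range, strong
  enough that the seed-averaged responsiveness curve and the
  resource-dependent proportion rise monotonically, which is the pattern
  the generator exists to emulate.
* `sigma_rep = 5` mOD replicate noise and blanks of 40 ± 3 mOD: a few
  permil of signal, typical of plate readers at stationary phase.

A deliberate limitation: the deficit multiplier is symmetric around
`t_mid`, so the generator encodes the intermediate-temperature minimum of
mutational damage but not an additional overall linear gain of relative
performance with temperature; and it simulates no incubator effects (in
this design an incubator term is confounded with temperature) and no
mutational process (no genomes, no substitution counts — effects are drawn
distributions, not mutations). Passing tests therefore certify the
pipeline's arithmetic and its behaviour under the assumed structure, not
the biology of any real MA panel: real data can violate the generator's
additivity-on-the-score-scale assumption, its Gaussian thermal curves and
its homoscedastic replicate noise.

## Problem sizes used in validation

The test suite and acceptance script validate at the default design size
(600 score cells per simulated assay). Ground-truth recovery uses 50
simulated assays with `sigma_rep = 5`; a component counts as recovered when
the estimate is within 10% relative (with a 1e-4 absolute floor for
near-zero components) of its exact ground truth at *every* temperature.
The qualitative pattern suite and the acceptance script average 24 assays;
the decomposition identity is exercised on 1,000 random matrices with
G ∈ 2..12, E ∈ 2..8; the logistic-trend oracle uses deterministic expected
counts at 1,000 trials per temperature against an iterative
grid-refinement maximizer of the binomial likelihood. These sizes were
chosen so the whole suite validates the pipeline at full design scale while
remaining quick to run routinely.
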