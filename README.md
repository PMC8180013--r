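# magxe

Genotype-by-environment analysis of mutation-accumulation growth assays.

## The problem

Mutation-accumulation (MA) experiments let spontaneous mutations fix by
drift and then ask what those mutations do to fitness. A recurring question
is how *environment-dependent* the damage is: a mutation that hurts growth
on every available resource constrains a population everywhere, while a
*conditionally neutral* mutation — deleterious on some substrates, invisible
on others — fuels fitness trade-offs and local adaptation. When growth
yields of MA genotypes and their ancestor are measured across carbon
substrates and assay temperatures, the question becomes quantitative: how do
the genetic, environmental and genotype-by-environment (G×E) components of
performance variation change with temperature, and how often is mutational
damage resource-dependent rather than resource-independent?

`magxe` is a pipeline for exactly this design: a plate reader measures
stationary-phase yields (milli-OD at 600 nm) of one ancestor plus G MA
genotypes on E carbon substrates at a series of temperatures, with technical
replicates and per-environment blank wells.

## The statistics at its core

**Relative growth performance.** For each MA genotype in each assay
environment (carbon × temperature), after blank subtraction and
replicate averaging,

```
s = log10( (mOD_MA + 1) / (mOD_ancestor + 1) )
```

(the +1 keeps the ratio defined at zero readings; s < 0 is a yield loss).

**Per-temperature variance partition.** The G×E cell-mean matrix at each
temperature is partitioned by method of moments: σ²_G is the sample variance
of genotype means, σ²_E the sample variance of substrate means, and σ²_GE
the interaction mean square SS_int/((G−1)(E−1)). The interaction is further
decomposed into

```
R = Σ_{i≠j} (σ_Ei − σ_Ej)² / (2G(G−1))          (responsiveness)
I = Σ_{i≠j} σ_Ei σ_Ej (1 − ρ_EiEj) / (G(G−1))   (inconsistency)
```

where σ_Ei is genotype i's environmental standard deviation across
substrates and ρ_EiEj the Pearson correlation of two genotypes' substrate
profiles. Under the package's denominator conventions the identity
σ²_GE = R + I holds analytically and is asserted on every call (and checked
against an independent brute-force oracle in the tests).

**Classification.** At each temperature and loss threshold
(score < log10 0.99, 0.95 or 0.90), a genotype is *resource-independent
deleterious* if it is below the cutoff on all E substrates,
*resource-dependent deleterious* if below on at least one but not all, and
*non-deleterious* otherwise.

**Trends.** Variance components are regressed on temperature with linear +
quadratic terms (type II F tests, stepwise simplification at α = 0.05);
category proportions get a binomial-logit trend with a likelihood-ratio χ²
against the intercept-only model.

A synthetic plate-reader generator (`simulate_experiment()`) emulates the
whole design with exact ground-truth components, so every stage is testable
end to end without any external data.

## Worked example

```r
library(magxe)
sim <- simulate_experiment(simulation_config(), seed = 42)
analysis <- run_pipeline(sim$records, sim$config$design)
print(analysis)
```

```
MA genotype-by-environment analysis
  scores: 600 genotype x carbon x temperature cells
  variance components by temperature:
 temperature_c   total sigma2_G  sigma2_E sigma2_GE responsiveness inconsistency
            23 0.01304  0.01198 7.173e-06  0.001048      0.0002413      0.000807
            25 0.01453  0.01181 3.860e-05  0.002682      0.0007402      0.001942
            27 0.01655  0.01145 5.421e-05  0.005055      0.0013720      0.003683
            29 0.02011  0.01164 8.013e-05  0.008396      0.0023810      0.006015
            31 0.02423  0.01169 1.504e-04  0.012390      0.0034960      0.008893
            33 0.02934  0.01198 1.492e-04  0.017200      0.0049120      0.012290
            35 0.03520  0.01229 2.080e-04  0.022710      0.0065180      0.016190
            37 0.04167  0.01290 2.843e-04  0.028490      0.0081310      0.020350
            39 0.04884  0.01372 2.165e-04  0.034900      0.0099940      0.024910
            41 0.05825  0.01468 3.517e-04  0.043220      0.0125700      0.030650
  mean genetic share of total variance: 50.8%
  mean responsiveness share of G x E variance: 27.8%
  resource-dependent trend (loss < log10 0.90): slope +0.1040 /C, LR chi2(1) = 6.784, p = 0.0092
  resource-dependent trend (loss < log10 0.95): slope +0.0939 /C, LR chi2(1) = 6.436, p = 0.0112
  resource-dependent trend (loss < log10 0.99): slope +0.0858 /C, LR chi2(1) = 5.647, p = 0.0175
```

Reading this: genetic differences dominate total score variance at every
temperature; the G×E component grows steadily warmer-ward, and so does the
proportion of genotypes whose losses are resource-dependent — the positive
logistic slopes say conditional neutrality becomes more common at higher
temperatures in this simulated assay.

Real data enters through the same door:

```r
design <- default_design()
records <- read_measurements("raw.csv", design)   # long-format plate CSV
analysis <- run_pipeline(records, design)
```

A thin command-line front end over the same functions is installed at
`system.file("exec/ma-gxe", package = "magxe")` with subcommands
`simulate`, `score`, `partition`, `classify`, `trends` and `rankcurves`.

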