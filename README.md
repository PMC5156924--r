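# transmitr

Simulation-based inference of **frequency-dependent cultural
transmission** from archaeological count tables.

Given counts of variant types (e.g. pottery decoration motifs) per
chronological phase, together with per-phase house counts, transmitr asks
which mode of social learning could have produced the observed frequency
trajectories: unbiased copying (cultural drift), **conformity**
(disproportionate copying of common variants) or **anti-conformity**
(disproportionate copying of rare ones).

## The model

One production event creates `v` items. Each item is a novel type with
probability μ (infinite-alleles innovation) or a copy of type *j* with
probability

π_j = (1 − μ) · m_j^(1−b) / Σ_l m_l^(1−b),

where m_j is the relative frequency of type *j* in the **sampling pool**
(the items of the last *w* production events — the social information
available to learners) and *b* is the frequency-dependence strength:
`b = 0` unbiased, `b > 0` anti-conformist, `b < 0` conformist.

Phase assemblages are **time-averaged**: the phase population of size
`N_i = round(n_i · r)` accumulates all η_i events of the phase, and the
observed sample of size n_i is a `1/r` random draw from it. Three
generative regimes are provided — equilibrium (burn-in, constant
parameters), variable population (demographic production schedule
v(t) ∝ ρ·H_i, pool seeded from the observed first phase via a Dirichlet
reconstruction), and variable population–transmission mode (per-phase
b_i, μ_i, w_i, pool re-seeded from each predecessor phase).

Inference is **ABC rejection**: draw parameters from priors, simulate,
measure a version-specific euclidean error level ε between simulated and
observed tables, retain the proportion α of draws with smallest ε.
Posteriors are summarised by medians and 95% highest-posterior-density
intervals; **posterior predictive checks** flag observed (phase, type)
cells outside the central 95% band of model replicates.

## Worked example

Generate a synthetic eight-phase assemblage with a known anti-conformist
bias (b = 0.1), fit the variable population version with known
demography, and check the fit:

```r
library(transmitr)

scenario <- merzbach_scenario(scale = 0.2, b = 0.1, seed = 42)
d <- generate_dataset(scenario)
d$counts[1:4, 1:8]
#>        BT1 BT2 BT3 BT4 BT5 BT6 BT7 BT8
#> phase1  25  20  12   2   1   0   0   0
#> phase2  23  21  20   0   0  12   2  10
#> phase3  25  25  23   0   0  22  11  14
#> phase4   8  25  17   0   0  16  27   6

fit <- fit_transmission(d$counts, d$houses$H, "variable_population",
                        s = 20000, alpha = 0.005, seed = 1,
                        fixed = list(rho = 1.5, r = 5))
fit
#> ABC rejection fit (variable_population version)
#>   s = 20,000 simulations, alpha = 0.005 -> 100 retained draws
#>   posterior b: median 0.182, 95% HPDI [-0.007, 0.373]

summary(fit)
#> posterior summaries (variable_population version, 95% HPDI)
#>   parameter  median     lower   upper
#> 1        mu 0.01217  0.002201 0.03074
#> 2         b 0.18209 -0.006524 0.37270
#> 3   w_years 3.93806  2.197645 4.99070
#> 4       rho 1.50000  1.500000 1.50000
#> 5         r 5.00000  5.000000 5.00000
#> retained epsilon range: [29.68, 50.93]

posterior_predictive(fit, n_reps = 500, seed = 2)
#> posterior predictive check (variable_population version, 95% bands, 500 replications)
#>    0 of 40 (phase, type) cells outside their band
```

The posterior median of b (0.18) has the right sign and its 95% HPDI
brackets the true value 0.1; every observed first-phase-type count lies
inside its predictive band, i.e. the fitted process reproduces the data.
`plot(fit)` draws the posterior of b, `plot(posterior_predictive(fit))`
the per-phase band plots; `coef`, `simulate`, `predict` and `residuals`
methods are available. A misspecified fit — e.g. a constant-b model on
data whose b flips sign mid-sequence — shows up as observed counts
escaping the bands in later phases.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/transmit.R synth --scale 0.2 --seed 9 --out data/
Rscript inst/cli/transmit.R fit --data data/counts.csv --houses data/houses.csv \
    --version variable_population --s 20000 --alpha 0.005 --seed 1 --out fit/
Rscript inst/cli/transmit.R ppc --fit-dir fit/ --data data/counts.csv \
    --houses data/houses.csv --n-reps 500 --seed 2 --out ppc/
```

Reruns with the same seed produce byte-identical outputs, including under
parallel execution of the rejection loop (`--cores`).

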