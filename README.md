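# raydemog

Demographic analysis for data-sparse elasmobranchs, built around the case
of the Spinetail Devil Ray (*Mobula japanica*): a species known from a
single length-at-age sample landed by an artisanal fishery, yet facing
enough fishing pressure that its productivity — and therefore its
extinction risk — needs to be quantified. The package turns such a sample,
plus a handful of life-history bounds, into estimates of somatic growth,
total and fishing mortality, and the maximum intrinsic rate of population
increase, with uncertainty carried through every stage. The same machinery
applies to any chondrichthyan with an aged catch sample or a life-history
table.

## The methods

**Growth.** The three-parameter von Bertalanffy function in its
size-at-age-zero form,

&nbsp;&nbsp;&nbsp;&nbsp;*DW*<sub>t</sub> = *DW*<sub>∞</sub> −
(*DW*<sub>∞</sub> − *DW*<sub>0</sub>) e<sup>−kt</sup>,

is fitted in log space (multiplicative lognormal error, variance σ²) by
Bayesian posterior sampling. When the sample misses the largest animals —
the devil-ray landings stop at 77% of the species' maximum size — maximum
likelihood overestimates *k* and underestimates *DW*<sub>∞</sub>.
Informative priors repair this: the asymptote prior is centred on
κ · *DW*<sub>max</sub>, where the conversion factor κ carries a
Gamma(1000, 990) hyperprior (mean 1000/990 ≈ 1.01, hard bounds [0.7, 1.3])
and *DW*<sub>max</sub> = 3100 mm; *DW*<sub>0</sub> is centred on the
880 mm size at birth; *k* gets a Beta(1.05, 1.5) prior. Three presets —
`strong`, `weaker`, `uninformative` — let the prior influence be compared.

**Mortality.** Total mortality *Z* is minus the OLS slope of log numbers
at age over the fully recruited classes (all classes from the most
abundant one onward; zero classes dropped for the log). Uncertainty comes
from a delete-20% bootstrap: 20,000 replicates each discard a random fifth
of the individual records and refit the truncated regression. Fishing
mortality is *F* = *Z* − *M* across paired draws.

**Productivity.** Natural mortality is the reciprocal of average lifespan,
*M* = 2/(α<sub>mat</sub> + α<sub>max</sub>); survival to maturity is
*l*<sub>mat</sub> = e<sup>−M α<sub>mat</sub></sup>; and *r*<sub>max</sub>
solves the juvenile-mortality-corrected Euler–Lotka equation

&nbsp;&nbsp;&nbsp;&nbsp;*l*<sub>mat</sub> b =
e<sup>r<sub>max</sub> α<sub>mat</sub></sup> −
e<sup>−M</sup> e<sup>r<sub>max</sub>(α<sub>mat</sub> − 1)</sup>,

where *b* is the annual reproductive output of daughters. A Monte Carlo
loop propagates uniform uncertainty in (*b*, α<sub>mat</sub>,
α<sub>max</sub>) through 10,000 draws; `rmax_batch()` repeats this over a
species table. *r*<sub>max</sub> doubles as the fishing mortality expected
to drive the population extinct, so comparing it with *F* says directly
whether a fishery is sustainable.

## Worked example

Everything below is seeded and reproduces exactly.

```r
library(raydemog)

# a devil-ray-like length-at-age sample: 60 animals, ages 0-14,
# landings restricted to 1100-2400 mm DW
d <- sim_length_at_age(n = 60, seed = 1)
fit <- fit_vbgm(d, vb_priors("strong"), seed = 1)
summary(fit)
#> Posterior summary (strong priors)
#>  parameter      mean    ci_low   ci_high  rhat    ess
#>          k 9.222e-02 7.126e-02 1.195e-01 1.008  581.8
#>     dw_inf 3.073e+03 2.805e+03 3.355e+03 1.006  666.3
#>        dw0 1.056e+03 9.512e+02 1.161e+03 1.004 1000.5
#>      kappa 1.001e+00 9.390e-01 1.061e+00 1.003 1170.1
#>     sigma2 6.741e-03 4.673e-03 9.752e-03 1.000 2615.8
```

The strong priors hold the asymptote near κ · 3100 mm even though no
simulated animal exceeds 2400 mm; `k` is estimated slow (0.09 year⁻¹),
and every parameter converges (split-chain R-hat ≤ 1.01).

```r
# an aged catch sample from a population fished at F = 0.163 on top of
# M = 0.087, fully recruited from age 2
comp <- sim_age_composition(m = 0.087, f = 0.163, sel_age_full = 2,
                            n_sampled = 5000, seed = 1)
zb <- bootstrap_Z(rep(comp$age, comp$count), n_boot = 20000, seed = 1)
zb
#> Bootstrapped catch curve: median Z = 0.246 year^-1 [0.240, 0.254]
#>   20000 replicates (0 discarded), drop fraction 0.20
```

The bootstrap median recovers the generating total mortality
M + F = 0.25 year⁻¹.

```r
# devil-ray life history: b in [0.25, 0.5] daughters/year, maturity at
# 5-6 years, maximum age 15-20 years
mc <- rmax_mc(n_draws = 10000, seed = 1)
mc
#> Monte Carlo r_max: 10000 draws (0 rejected)
#>   m      median 0.087 year^-1 [q05 0.079, q95 0.097]
#>   r_max  median 0.077 year^-1 [q05 0.045, q95 0.105]

fishing_mortality(zb$z_draws, mc$draws$m, seed = 1)
#> Fishing mortality: median F = 0.159 year^-1 [q05 0.148, q95 0.169]
```

The punchline of the analysis: the estimated fishing mortality
(≈ 0.16 year⁻¹) exceeds the median *r*<sub>max</sub> (0.077 year⁻¹) — the
fishing rate the population can withstand at most — so fishing at this
level is expected to drive the population toward extinction.

`run_pipeline()` chains the stages from a single YAML or list
configuration, writing draws as CSV and summaries as JSON with the seed
and package version embedded; `inst/scripts/raydemog` exposes the same
stages as shell subcommands.

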