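---
title: "Methods: growth, mortality and productivity of data-sparse devil rays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth, mortality and productivity of data-sparse devil rays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raydemog)
```

This vignette records the models behind `raydemog`, the assumptions they
make, and the numerical and design choices taken where more than one
reasonable option existed. It is the companion to the README's worked
example: the README shows what the package prints; this document explains
why.

## The scientific setting

Devil rays are landed in artisanal and industrial fisheries worldwide,
but for most species the only quantitative biology available is a single
vertebral-ageing study. That puts them in the worst corner of stock
assessment: enough fishing to worry about, too little data for a
conventional assessment. The package implements the workflow appropriate
to that corner: squeeze a growth curve, a total mortality rate and a
productivity estimate out of one aged sample and published bounds on
reproduction and longevity, and be explicit about the uncertainty at
every step.

## Bayesian von Bertalanffy growth

### Model

For an individual of age $t$ (integer vertebral band count) with disc
width $DW_t$ (mm),

$$DW_t = DW_\infty - (DW_\infty - DW_0)\,e^{-kt}, \qquad
\ln DW_t^{obs} \sim N(\ln DW_t, \sigma^2).$$

The size-at-age-zero parameterisation (rather than the $t_0$ form) is
used because size at birth is the quantity with an informative published
range for live-bearing rays, so the prior lands directly on a parameter.
The error is multiplicative: measurement and individual variability in
size scale with size. Sexes are pooled and ages are taken as exact — no
ageing-error model (see Limitations).

### Priors

The whole point of the Bayesian treatment is the truncated sample
problem: when no sampled animal approaches the species' maximum size,
likelihood-only fits push $DW_\infty$ down and $k$ up. The informative
presets encode two out-of-sample facts — a maximum recorded size
($DW_{max} = 3100$ mm) and a size at birth near 880 mm:

| parameter | strong | weaker | uninformative |
|---|---|---|---|
| $k$ (year⁻¹) | Beta(1.05, 1.5) | Beta(1.05, 1.1) | U(0, 2) |
| $DW_\infty$ (mm) | N($3100\kappa$, 100) | N($3100\kappa$, 400) | U(0, 4000) |
| $DW_0$ (mm) | N(880, 200) | N(880, 300) | U(0, 2000) |
| $\kappa$ | Gamma(1000, 990) on [0.7, 1.3] | Gamma(200, 198) on [0.7, 1.3] | U(0.7, 1.3) |
| $\sigma^2$ | half-Cauchy(0, 30000) | same | same |

Conventions fixed here: Normal priors are (mean, sd); Gamma priors are
(shape, rate), so the strong $\kappa$ hyperprior has mean exactly
$1000/990 \approx 1.01$ — the average ratio of asymptotic to maximum size
across fishes; Beta priors are (shape1, shape2). The $\kappa$ bounds are
implemented as hard truncation of the gamma density. The half-Cauchy
scale of 30000 is far in the tail of any plausible log-scale variance, so
it acts as a very weakly informative positive prior; it is kept on
$\sigma^2$ as specified rather than re-derived, since with the sample
sizes involved the likelihood dominates it anyway. The joint support
constraint $DW_\infty > DW_0 > 0$ is part of the model, enforced in the
posterior density.

### Sampler

`fit_vbgm()` uses the package's own componentwise adaptive random-walk
Metropolis sampler, augmented with a joint multivariate proposal whose
covariance is learned during warmup (scaled by $2.38^2/d$). The joint
step matters: $k$, $DW_\infty$ and $\kappa$ are strongly correlated along
a growth-curve ridge, and componentwise sweeps alone mix an order of
magnitude more slowly there. $\sigma^2$ is updated on the log scale with
the Jacobian correction. Adaptation (both the componentwise scale tuning
toward 0.44 acceptance and the covariance estimation) is frozen at the
end of warmup, so retained draws come from a fixed Markov kernel.

Defaults are 4 chains of 1500 warmup + 2500 retained iterations — chosen
so that the default fit of a few hundred records reaches split-chain
R-hat below about 1.01 in a few seconds. Convergence is diagnosed per
parameter with split-chain R-hat (own code) and effective sample size
(`coda::effectiveSize`); a fit exceeding the threshold is *flagged* with
a warning and in the object, never silently accepted, because truncated
samples under uninformative priors genuinely produce weakly identified,
slow-mixing posteriors — that flag is information, not a failure mode.
Initial values are drawn from the priors (with the half-Cauchy tail
capped at $\sigma^2 = 1$, far above any log-scale variance a growth
sample produces) so chains start overdispersed.

## Catch-curve total mortality

Under constant recruitment, a closed population, and catch that is
non-selective above some recruitment age, numbers at age decline as
$e^{-Za}$ and the OLS slope of $\ln N_a$ on $a$ over the recruited
classes estimates $-Z$. The implementation fixes the choices the method
leaves open:

* **Peak rule.** Classes younger than the most abundant class are
  assumed less catchable and dropped; the peak class itself is kept.
  Ties go to the *earliest* tied age — the choice that retains the most
  classes and yields the most conservative (shallowest) slope.
* **Zero classes** are kept in the tabulated composition (they are real
  structure) but dropped from the regression, where $\ln 0$ is
  undefined. The composition grid runs from age 0 to the oldest observed
  age *before* exclusions, so excluding a terminal class does not
  silently shorten the grid.
* **Degeneracy.** A regression needs at least 3 usable classes;
  anything less is an error, not a guess.
* **Bootstrap.** `bootstrap_Z()` deletes $\lfloor 0.2n \rfloor$ records
  per replicate without replacement (deletion, not resampling — the
  uncertainty of interest is "what if we had sampled slightly fewer
  animals"), refits, and reports the median and equal-tailed 2.5%/97.5%
  quantiles of 20,000 replicates. Replicates failing the 3-class rule
  are discarded and counted. An optional `max_age_cutoff` drops the
  oldest ages first, the conservative variant when old-age scarcity
  might reflect migration rather than death.
* **F = Z − M** pairs the bootstrap Z draws with Monte Carlo M draws by
  independent resampling to a common length. Negative F draws are kept —
  they are the honest statement that Z might not exceed M. The F
  interval is reported at 5%/95% to match the M and $r_{max}$
  convention.

The closed-form OLS slope is used internally (the bootstrap calls it
20,000 times); the test suite verifies it against `stats::lm` on
randomly generated compositions, keeping implementation and oracle on
separate routes.

## Productivity: Euler–Lotka $r_{max}$

Natural mortality comes from the reciprocal-lifespan estimator
$M = 1/\omega$, $\omega = (\alpha_{mat} + \alpha_{max})/2$, and survival
to maturity is $l_{mat} = e^{-M\alpha_{mat}}$. The maximum intrinsic rate
of population increase solves

$$l_{mat}\, b = e^{r_{max}\alpha_{mat}} -
e^{-M} e^{r_{max}(\alpha_{mat}-1)},$$

the simplified Euler–Lotka form in which a cohort's reproduction is
discounted by juvenile survival and adults survive year to year with
probability $e^{-M}$. Including $l_{mat}$ matters for low-fecundity
species: without it, $r_{max}$ is systematically optimistic.
$\alpha_{mat}$ enters as a continuous exponent (no rounding to whole
years).

**Root finding.** The residual $g(r)$ is monotone near its root;
`solve_rmax()` brackets a sign change starting from $[-0.5, 1]$ and
expanding to at most $[-1, 5]$ (rates outside that range are biological
nonsense and indicate bad inputs, which the solver reports rather than
chases), then calls `uniroot` at tolerance $10^{-13}$ and *verifies*
$|g(r)| < 10^{-10}$ before returning. A bracketed root finder replaces
general-purpose minimisation of $g^2$: same solution, but with a
guaranteed sign-change certificate and no flat-gradient failure mode.
The test suite checks it against an independent plain-bisection oracle
across a parameter grid.

**Monte Carlo.** `rmax_mc()` draws $b \sim U(0.25, 0.5)$ (one pup per
year shared between annual and biennial cycles, 1:1 sex ratio),
$\alpha_{mat} \sim U(5, 6)$ and $\alpha_{max} \sim U(15, 20)$ — the
devil-ray defaults — independently, 10,000 times. Each draw's
$\alpha_{mat}$ is shared between the $M$ calculation and the maturity
exponent: drawing them separately would let a single hypothetical animal
mature at one age for survival purposes and another for reproduction.
Draws with $\alpha_{mat} \ge \alpha_{max}$ (impossible under the default
ranges, possible for user-supplied overlapping ones) are rejected and
redrawn, with the count reported. Intervals on $M$ and $r_{max}$ are the
5th and 95th percentiles; under the default ranges $\omega$ follows a
symmetric trapezoid on $[10, 13]$, giving closed-form checks
median $M = 2/23$ and quantiles $2/(26-\sqrt{0.5})$, $2/(20+\sqrt{0.5})$
that the acceptance suite verifies.

`rmax_batch()` maps the same computation over a species table
(`species, b_low, b_high, ...`; point values as `low == high`), deriving
one sub-seed per row so results are invariant to adding or removing other
rows; malformed rows are reported by name and skipped.

## What the simulators emulate — and what they do not

`sim_length_at_age()` reproduces the statistical structure the growth
model assumes: integer ages uniform on a range, lognormal multiplicative
error, and an optional landing window (defaults: n = 60, ages 0–14,
window 1100–2400 mm, $k = 0.12$, $DW_\infty = 2995$, $DW_0 = 880$,
$\sigma^2 = 0.01$ — a sample-size and size-window pattern imitating the
published devil-ray dataset; these are stated assumptions, since the
original per-age counts are not published). Ages are sampled uniformly
*on purpose*: growth-fitting fixtures should not entangle the growth
test with mortality structure. Composition fixtures use the opposite
convention: `sim_age_composition()` decays expected proportions as
$s(a)e^{-(M+F)a}$ with a logistic selectivity ogive that equals 1 from
the full-recruitment age upward (`steepness = Inf` is knife-edge), then
samples multinomially. `sim_fished_population()` is fully deterministic
cohort decay with fishing applied through the ogive; its purpose is the
closed-loop check that a catch curve fitted to a noise-free fished
equilibrium returns exactly $M + F$, demonstrating that a steep right
limb can arise from fishing alone.

Passing tests on these simulators show the estimators are correct *under
their own assumptions*. Real catch samples violate them in known ways
the generators deliberately do not model: ageing error and band-count
underestimation in old animals, size-selective gear within the recruited
range, recruitment variability, immigration/emigration, and
non-stationary fishing mortality. Results on real data inherit those
caveats; the package's contribution is to make the assumption set
explicit and the uncertainty honest, not to remove it.

## Reproducibility and problem sizes

Every stochastic function takes a single integer seed and is bitwise
reproducible from it; `run_pipeline()` derives fixed offsets of its one
seed for each stage and embeds seed, settings and package version in
every summary JSON. The test suite exercises the full stack at sizes
chosen to make each statistical claim decidable in seconds: growth
recovery at 300 records, bootstrap recovery at 5000 individuals and
2000 replicates, Monte Carlo checks at 10,000 draws, solver-oracle
agreement on 100-point grids.

## Limitations

* No ageing-error or sex-structured growth model; band counts are taken
  at face value and sexes pooled.
* The catch curve assumes equilibrium age structure, constant
  recruitment and a closed population; the `max_age_cutoff` variant
  mitigates, but cannot test, migration of old animals.
* The half-Cauchy prior scale acts on the log-space variance only
  through its tail; users fitting data on other scales should revisit
  it.
* $r_{max}$ is density-independent by construction: it is the growth
  rate at vanishing density and says nothing about compensation.
* The Euler–Lotka form assumes knife-edge maturity and constant $M$
  across ages after birth.
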