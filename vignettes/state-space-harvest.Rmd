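---
title: "A Bayesian state-space logistic model for a harvested invasive iguana population"
author: "iguanaharvest authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian state-space logistic model for a harvested invasive iguana population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Green iguanas (*Iguana iguana*) invaded Grand Cayman in the early 1990s and,
by August 2018, islandwide post-reproduction surveys put their abundance above
1.3 million. A bounty-paid cull removed over 1.3 million animals between
October 2018 and August 2021, after which abundance estimates collapsed to
tens of thousands — and then began rebounding as harvest effort waned.
Managers need three things from the survey record: estimates of the
population's carrying capacity $K$ and maximum intrinsic growth rate
$r_{max}$; the maximum sustained harvest rate $h_{msy} = r_{max}/2$ that any
control programme must exceed; and projections of abundance through 2030
under candidate harvest-rate policies.

`iguanaharvest` implements that analysis end to end: a discrete-time
harvested logistic population model, a Bayesian state-space fit by MCMC, a
forward Monte Carlo scenario projector, and a synthetic-data generator with
a parameter-recovery harness that validates the whole pipeline against known
truth.

## The state-space model

Let $N_t$ be the true (latent) abundance at the August survey of year $t$,
and $y_t$ the survey-based estimate with standard error $s_t$ (both produced
upstream by distance-sampling; this package consumes them as data). The model
separates two noise sources.

**Process layer.** Post-reproduction growth follows the discrete logistic
map $G(N) = N + r_{max} N (1 - N/K)$. A known harvest rate $h_t$ (or a total
count $H_t$) is removed each inter-survey interval, and multiplicative
lognormal environmental noise perturbs the result:

$$N_{t+1} = \max\!\big(0,\; G(N_t)\,(1 - h_t)\big)\; e^{\varepsilon_t},
\qquad \varepsilon_t \sim \mathrm{Normal}\!\left(-\tfrac{\sigma_{proc}^2}{2},\; \sigma_{proc}^2\right).$$

**Observation layer.** Estimates are lognormal around the latent state with
a per-survey log-scale SD fixed from the published CV
($\mathrm{CV}_t = s_t/y_t$), matching the lognormal confidence-interval
convention used to report them:

$$\log y_t \sim \mathrm{Normal}\!\big(\log N_t,\; \sigma_{obs,t}^2\big),
\qquad \sigma_{obs,t} = \sqrt{\log(1 + \mathrm{CV}_t^2)}.$$

Priors are uniform — $K \sim U(900{,}000,\ 2{,}000{,}000)$ individuals,
$r_{max} \sim U(0.5,\ 2.0)$ per year, $\sigma_{proc} \sim U(0.01,\ 1.0)$ —
and the initial latent state has a lognormal prior centred on the first
survey estimate with its own CV. With eight noisy surveys the data update
$K$ and $r_{max}$ only weakly; the posterior remains close to these priors,
which therefore deserve as much scrutiny as any likelihood choice.

### Two open structural choices, and how we resolved them

The survey paper specifies the harvest identity $H_t = N_t h_t$ and the
logistic roles of $K$ and $r_{max}$, but not the exact discretization — the
full equation lives in a companion monthly model that is out of scope here.
Two orderings are defensible and both are implemented:

- `timing = "sequential"` (default): growth first, then proportional
  removal, $N' = G(N)(1-h)$. The per-year multiplier at low abundance is
  $(1 + r_{max})(1 - h)$, which falls below 1 for heavy harvest — e.g. at
  $r_{max} = 1.3$, $h = 0.8$ the population shrinks by ~54% per year. This
  matches both the biology (August surveys count the year's hatchlings;
  the cull then removes a fraction of that whole grown population over the
  following year) and the published scenario tables, in which rates above
  0.7 crush the population within a few years.
- `timing = "simultaneous"`: the classical Schaefer surplus-production form
  $N' = G(N) - hN$. Its per-year multiplier at low abundance is
  $1 + r_{max} - h$, which *exceeds 1 for every* $r_{max} > h$ — under it
  no harvest rate below 0.9 can ever collapse a population with
  $r_{max} > 0.9$, so the heavy-harvest declines the analysis must
  reproduce are structurally unreachable. We keep this form available
  because its equilibrium algebra is the textbook one: sustained-yield
  abundance $N^* = K(1 - h/r_{max})$ and MSY rate $r_{max}/2$ are exact,
  and the package's property tests verify both identities under it.

Process-noise placement is the second open choice. `noise_centering = "mean"`
(default) draws $\varepsilon_t$ with mean $-\sigma_{proc}^2/2$, so
$E[N_{t+1} \mid N_t]$ equals the deterministic prediction. The alternative
`"median"` (zero-mean deviates, the common Meyer–Millar convention) leaves
the deterministic prediction at the *median* and inflates the conditional
mean by $e^{\sigma_{proc}^2/2}$ — a ~32%/year phantom boost at the
$\sigma_{proc} \approx 0.75$ this dataset demands, which would leak into
every projection mean. With the small process SDs typical of well-resolved
fisheries data the two are nearly indistinguishable; here the distinction
matters, and the mean-unbiased form keeps "no expected growth distortion
from noise" true by construction.

The annualised harvest rates for the fit are 0 for the four pre-cull
intervals and 0.629, 0.374, 0.082 for 2018–19, 2019–20, 2020–21. Two rates
were reported within the 2018–19 interval (0.629 to July 2019, 0.568 in
August 2019); the packaged schedule uses 0.629, and the alternatives (0.568,
or the compounded $1-(1-0.629)(1-0.568)=0.840$) are one-line edits to the
harvest CSV documented in the default config.

### What the fit can and cannot learn here

The 2019→2020 interval records a fall from 103,020 to 25,259 under a
nominal rate of only 0.374 — no annual-step logistic explains a 75% decline
with a 37% removal, so the posterior absorbs the conflict into
$\sigma_{proc}$ (posterior mass near 0.7–0.8, against a prior upper bound
of 1.0). That inflated process noise is the fingerprint of annualising a
harvest that in reality compounded month by month; it widens all projection
intervals and, over a 9-year horizon, lets occasional noise spikes push
trajectories above the level where the deterministic map turns negative,
after which the zero floor makes them extinct. Long-horizon light-harvest
ensemble *means* are therefore biased low relative to an analysis with
monthly harvest logs. Short-horizon summaries (one–two years) and the
heavy-harvest medians are robust to this; users who want smaller process
noise should fit totals from monthly logs rather than annual rates.

## The sampler

`run_mcmc()` is an adaptive random-walk Metropolis-within-Gibbs sampler over
$(K, r_{max}, \sigma_{proc}, \log N_0, \ldots, \log N_T)$ — 11 coordinates
for the 8-survey series. Each coordinate gets a scalar Gaussian proposal;
step sizes adapt toward a 44% acceptance rate in batches of 100 during
burn-in and are frozen afterwards, so the retained chain is Markovian.
Proposals outside the uniform prior supports are rejected, keeping the
priors exact rather than reflected. Chains start overdispersed (parameters
drawn from their priors, latent states jittered around the observed
series). Defaults are 4 chains × 50,000 iterations, half burn-in, thinned
to 10,000 retained draws — about a minute of computation — with split-chain
$\hat R$ and an initial-monotone-sequence effective sample size reported
per quantity, and a convergence gate of $\hat R < 1.05$ on the model
parameters. The joint density is exported as `log_posterior()` so it can be
audited point-wise; the test suite pins it to an independently coded
brute-force density sum at fixed points ($10^{-8}$ relative), and a JAGS
implementation of the same model (via `rjags`, when installed) is used as
an independent-software cross-check of the posterior means.

Derived quantities are transformed per draw — `h_msy` is `r_max/2` applied
to every retained draw, never to summaries — so posterior intervals of
derived quantities are exact functionals of the joint posterior.

## Projection

`project()` pushes every retained draw forward from its own latent
August-2021 state — not from the raw survey mean — so observation
uncertainty, parameter uncertainty and process noise propagate jointly.
Scenario bands draw an annual harvest rate
$h \sim U(\mathrm{lower}, \mathrm{upper})$ independently per projected year
and per draw (`h_mode = "per_year"`, the default; `"per_trajectory"` holds
one rate per trajectory, and which of the two the original analysis used is
not stated — the per-year default reproduces the published heavy-tailed
scenario spreads). Process noise stays on by default; the published
no-harvest 2030 spread, with an SD exceeding its mean, is only attainable
with it. `time_to_threshold()` reports per-trajectory first-passage years
(censored when a trajectory never crosses), including "reach 95% of this
draw's own $K$" via `threshold = "K"`.

Ensemble sizes default to every retained draw once; `n_ensemble` resamples
draws (seeded) when more members are wanted. 20,000–40,000 members hold the
Monte-Carlo error of year-2030 medians of the extreme bands below a few
percent.

## The synthetic-data generator and what passing tests mean

`generate_study()` builds a complete study from known truth: a latent
trajectory simulated from the same process model (noise attached to the
latent, not the deterministic, path — the hierarchy the fit assumes),
harvest by the same schedule machinery, and observed estimates drawn
lognormally around the latent states with per-year CVs fixed by design. The
default CV design copies the eight empirical survey CVs (0.19–0.42), so
recovery experiments reflect the survey precision actually achieved in the
field; the default study conditions mirror the real series (truth
$K = 1.3$M, $r_{max} = 1.3$, $\sigma_{proc} = 0.05$, $N_0 = 254{,}162$,
harvest pattern 0/0/0/0/0.629/0.374/0.082).

`recovery_experiment()` repeats generate → fit → score: posterior-mean
error, 95%-interval coverage of truth, and the convergence gate per
replicate (gate failures are flagged, never dropped). At the default
conditions, 20 replicates with 2 × 20,000-iteration chains give ≥ 90%
coverage for $K$ and $r_{max}$ and under 1% mean relative bias on
$r_{max}$ — the test suite asserts exactly this, in about three minutes.

What this does *not* show: the generator shares the fit's structural
assumptions, so recovery cannot detect misspecification of those
assumptions against real data (annualised harvest, lognormal observation
error with known CV, a single well-mixed population). It validates the
inference machinery, not the survey design; a shuffled-label negative
control in the tests confirms the harness flags structurally impossible
series rather than absorbing them silently.

## Numerical choices and degenerate inputs

- Abundances are kept as reals; whole-animal rounding appears only at
  reporting boundaries (`harvest_needed()` uses a ceiling so a recommended
  rate is strictly achieved).
- The zero floor makes extinction absorbing; over-harvest in total-count
  form is not an error, it is extinction.
- $\sigma_{proc} = 0$ with any non-zero process deviation yields a
  log-density of $-\infty$ (documented), not an exception; the prior lower
  bound 0.01 keeps the sampler away from that ridge.
- Harvest totals are capped at the grown abundance, so a total can
  extinguish but never drive abundance negative.
- Proposed latent states implying a non-positive deterministic prediction
  are rejected through the $-\infty$ density, which is what confines the
  posterior to dynamically feasible trajectories.
- All randomness flows through a single seed per entry point
  (`withr::with_seed`), so every artefact is bit-reproducible on one
  platform.

## Problem sizes used in the shipped checks

The packaged analysis runs 4 × 50,000 MCMC iterations (10,000 retained
draws) for the survey fit, 40,000-member ensembles for projections, and 20
replicates of 2 × 20,000 iterations for the recovery experiment — sizes at
which the Monte-Carlo error of every asserted summary is well inside the
tolerance asserted on it, while the whole test suite stays in the
ten-minute range on a single CPU.

## Known limitations

- Age and sex structure are pooled, as in the surveys; no Allee effect or
  theta-logistic curvature, so extrapolation far below observed densities
  is prior-driven.
- Harvest is annualised. The monthly dynamics of the real cull are visible
  in the data only as inflated process noise (see above), which widens
  long-horizon projection intervals and depresses light-harvest long-run
  means.
- Observation SDs are fixed from published SEs, not estimated; detection
  probability is assumed handled upstream by the distance-sampling stage.
- With eight surveys the parameter posteriors remain prior-dominated;
  conclusions about $h_{msy}$ inherit the prior's support $[0.25, 1.0]$.
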