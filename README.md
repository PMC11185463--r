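# rookery

Estimating sea-turtle nesting abundance on remote, scattered islet
rookeries from sparse repeated beach surveys.

## The problem

Many nesting aggregations sit on dozens of small, hard-to-reach coral
islets. No islet can be patrolled nightly, so the data are counts of
*newly detected* nests per survey visit, separated by weeks, on a subset of
islets — some monitored repeatedly through the season (an "A-set"), others
only twice near the nesting peak (a "B-set"), and some not at all in a
given season. Nest tracks (body pits) also fade: after a long enough gap a
count is only a lower bound on the true activity. `rookery` turns such
data into seasonal and multi-season nest totals with 95% credible
intervals, for monitoring programs and conservation assessment.

## The model

Nightly nesting activity follows a piecewise-cosine seasonal curve with
shape parameters `P` (peak ordinal date, October 1 = day 1),
`LengthB = P - B`, `LengthE = E - P` (days from the beginning `B` to the
peak and from the peak to the end `E`), an optional flat top of half-width
`F`, and scale parameters `Max` (mean nests per night at the peak,
specific to each islet) and `PMin` (relative off-season floor):

```
n(t) = PMin * Max                                        t < B or t > E
n(t) = [(1 + cos(pi (P-F-t)/(P-F-B))) / 2] (Max - PMin*Max) + PMin*Max    B <= t < P-F
n(t) = Max                                               P-F <= t <= P+F
n(t) = [(1 + cos(pi (t-P-F)/(E-P-F))) / 2] (Max - PMin*Max) + PMin*Max    P+F < t <= E
```

A survey count over a multi-night window is Poisson (or negative binomial,
`NB(x; m, k)` with aggregation parameter `k`) on the window sum; windows
longer than the track-detection half-life give censored ("minimum")
counts whose likelihood integrates the window-total pmf from the observed
count `N` up to `N_max`. `N_max` comes from a logistic track-persistence
curve `d_a = 1 / (1 + exp(-(A - a)/(4S)))` fitted to repeated observations
of marked nests with AR1 within-track dependence. Year effects on `P`
and/or (`LengthB`, `LengthE`) define four candidate model families,
compared by AICc and Akaike weights. Never-surveyed islet-seasons are
imputed from sum-to-one site proportions (`E_ij = T_i * p_j`, gamma
observation model). Posteriors come from adaptive Metropolis–Hastings
(target acceptance 0.234).

## Worked example

```r
library(rookery)

# a synthetic rookery with known truth: 12 A-set + 16 B-set islets,
# 6 seasons, peaks drifting from late to mid-December, track fading with
# a ~22-day detection half-life
set.seed(1)
sim <- simulate_rookery(simulation_config(seed = 1))

res <- run_pipeline(
  sim$surveys,
  tracks = sim$tracks[, c("track_id", "season", "age_days", "detected")],
  seed = 1, n_boot = 99,
  mcmc = mcmc_config(n_iter = 4000, burn_in_fraction = 0.25, seed = 1),
  n_resample = 20000)
render_report(res)
```

which prints (numbers from this exact call):

```
Nesting seasonality and rookery totals
======================================
Season 2017-18: 03 Nov -> 24 Mar (peak 28 Dec, length 141 days); nests 412 (95% CI 355-478)
Season 2018-19: 06 Nov -> 27 Mar (peak 01 Jan, length 141 days); nests 406 (95% CI 349-481)
Season 2019-20: 05 Nov -> 25 Mar (peak 30 Dec, length 141 days); nests 438 (95% CI 374-512)
Season 2020-21: 31 Oct -> 20 Mar (peak 25 Dec, length 141 days); nests 374 (95% CI 323-433)
Season 2021-22: 28 Oct -> 18 Mar (peak 22 Dec, length 141 days); nests 371 (95% CI 318-436)
Season 2022-23: 19 Oct -> 09 Mar (peak 13 Dec, length 141 days); nests 436 (95% CI 378-502)
Across seasons: mean 407 nests (95% CI 380-439)
Imputed islet-seasons: 0
```

Each line gives the fitted season calendar (beginning, peak, end from the
selected AICc family) and the posterior median seasonal nest total with
its 95% credible interval; the last lines give the multi-season mean and
how many islet-seasons had to be imputed from site proportions. The
detectability stage estimated a half-life `A = 21.8` days (truth 22.23)
and fed the detection-aware likelihood. The true generating peaks are
Dec 30 / Jan 1 / Dec 28 / Dec 27 / Dec 24 / Dec 14 and the realised true
totals are 430 / 428 / 409 / 414 / 411 / 408 nests — peaks recover to
within a few days and every 95% interval covers its true total.

A command-line wrapper exposes the same stages:

```sh
Rscript -e 'rookery::rookery_cli()' simulate --out fixtures --seed 2
Rscript -e 'rookery::rookery_cli()' run-all --surveys fixtures/surveys.csv \
    --tracks fixtures/tracks.csv --out reports --seed 2
```

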