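# fsmanip

Analysis of resource-manipulation experiments on home-ranging herbivores
tracked by GPS — and a fully synthetic re-implementation of such an
experiment for testing every stage of the analysis.

## The problem

Supplemental feeding sites are discrete, high-reward resource patches whose
availability can be manipulated in the field. In the design this package
analyses, each tracked animal-year passes through three consecutive phases —
**pre-closure**, **closure**, **post-closure** (homogenised to 14 days
each) — with food access withdrawn during closure at the animal's most
attended, *manipulated* site (M). Other provisioned sites (*alternate*, A)
stay open; everything else is the vegetation matrix (V). The questions are
behavioural: does losing a familiar resource enlarge and shift home ranges,
lengthen movements, and divert resource use — and does the animal return
once access is restored (site fidelity)?

The package is aimed at movement ecologists who want this analysis as a
tested, reusable pipeline rather than a one-off script.

## What it computes

* **Preference.** `h_FS`, an animal-year's preference for feeding sites: the
  proportion of pre-closure fixes within a buffer (radius `l`, the population
  mean hourly displacement) of any site, with a buffer-scale sensitivity
  analysis over `{0.5, 1, 1.5, 2, 3, 4} x l`.
* **Resource states.** Each fix classified M / A / V (closed buffers,
  precedence M > A > V), with the three presence/absence series
  `u_M, u_A, u_V` and their 1/2/24 h lags.
* **Space use.** Gaussian-kernel utilization distributions (UD) per
  animal-year x phase on a 10 m grid with bandwidth `l/2`; 95% ("home
  range") and 50% ("core area") isopleth areas in hectares; volume of
  intersection `VI = sum(min(p1, p2))` between phase pairs.
* **Movement.** Hourly step lengths `s_t` and turning angles `theta_t`;
  models on `log s_t` and the logit of `|theta_t| / pi`.
* **Inference.** `lme4` mixed models (ML) with an animal-year random
  intercept: linear models for log areas, logit VI and movement metrics;
  binomial-logit models for the three state series (with and without
  response lags; pre-closure excluded from the V model to avoid
  circularity). Progressive fixed-effect construction
  (`Phase`, `+h_FS`, `+Phase:h_FS`, `+Sex`, `+Phase:Sex`), drop-one
  likelihood-ratio p-values, backward elimination respecting marginality,
  and marginal / conditional R² by variance partitioning
  (residual `pi^2/3` for logit models).
* **Simulation.** `simulate_experiment()` generates a complete synthetic
  study — landscape, schedules, three-mode biased correlated random-walk
  trajectories (attend / forage / relocate), ground truth — deterministic
  under a fixed seed.

## Worked example

```r
library(fsmanip)

bundle <- simulate_experiment(sim_config(n_animal_years = 25, rng_seed = 101))
an <- analyze_experiment(bundle$fixes, bundle$sites, bundle$schedule, nagq = 0)
print(an)
```

```
Feeding-site manipulation analysis
  25 animal-years | 25200 retained fixes | phases truncated to 14 days
  mean hourly displacement l = 58.8 m | buffer 58.8 m | bandwidth 29.4 m
  preference h_FS: mean 0.377, IQR 0.339
  home range (95%), ha: pre 34.62 | closure 60.85 | post 36.22
  core area (50%), ha:  pre 5.43 | closure 13.87 | post 5.42
  overlap VI: pre/closure 0.301 | closure/post 0.300 | pre/post 0.682
  step length, m: pre 54.6 | closure 66.6 | post 55.3
  use of M: pre 0.33 | closure 0.01 | post 0.34
  use of A: pre 0.04 | closure 0.22 | post 0.04
  use of V: pre 0.62 | closure 0.76 | post 0.62
  fitted models: area95, area50, overlap, step, turn, u_M, u_A, u_V
```

Reading this: the closure roughly doubles home-range size and lengthens
steps; use of the manipulated site collapses (0.33 to 0.01) and is partly
compensated by alternate sites (0.04 to 0.22); space use barely overlaps the
pre-closure range during closure (VI 0.30) but returns once access is
restored (pre/post VI 0.68) — site fidelity. Individual fits live in
`an$fits` (full) and `an$final` (after term dropping), e.g.
`an$final$area95` for the home-range model with its coefficient table,
likelihood-ratio p-values and R².

The same pipeline runs on field data via `read_fixes()`, `read_sites()` and
`read_schedule()` (CSV schemas in their help pages).

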