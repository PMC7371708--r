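---
title: "Analysing feeding-site manipulation experiments: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing feeding-site manipulation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsmanip)
```

## The problem

Supplemental feeding sites give a rare experimental handle on home-ranging
behaviour: a discrete, high-reward resource whose availability can be switched
off and on while animals are tracked by GPS. The design this package analyses
has three consecutive phases per animal-year — *pre-closure*, *closure* and
*post-closure* — with food access withdrawn during the middle phase at one
*manipulated* site (M), the site the animal attended most beforehand. Other
provisioned sites (*alternate*, A) stay open throughout, and everything else
is the vegetation matrix (V).

The pipeline turns hourly fixes, site coordinates and the phase schedule into:

1. phase-truncated trajectories with step lengths and turning angles;
2. resource-state series (M/A/V) and the per-animal preference score
   $h_{FS}$ — the proportion of pre-closure fixes within a buffer of any
   feeding site;
3. kernel utilization distributions (UD) per animal-year and phase, their 95%
   ("home range") and 50% ("core area") isopleth areas, and the volume of
   intersection (VI) between phases;
4. mixed-effect models quantifying how the closure, the preference score, sex
   and their interactions drive the responses.

A biased correlated random-walk simulator generates complete synthetic
experiments with known ground truth, so every stage is testable without any
field data.

## Scales derived from the data

The population mean hourly displacement, $l$, is computed from the data at
hand (mean step length over all retained, gap-free hourly steps), not
hard-coded. It sets

* the feeding-site buffer radius (working scale $1 \times l$),
* the KDE bandwidth ($l/2$),
* a natural default for the resettlement radius.

A buffer-scale sensitivity analysis recomputes $h_{FS}$ at
$\{0.5, 1, 1.5, 2, 3, 4\} \times l$ and reports the interquartile range per
scale; the IQR-maximising scale discriminates best between site users and
non-users. The working definition stays at $1 \times l$ by default even if
another scale marginally maximises the IQR, to keep results comparable across
datasets; `buffer_sensitivity()` flags the maximiser for inspection.

## Trajectory conventions

* **Truncation.** Phases are homogenised to 14 days: the pre-closure and
  closure windows keep their final 14 days (anchored at the closure start and
  the post start respectively), the post-closure window keeps its first
  14 days. Boundaries are half-open `[start, end)` in UTC. A raw phase
  shorter than the target is an explicit error. The operation is idempotent.
* **Steps and turns.** $s_t$ is the Euclidean distance between successive
  fixes; $\theta_t$ the signed difference between successive headings wrapped
  to $(-\pi, \pi]$, counterclockwise positive. Steps across missing fixes are
  flagged and never contribute turns or lag values; missing fixes are never
  interpolated. A zero-length step has no heading: its $\theta$ is missing
  and the previous non-zero heading is carried forward.
* **Transforms.** Modelling uses $\log s_t$ (floored at 1 m) and the
  logit-transformed absolute turning angle. The logit needs an argument in
  $(0,1)$; since $|\theta_t| \in [0, \pi]$, we divide by $\pi$ first — the
  only scaling that maps the full support onto the unit interval — and clamp
  by $\varepsilon = 10^{-6}$ at the boundaries. The same clamp is used for
  logit-transformed VI overlaps.
* **Lag chains.** The movement and resource models include the response at
  lags 1, 2 and 24 h to absorb serial autocorrelation. A lag value is taken
  only from a *complete* modelled step (present, gap-free, defined turn), so
  chains never silently reach across holes; a complete hourly series of 1008
  fixes therefore yields $1008 - 1 - 1 - 24 = 982$ modelled steps. Rows with
  incomplete lag sets are excluded, not imputed, and counted.

## Resource states and exclusions

Sites become areas by buffering their coordinate (closed disc: a distance
exactly equal to the buffer is inside). Buffers can overlap at large scales;
precedence is M over A over V, which is conservative for the headline
contrast (use of M). M is identified per animal-year as the managed site with
the most pre-closure fixes within radius $l$, ties broken by smaller mean
distance and then lexicographically, so the assignment is deterministic.
Animal-years with no pre-closure fixes near any managed site are "non-users"
and cannot be assigned an M; animal-years that never visited an alternate
site before the manipulation carry no information on the M-vs-A compensation
and are excluded from the resource-use models (the exclusion is logged, and
the models can be rerun with them retained).

## Space use

The UD is the average of isotropic Gaussian kernels (sd = bandwidth) centred
on the fixes, evaluated at the centres of a 10 m grid and renormalized to sum
to one. The extent is the bounding box of the fixes padded by four bandwidths
and snapped to the resolution lattice: the padding captures > 99.99% of each
kernel's mass, so isopleth areas are insensitive to the extent rule (halving
the resolution changes the 95% area by well under 2% on smooth surfaces —
verified by test). Renormalization after truncation to the finite grid
guarantees the partition-of-unity invariant.

Isopleth areas are cell-count based (no polygonization): cells are ranked by
density and the smallest prefix reaching the cumulative level is counted.
This keeps areas exactly testable — a single kernel reproduces the analytic
bivariate-normal quantile disc ($\pi \sigma^2 \cdot (-2\ln 0.05)$ for the
95% level) within discretisation error — and makes the area deterministic
even when cells at the cutoff are tied (ties affect which cells are drawn,
never how many).

VI is $\sum_{cells} \min(p_1, p_2)$ after re-evaluating both kernel
estimates on the union extent; kernels are re-evaluated rather than
interpolated so the statistic is exact on the common grid. Two unit kernels
offset by $d$ overlap by $2\Phi(-d/2\sigma)$, an oracle the implementation
matches within 0.005.

## Inference

All mixed models are fitted by maximum likelihood with `lme4`, with an
animal-year random intercept (`ind`): an individual may respond
independently in different winters, and refitting with an animal-level
intercept is available as a sensitivity check. The fixed-effect structure is
built progressively (phase; + $h_{FS}$; + phase:$h_{FS}$; + sex; +
phase:sex), checking that log-likelihood increases and coefficient signs stay
stable across the nested sequence before trusting the full structure.

Term-level p-values are drop-one likelihood-ratio tests. The original
analysis ecosystem delegates p-values to a testing add-on without specifying
the method; LRTs on ML fits are reproducible across ecosystems and are used
throughout, which may produce small numeric differences from other
conventions (Kenward–Roger, Satterthwaite). Backward elimination removes the
least significant droppable term above $\alpha = 0.05$ and refits; a main
effect participating in a retained interaction is never dropped
(marginality — the one-line dropping rule in the source protocol does not
address it, so it is enforced here).

Resource use is modelled by three binomial-logit mixed models on the
single-state indicator series, fitted both with and without the lagged
responses; conclusions should not depend on that choice, and both fits are
reported. For the vegetation model the pre-closure phase is excluded
(closure becomes the reference): $h_{FS}$ equals one minus the mean
pre-closure $u_V$ by construction, so including that level would be
circular. Degenerate (all-0/all-1) responses are refused; suspected
separation (absurdly large coefficients) is flagged in the fit's messages.

Variance explained is reported as variance-partition coefficients:
marginal $R^2 = \sigma^2_f / (\sigma^2_f + \sigma^2_\alpha + \sigma^2_e)$
and conditional $R^2$ adds $\sigma^2_\alpha$ to the numerator, with
$\sigma^2_e = \pi^2/3$ for binomial-logit models. A singular random-effect
variance is retained at zero with a warning recorded, in which case the two
statistics coincide.

## The simulator

No behavioural-state model is claimed by the experimental protocol the
package emulates; the three-mode mover is this package's own assumption,
chosen as the simplest Markovian mechanism that produces all observed
response directions.

Each hour the animal is in one of three modes:

* **ATTEND** — small steps (gamma, mean 10 m) hovering at the target site;
  ends with probability 0.3 per hour, immediately if the site closes.
* **FORAGE** — correlated random walk (gamma mean 55 m, turn concentration
  $\rho = 0.3$) with a linear bias toward the home-range centre that ramps
  up with distance (saturating at 600 m).
* **RELOCATE** — directed travel (gamma mean 150 m); the heading is the
  circular weighted mean of the previous heading (0.3) and the bearing to
  the target (0.7); arrival within 25 m switches to attendance.

A foraging animal initiates a visit with probability $0.5\,p_i$ per hour,
where $p_i \in [0,1]$ is its true preference (Beta-distributed across the
population, mean 0.34). The target is drawn with weight
$\text{familiarity} \times e^{-d/1000\,\text{m}} \times \text{availability}$,
familiarity 1 for M and 0.05 for alternates; the visit proceeds with
probability $S/(S + 0.1)$ where $S$ is the summed weight, so closing M
depresses the visit rate rather than merely redirecting it — the mechanism
behind the increased matrix use and longer steps during closure.
Post-closure, restored availability plus maximal familiarity drive the
return to M (site fidelity).

The landscape is a featureless plane — one neighbourhood per animal-year,
kilometres apart, with M near the home-range centre and a truncated-Poisson
number of alternates (mean 4) at truncated-Gaussian distances (mean 700 m,
sd 300 m) from M. Ad libitum provisioning removes depletion, so homogeneous
vegetation quality is consistent with the design being emulated. Raw phase
lengths are 14 days plus a uniform surplus of up to 3 days, so phase
truncation always has leading excess to remove. Optional uniform fix dropout
(never interpolated) emulates imperfect GPS acquisition.

The behavioural rates were calibrated once by a coarse grid search
(`scripts/calibrate.R`) so that the default population lands near the
regime the design targets: mean hourly displacement ~55–60 m, mean
$h_{FS} \approx 0.34$ with wide inter-individual spread, pre-closure use
near M/A/V $\approx$ 31/2–4/65%, closure use of A $\approx$ 16–20%, and
pre-closure home ranges of roughly 30 ha. The mode step-length means
(10/55/150 m) and the design constants are fixed, not searched.

What the simulator does **not** emulate: terrain, snow, cover, conspecific
interactions, predation risk, energetics, GPS positional error, or
non-Markovian memory beyond the static familiarity weights. Passing tests on
synthetic data therefore validate the pipeline's arithmetic and the
direction and rough magnitude of the experimental contrasts — not the
ecological realism of any particular field system.

## Problem sizes and approximations used in the shipped checks

The package's own test suite and the acceptance script analyse a default
synthetic study of 25 animal-years (three 14-day phases at hourly
resolution, 1008 retained fixes each, ~25&nbsp;000 rows), the sampling
design of the experiment being emulated. The binomial models in the
end-to-end runs use `nAGQ = 0` (penalized iteratively reweighted least
squares), which is accurate enough for effect directions and variance
partitioning at these sizes; calibration checks of the model machinery
(coverage, recovery, type-I rates) use the default Laplace approximation on
smaller replicated designs.

## Known limitations

* Isopleth areas count grid cells; at very small bandwidths or coarse
  resolutions the discretisation error of small cores grows
  (boundary-to-area ratio scales like resolution/radius).
* The LRT p-values are asymptotic; with very few groups they run slightly
  anticonservative, which the type-I test brackets explicitly.
* M/A buffer overlaps at 3–4 $\times l$ are resolved by fixed precedence
  (M first); alternative conventions would change state counts only at
  those extreme scales.
* The exclusion rule for resource models catches zero-A users; it does not
  attempt to detect other pathologies (e.g. two equally-used candidate M
  sites), which remain the analyst's judgement.
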