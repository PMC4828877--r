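---
title: "Methods: supply and need modelling for GP workforce planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supply and need modelling for GP workforce planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpworkforce)
library(dplyr)
```

gpworkforce implements a two-part planning model for a regional general
practitioner (GP) workforce: a deterministic state-transition cohort model
of GP *supply*, calibrated to observed stock series by accept-reject
sampling, and a needs-based model of GP *demand* that converts population
burden of disease into required consultations and full-time-equivalent
(FTE) GPs under alternative scenarios. This vignette documents the models,
their assumptions, the tunable parameters, and the design decisions taken
where the methodology left choices open.

## The supply sub-model

### State space and dynamics

The workforce is stratified by sex, five age bands (`under_35`, `35_44`,
`45_54`, `55_64`, `65_plus`), location (urban/rural) and work status.
Full-time means at least 35 weekly clinical hours; part-time means fewer.
Besides the active states there are two exit states per demographic
stratum: *temporary exit* (reversible, e.g. parental leave; retains the
stratum and can re-enter active work) and *permanent exit* (absorbing).

Counts are continuous expected flows, not stochastic realisations: the
model moves the expected proportion of each cohort between states once per
calendar year. With 100 full-time urban GPs and an annual full-to-part
transition probability of 0.05, exactly 5 move that year. Allowed moves
are full-time <-> part-time (within a location), urban <-> rural (within a
status), active -> temporary or permanent exit, temporary exit -> active,
and temporary exit -> permanent exit. For each from-state the residual
`1 - sum(outbound probabilities)` is the stay probability; if sampled
outbound probabilities sum above 1 they are rescaled proportionally with a
warning (stay probability 0), so headcount is always conserved.

### Event order within a year

The within-year order is fixed and documented rather than inferred:

1. **entries** -- graduates and in-migrants are added, allocated across
   active states;
2. **transitions** -- all flows are computed simultaneously from the
   post-entry stock at the effective probabilities;
3. **aging** -- a fraction of each non-terminal band's survivors (active
   and temporary-exit states; permanent exits are absorbing and not aged)
   moves to the next band, state otherwise preserved.

Under this order total headcount (active + temporary + permanent exit) at
the end of a year equals the start-of-year total plus entries, which the
test suite verifies to 1e-9 relative tolerance against an independent
brute-force flow enumeration.

### Time variation

Each transition probability `p` carries an annual percentage-change
multiplier `m`; `k` years after the base year the effective probability is
`p (1+m)^k`, clamped to `[0, 1]`. Compounding (rather than a one-off
shift) is our reading of "annual percentage change"; users supplying their
own multipliers should note this. Multipliers are bounded to
`[-0.10, +0.10]` by convention in the priors.

### Parameters and defaults

| parameter | default | unit / rationale |
|---|---|---|
| aging fraction | 1/10 per non-terminal band | band width 10 years; steady-state flow approximation, configurable |
| graduate entry bands | 70% `under_35`, 30% `35_44` | entry-age split; configurable |
| graduate sex/location/status allocation | base-year stock marginal shares | entry counts are published, allocations are not |
| in-migrant allocation | base-year stock joint distribution | as above |
| entry counts | constant at base-year values | unless a per-year series is supplied |
| standard week | 40 h | full-time clinical working week |
| working year | 44 weeks | allows for leave; 40 x 44 = 1760 clinical h/FTE/year |
| default weekly hours | 40 full-time, 24 part-time | the source hours distribution is unpublished; override via `hours.csv` |

Hours lookups fall back from the full (sex, age band, status) stratum to
the status-only mean and error only when a populated status has no hours
at all.

## Calibration

Candidate parameter sets are sampled from per-transition priors: a beta
distribution for each base probability and a uniform range for each
multiplier. Each candidate is projected over the target years and accepted
iff its predicted headcount deviates by less than the tolerance (default
5%) from the smoothed observed value at *every* (year, stratum) target;
all convergent sets are retained, representing the joint parameter
uncertainty for sensitivity analyses. The search is plain seeded
accept-reject sampling (candidate `i` uses seed `seed + i`), chosen for
reproducibility over solver-based searches.

Observed series are smoothed with a per-stratum ordinary-least-squares
linear trend before comparison, because survey definition changes make the
raw year-to-year series jumpy. Deviations use the smoothed observed value
as denominator; targets with a smoothed value of 0 are dropped with a
warning. Alongside per-target percentages the report carries the summed
absolute headcount deviation across years. When nothing converges the
result is empty but carries the best (minimum-max-deviation) candidate as
a diagnostic.

Priors are a required user input: the package ships no real transition
rates, and the reference rates behind the original model were revised by
expert review rather than published. The synthetic fixtures play that
role in testing (below).

## The need sub-model

### Fitting service norms

There is no gold standard for the level of service a condition requires,
so base-year norms are *fitted* from utilisation: within each sex and age
band,

```
per_case(chapter) = attendances x share(chapter) / (incident + prevalent cases of chapter)
```

where `share(chapter)` is the proportion of consultations in which the
chapter's conditions are managed. Preventive and administrative activity
is captured as consultations per capita (`attendances x pa_share /
persons`). Because one consultation can manage several problems, chapter
shares may sum above 1; each chapter is fitted independently, so projected
chapter volumes are problem-management volumes and the reconstruction
identity -- projecting the fitted profile on its own inputs returns the
observed attendance totals -- holds on the share-weighted sum as fitted.
A positive share with zero cases is a fit error naming the cell. Burden
sources grouped by cause categories are recoded onto condition chapters
through a user-supplied two-column crosswalk (`map_burden_categories()`).

### Projection and scenarios

Cases are projected as base-year per-capita rates times the projected
population, compounded by an annual growth factor in age- and sex-specific
rates; required consultations are `per_case x utilisation^k x cases`
summed over chapters plus the per-capita preventive/administrative volume,
which scales with population. Required FTE is total minutes / 60 / 1760.
Three preset scenarios:

| scenario | utilisation multiplier | burden growth | reading |
|---|---|---|---|
| 1 | 1 | 1 | base-year utilisation optimal; demographics drive change |
| 2 | 1.0112 | 1 | utilisation optimal at the end of the decade (+1.12%/year per case) |
| 3 | 1 | 1.02 | incidence and prevalence rates rise 2%/year |

Both factors compound annually from the base year (supply base year 2004,
need base year 2003 by default). Scenario 2 equals scenario 1 at the base
year by construction; scenario 3 dominates scenario 1 in every later year
because required FTE is monotone in both factors.

## Synthetic data: what it emulates and what it does not

All tests run on generated fixtures with known truth; the package ships no
real data.

The **supply fixture** fixes a true transition table and multiplier set
(smooth deterministic functions of the stratum indices, so every stratum
differs but nothing is sampled), projects them forward to create the
observed target series, and optionally perturbs the targets with
multiplicative lognormal noise (headcounts are positive; default sdlog
0). Priors are informative distributions centred on the truth -- beta
with effective sample size 2000 and uniform multiplier ranges of
half-width 0.02 around the true values (clipped to the +-0.10 bound) --
emulating the expert-revised priors of a calibrated planning model rather
than raw longitudinal survey rates.

One generator choice deserves emphasis: the base stock is produced by
burning the cohort in to demographic equilibrium under the base-year
probabilities. Calibration deviations are measured against linearly
smoothed targets, so a recovery experiment is only coherent when the true
trajectories are themselves near-linear over the window -- as the real
observed series are. Far from equilibrium, the linear smoother's
lack-of-fit alone would reject even the generating parameters; that is a
property of the smoothing, not of the calibration. The `paper_like`
preset anchors the baseline active headcount (1789) and the 42:47
graduate-to-migrant mix, scaling entry counts with the stock so
equilibrium is preserved; the `toy` preset (2 sexes x 2 bands x urban
only) keeps oracle and recovery tests fast.

The **need fixture** is built backwards from a true service profile:
attendances are computed as the profile's implied volumes, and the
condition-mix shares are derived so they sum to exactly 1 per cell, which
makes the generate-then-fit round trip exact (verified to 1e-9 relative)
and the reconstruction identity bind.

Passing tests on these fixtures show that the estimators invert their own
generative model correctly and that the dynamics respect their invariants.
They do not show that real workforce data meet the assumptions: real
observed series have definition breaks and non-lognormal noise, real
condition mixes overlap (shares summing above 1), burden categories map
imperfectly onto consultation chapters, and consultation lengths vary by
condition, none of which the fixtures emulate.

## Numerical choices and degenerate inputs

- Counts are continuous; rounding happens only in rendered reports
  (headcounts to integers, FTE to one decimal).
- Effective probabilities are clamped to `[0, 1]`; overloaded outflows are
  rescaled proportionally, with a warning, preserving conservation.
- An empty outbound set is an absorbing state (stay probability 1).
- Smoothing requires at least two observations per stratum and errors
  otherwise, directing the user to supply the raw value.
- Percent-difference denominators are always the observed (or smoothed
  observed) value, consistently between calibration and validation
  reports.
- Seeds: every stochastic step takes an explicit integer seed and restores
  the global RNG state (`withr::with_seed`); fixture generation is a pure
  function of its config.

## Problem sizes used by the shipped tests

The test suite and the acceptance script use the toy state space for the
heavy loops: 1000 random single-step trials against the brute-force
oracle, 100 random parameter sets for the conservation suite, and a
5000-sample calibration at 2% target noise (8 target years, 64 targets)
for parameter recovery. The need-model round trip and scenario ordering
run on the paper-like dimensions (17 chapters x 10 strata, 10-year
horizon). These sizes were chosen to exercise every code path with
comfortable margins while keeping a full run in the order of a minute or
two on one CPU.

## Known limitations

Inherited from the methodology: no sub-state geography for need, no
multimorbidity adjustment, uniform consultation length across conditions,
and no stochastic (individual-level) realisations -- the model propagates
expected values. Additions of this package's own: aging fractions are a
steady-state approximation rather than an age-distribution model, and
entry allocations default to base-year stock shares where the underlying
data are unpublished. Scenario projections are point estimates; the
retained calibration sets support sensitivity analysis around supply, but
no uncertainty intervals are produced for need.
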