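---
title: "Designing rainfall-deficit index insurance with rainindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing rainfall-deficit index insurance with rainindex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rainindex)
```

## The problem

Smallholder farmers in drought-prone tropical regions carry rainfall risk that
conventional crop insurance cannot serve: verifying losses farm by farm is
expensive and invites moral hazard and adverse selection. Weather-index
insurance replaces loss adjustment with a transparent index computed from an
official weather-station record. The insurer pays when the index crosses a
trigger, regardless of what happened in any particular field.

The quality of such a contract stands or falls with how well the index tracks
crop losses. A naive index — say, a percentage shortfall of seasonal rainfall
— carries heavy basis risk, because it ignores *when* the rain failed: a dry
spell at flowering can destroy a bean crop that the same dry spell just after
sowing would barely touch. `rainindex` implements a calibration procedure
that builds the timing in: the season is cut into dekads (10-day windows),
each dekad is assigned a minimum water requirement (MWR, in mm of rainfall),
and the index is the total rainfall *deficit* — the sum over dekads of
`min(rain − MWR, 0)`. Rainfall above the MWR in one dekad cannot compensate a
shortfall in another; only shortfalls count.

The MWR row is not guessed. It is fitted against simulated water-limited
yields so that, over the worst quarter of simulated seasons, the total
deficit correlates maximally with yield.

## The pipeline

The full workflow, driven by `run_pipeline()` from a YAML configuration:

1. **Weather** (`generate_daily()`): multi-year daily rainfall per site from
   a seeded stochastic generator.
2. **Sowing** (`determine_sowing_date()`): each year's sowing date from an
   onset rule ("first day after *k* consecutive rainy days over τ mm each")
   inside a sowing window.
3. **Aggregation** (`aggregate_to_dekads()`): rainfall totals for dekads
   positioned relative to sowing, by default day −10 to day +70 (8 dekads).
4. **Yields** (`run_grid()`, `simulate_yield()`): a soil-bucket water-balance
   crop model on a set of generic soils, producing a run table with one row
   per (pixel, soil, year).
5. **Calibration** (`lowest_quartile()`, `initial_mwr()`, `calibrate_mwr()`):
   the MWR row per pixel × soil, maximizing the squared correlation of total
   deficit with yield over the lowest yield quartile, subject to MWR ≥ 0.
6. **Contract** (`contract_spec()`, `evaluate_season()`): the familiar
   MIN/RAIN/DEF sheet with a trigger (e.g. −70 mm) and an indemnity rate
   (e.g. US$5 per mm of deficit beyond the trigger).
7. **Pricing** (`exceedance_probability()`, `price_contract()`, `risk_map()`):
   empirical trigger-exceedance frequencies and burn-rate premiums per
   pixel × soil, plus soil means.

## The weather generator

Rain occurrence follows a wet/dry Markov chain whose state is the wet/dry
history of the last 1–3 days (default order 3). A first-order chain cannot
reproduce the long clustered wet and dry spells of tropical convective
rainfall; the higher-order history gives runs of wet days a higher chance of
continuing and dry spells a higher chance of persisting. Two
parameterizations are offered: a full month × state probability matrix, or a
monthly wet-day probability plus a `persistence` coefficient that scales the
probability up when the recent history is wet and down when it is dry.

Wet-day amounts are gamma distributed with monthly shape and scale. The
mid-season dry spell characteristic of Central America (the *canícula*,
July–August, separating the *primera* and *postrera* cropping seasons) is
imposed by multiplying the wet-day probability inside a calendar window by a
depression factor.

Deliberate simplifications: years are 365 days (the method never references
calendar precision); temperature and radiation are not generated (they vary
little over the growing season at a given tropical site, and the crop model
is rainfall-driven); no interannual climate modes (ENSO conditioning is out
of scope). Each year draws from a substream derived deterministically from
the master seed, so output is reproducible and extending `n_years` does not
perturb earlier years.

## The crop model

`simulate_yield()` runs a per-dekad bucket water balance:

* infiltration = rain × (1 − runoff fraction); the runoff fraction grows
  with texture heaviness and slope (`runoff_fraction()`), reflecting the
  lower infiltration rates of fine-textured and sloping soils;
* available water = carried storage + infiltration + a small constant
  `trickle_mm` (capillary rise, dew and extraction below the nominal root
  zone — see below);
* uptake = min(available, demand) for that dekad's crop water demand;
* closing storage is capped at the soil's plant-available water-holding
  capacity (WHC); the surplus drains.

Yield is multiplicative stage-stress:
potential × Π<sub>d</sub> (relative supply<sub>d</sub>)<sup>s<sub>d</sub></sup>,
with relative supply = min(1, uptake/demand) and stage sensitivities
s<sub>d</sub> peaking at flowering and pod fill, echoing the shape of a
calibrated MIN row (low at establishment and maturity, high mid-cycle). An
optional mean-one lognormal noise term stands in for everything the water
balance ignores (pests, management, nutrient status); it is switchable off
for deterministic tests. Yields are clamped to [0, potential].

Default crop parameters describe a 60–75-day drybean cycle evaluated over 8
dekads from day −10: demands (10, 25, 40, 55, 60, 55, 55, 40) mm/dekad,
totalling 340 mm — inside the 300–400 mm optimum for the crop; a season that
meets every demand exactly reaches the potential yield in noise-free mode.

The `trickle_mm` term (default 2 mm/dekad) deserves a note. Without it, the
power-form stress model sends yield to *exactly* zero the moment any
sensitive dekad has zero available water, producing an unrealistic atom of
identical total-failure years; real crops retain access to residual water
and fail gradually. The trickle keeps relative supply strictly positive so
drought damage is graded — all-zero-rainfall seasons still end below 5 % of
potential.

Eight generic soils ship as defaults: four textures (sand, loam, clay loam,
silty clay) × two profile depths. WHC rises with texture fineness and depth
(shallow sand 30 mm … deep silty clay 140 mm); the runoff fraction rises
with fineness (2 %–15 % on flat land) and with slope. Both lookup tables are
package defaults, not measurements of any particular landscape: the design
names the soil set, not its values.

## Calibration choices

**Objective.** The optimizer maximizes the squared Pearson correlation
between total deficit and yield over the lowest yield quartile. Squared
correlation and absolute correlation have the same maximizers here (deficit
correlates positively with yield by construction), and a squared objective
is what the reported R² range refers to.

**Lowest quartile.** floor(n/4) smallest yields; ties broken by stable input
order with a warning. The upper and middle quartiles are not used in
fitting: good years carry no deficit information.

**Starting values.** `initial_mwr()` supplies a plausible start: the
per-dekad median rainfall of the top-quartile-yield runs, capped at the
per-dekad minimum over the upper three quartiles. The cap enforces, exactly,
the design property that runs with good yields have zero total deficit at
the start — only drought years register shortfall.

**Optimizer.** Multi-start bounded L-BFGS-B (default 8 starts: the supplied
start, the subset's per-dekad rainfall median, upper quartile and maximum,
then uniform random starts), followed by a Nelder–Mead polish of the best
iterate — the objective has kinks where an MWR crosses an observed rainfall
value, and the derivative-free polish cleans up what the quasi-Newton steps
leave. Multi-start order is fixed by the seed, so results are reproducible.
On 2- and 3-dekad problems the returned objective matches an exhaustive grid
search to 10⁻⁶.

**Bounds.** MWR ≥ 0 elementwise, and ≤ `mwr_max` (default 80 mm/dekad,
about the potential evapotranspiration of a tropical crop over ten days). The
upper bound is substantive: without it the correlation objective has a
degenerate attractor in which every dekad's MWR exceeds every observed
rainfall and the "deficit" collapses into total rainfall minus a constant —
a valid correlate, but no longer a *minimum water requirement*. A per-dekad
vector bound (e.g. the crop demand row) can be supplied instead; the scalar
default is deliberately looser because on storage-buffered soils rainfall
above the instantaneous demand is banked and genuinely required later.

**Degeneracy and ties.** Raising an MWR below the subset's minimum rainfall
for its dekad changes nothing; after optimization such entries are snapped
to zero, the smallest equivalent value. Among starts whose final objectives
tie within 10⁻⁶, the row with the smallest rainfall index (sum of MWRs) is
returned — the parsimonious representative. Zero yield variance in the
subset is an error, not a silent zero.

**Window.** The default calibration window is 8 dekads from day −10 to
day +70 around sowing; the contract sheet may instead span 9 dekads (days
1–90). Both conventions appear in practice and the dekad count is a
first-class parameter throughout — nothing in the package hard-codes either.

## Contract and pricing conventions

Deficits are stored as negative numbers; the trigger is negative (e.g.
−70 mm). A season is *triggered* when total deficit ≤ trigger, and the
indemnity is rate × max(0, |total| − |trigger|): payment accrues per mm
beyond the trigger, so a season exactly at the trigger is flagged but pays
zero. The official reference-station record settles claims; the contract
sheet's RAIN row is informational for the policyholder.

Premiums are burn-rate: the fair premium equals the mean simulated payout
per season, and a multiplicative loading (default 0) is exposed for
everything an actuary would add. Exceedance probabilities are empirical
frequencies — no distribution is fitted and no tail extrapolation is
attempted, so probabilities of deficits rarer than the simulated record are
reported as 0 rather than extrapolated.

`risk_map()` accepts per-cell calibrated MWR rows, so each soil within each
pixel is priced under its own index (as when contracts are site- and
soil-specific); with a single template row, soils sharing a pixel's weather
are — correctly — indistinguishable, since the index reads station rainfall,
not soil moisture.

## What the synthetic generators do and do not show

The weather and crop generators exist so the whole pipeline is testable
offline, seeded and at desk scale. They emulate the *structure* the
calibration relies on — clustered tropical rainfall with a mid-season dry
spell, and yields whose losses trace dekad-specific water shortfalls — and
the shipped demo conditions were chosen once to produce a realistic
water-limited yield distribution (droughty enough that the lowest quartile
is drought-driven, wet enough that total crop failure is the exception).
Under those conditions a 99-year deep-loam calibration attains
lowest-quartile R² ≈ 0.7–0.9 across seeds, consistent with the range the
method is reported to reach against a full crop model.

They do not emulate: absolute yield levels of any real region or variety
(no genetic coefficients, no management), spatial correlation between
pixels, temperature or radiation response, ENSO, or observed station
records. Passing tests therefore demonstrate the method's internal
soundness — recovery of known stage demands, oracle-equality of the
optimizer, correct orderings across soils and triggers — not skill against
field data.

Two fixture regimes appear in the tests. The *droughty* demo climate
exercises calibration quality. A *milder* matched-grid climate (higher wet
probability, weaker canícula) is used for cross-soil comparisons and
parameter recovery: with moderate stress the deficit–yield relation is close
to linear and identifiable, whereas under catastrophic drought the lowest
quartile degenerates into near-total failures whose ranking carries little
information — a regime in which no rainfall index (and no insurer) operates.

## Numerical and scale choices

* Convergence tolerance 10⁻⁸ on the objective, ≤ 500 iterations per start.
* Demo problem sizes: 3 pixels × 2 soils × 30 years for end-to-end runs
  (seconds), 99 years for single-cell calibrations (~1–2 s per cell). At 30
  years the lowest quartile holds only 7 seasons against 8 free MWR entries,
  so demo-scale calibration R² runs high (in-sample overfit); the 99-year
  calibrations are the meaningful ones.
* The full-scale design — 151 pixels × 8 soils × 99 years = 119,592 runs —
  is accounted for exactly but only executed at reduced scale.
* Currency is a tag on decimal quantities; no exchange-rate logic.

## Known limitations

* The calibrated MWR row is only as identifiable as the lowest quartile is
  informative; cells where the index explains little (e.g. heavily buffered
  soils under mild climates) yield unstable rows with low R², and a real
  contract design would reject them on exactly that diagnostic.
* Pearson correlation is sensitive to single extreme seasons in a 24-point
  subset; the multi-start optimizer finds the global objective, but the
  objective itself inherits that sensitivity.
* Empirical exceedance probabilities cannot see beyond the simulated record;
  pricing rare triggers needs longer simulations, not this package's tails.
* One reference station per pixel: spatial basis risk within a pixel is not
  modelled.
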