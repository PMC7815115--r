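---
title: "Modelling regional soil organic carbon dynamics with socdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling regional soil organic carbon dynamics with socdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socdyn)
```

## The problem

Dry (rain-fed) farmland holds large soil organic carbon (SOC) stocks whose
slow drift — a few hundredths of a megagram of carbon per hectare per year —
decides whether a cropping region is a carbon source or sink. Direct
measurement at regional scale is impossible at that precision, so the
standard approach couples a multi-pool SOC turnover model to a polygon-based
soil database: every map polygon carries measured soil attributes, is driven
by its nearest weather station, is initialised against its measured SOC, and
is simulated forward independently. `socdyn` implements that pipeline
end-to-end for the 0–20 cm layer of a temperate continental monsoon cropping
region, together with seeded synthetic-data generators so the whole analysis
is testable without any external database.

## The turnover model

The model is a carbon-only, monthly-timestep turnover network in the CENTURY
tradition, with five pools (g C m⁻²): structural and metabolic litter,
and the active, slow and passive soil organic matter pools. Incoming plant
residue is split 55% metabolic / 45% structural; each pool decays every month
by the exact within-month exponential

$$D_i = C_i\,\bigl(1 - e^{-k_i\,\mathrm{DEFAC}\,m_i/12}\bigr),$$

with base rates $k$ (yr⁻¹) of 3.9 (structural), 14.8 (metabolic), 7.3
(active), 0.2 (slow) and 0.0045 (passive). The exponential form (rather than
forward Euler) means even the fast metabolic pool cannot decay below zero at
any climate scalar. $m_i$ is 1 except for the texture effect on the active
pool ($1 - 0.75(\mathrm{silt}+\mathrm{clay})$) and a ×1.2 cultivation
multiplier on litter and active pools in tilled months.

Decayed carbon is partitioned by fixed flow fractions: structural litter
respires 30%, sends the lignin share (default 0.20) of the remainder to the
slow pool and the rest to the active pool; metabolic litter respires 55%,
remainder to active; the active pool respires the texture-dependent fraction
$0.85 - 0.68(\mathrm{silt}+\mathrm{clay})$ and routes
$0.003 + 0.032\,\mathrm{clay}$ of the remainder to the passive pool, rest to
slow; the slow pool respires 55% and routes $0.003 + 0.009\,\mathrm{clay}$
of the remainder to passive, rest to active; the passive pool respires 55%,
remainder to active. Every flow fraction is state-independent, which has two
consequences used throughout the package: carbon mass balance closes to
float precision by construction, and a simulated year is an exact affine map
of the pool vector (see *Spin-up* below).

Climate enters through a single decomposition scalar
$\mathrm{DEFAC} = f_T \times f_W \in [0,1]$: a Q10 temperature response
$f_T = \min(1, 2^{(T-30)/10})$ and a moisture response
$f_W = \min(1, \max(0.1, P/\mathrm{PET}))$, with potential
evapotranspiration from the classical Thornthwaite monthly formula
(day-length corrected; PET = 0 for months at or below 0 °C). The floor of
0.1 keeps a trickle of decomposition in frozen or rain-free months. This
two-parameter abiotic scalar deliberately replaces a full soil
temperature/moisture sub-model: it preserves the qualitative climate
sensitivity with interpretable parameters, at the price of ignoring snowmelt
moisture storage and soil-air temperature lags.

Plant production in a growing-season month is
$\mathrm{PRDX} \times g_T \times f_W$, with a parabolic temperature response
$g_T = \max\{0, 1-((T-T_{opt})/T_{width})^2\}$ ($T_{opt}/T_{width}$ = 25/15 °C
for corn, 22/15 for soybean, 20/15 for C3 grass). PRDX, the potential
monthly production (g C m⁻² month⁻¹, default 150), is the single calibration
knob. Half of production is allocated aboveground. Grassland drops its
litter continuously (less a grazing offtake); crops accumulate standing
biomass, and at harvest the grain and surplus straw are exported while a
fixed residue-return fraction (default 0.15) of aboveground biomass plus all
roots enter the litter pools.

Bookkeeping: SOC content (g kg⁻¹) of a state is total pool carbon divided by
$BD \times \mathrm{depth_{cm}} \times 10$ (the kg of soil per m² in the
layer), so SOC density obeys SOCD (Mg C ha⁻¹) = SOCC × BD × H × 0.1 =
g C m⁻² × 0.01, and regional stocks are
$\mathrm{SOCS\,(Tg)} = \sum_i \mathrm{SOCD}_i S_i / 10^6$ over polygon areas
$S_i$ (ha).

## Spin-up and calibration

Initial pool sizes dominate a multi-pool model's behaviour, so each polygon
is initialised in three stages:

1. **Grassland equilibrium** (3000 years): temperate C3 grassland with
   moderate grazing (30% of monthly aboveground production) and one litter
   burn (80% of litter, April) every tenth year, from zero pools under
   long-term mean monthly climate.
2. **Historical agriculture** (default 80 years): corn with 15% residue
   return and a small organic amendment (15 g C m⁻² yr⁻¹).
3. **Early-fertiliser agriculture** (25 years): the same cropping with
   30 g C m⁻² yr⁻¹ organic amendment and a 10% mineral-fertiliser production
   boost.

Because the model is affine in the pool vector under fixed monthly forcing,
stage 1 does not need three thousand simulated years of stepping: the
one-year (or one-fire-cycle) affine map is probed from the step function
itself and raised to the required power by repeated squaring
(`equilibrium_stage(fast = TRUE)`), reproducing the stepped trajectory
endpoint to float precision. The true fixed point $(I-A)^{-1}b$ is exposed
separately as `steady_state()`. The two are distinguished deliberately:
under a cool continental climate (mean DEFAC ≈ 0.16) the passive pool's
e-folding time is on the order of a millennium, so a 3000-year run from zero
reaches only a *relative* equilibrium a few percent below the fixed point.
Tests therefore check the fixed point as a fixed point (a trajectory started
on it stays flat), and check its agreement with a from-zero run under warm,
wet forcing where convergence is genuinely complete.

The stage-2 duration deserves a note. The historical cropping period could
be simulated at full length (`default_stage_plans(full_history = TRUE)`),
but at these turnover rates anything beyond a century of fixed management
adds cost without information — except that it also *erases* the
grassland-legacy disequilibrium: after two or more slow-pool time constants
of cropping, the simulated system sits at its cropping equilibrium and the
subsequent fertiliser-era transient makes regional SOC *rise*. The dry
farmland this package emulates was largely reclaimed from grassland in the
late 19th and early 20th century, so the default uses 80 years: at 1985 the
slow and passive pools still carry grassland legacy, and the simulation
period shows the slow regional decline characteristic of such regions. This
is the package's own reading of the land-use history, and it is the single
most consequential default in the spin-up.

**Calibration.** A single global multiplier on PRDX, applied to all stages,
is searched by bisection on [0.1, 10] until the end-of-initialisation SOC
content matches the polygon's attributed value within 1% (final SOC is
monotone in the multiplier, which is asserted by tests; an unreachable
target fails loudly with the achievable range). Only this one parameter is
calibrated: with one measured value per polygon, one degree of freedom is
all the data can support.

## Regional scaling

Each polygon takes the weather record of its nearest station (haversine
distance on WGS84 coordinates, ties broken by lowest station id), is
initialised as above with climate normals from the 1955–1980 window, and is
then simulated year by year from 1985 to 2015 under the modern schedule,
reporting December-state SOC density annually. Polygons are independent, so
results are order-invariant and trivially parallelisable; a polygon whose
calibration or run fails is reported by id and excluded from aggregates,
never silently dropped. The modern schedule keeps corn with 15% residue
return and mineral fertiliser but lowers the organic amendment to
10 g C m⁻² yr⁻¹ — below the collectivised-era level of stage 3 — reflecting
the replacement of farmyard manure by chemical fertiliser from the 1980s on.

## Validation metrics

Monitoring-site validation uses the sample Pearson correlation between
observed and simulated series, with the conventional verbal classes
(r ≥ 0.8 high; 0.5–0.8 moderate; 0.3–0.5 low; < 0.3 extremely weak), and a
Nash–Sutcliffe-type modelling efficiency
$ME = 1 - \sum(P_i-O_i)^2 / \sum(O_i-\bar O)^2$ (1 = perfect; ≤ 0 = no
better than the observed mean). A second variant with $\sum(P_i-\bar O)^2$
in the denominator — a form that circulates in the applied literature — is
implemented as `variant = "as_printed"` and reported alongside, but the
standard form is the default and the one interpreted. Per-polygon density
changes are reported in left-closed bins
(−∞,−10), [−10,−5), [−5,0), [0,5), [5,∞) Mg C ha⁻¹, with zero on the gain
side; descriptive summaries use the sample (n−1) standard deviation.

## What the synthetic data emulate — and what they do not

The generators are pure functions of a seed and a configuration whose
defaults describe the study system: six soil groups with fixed attribute
centroids (texture, bulk density, SOM, pH), SOM converted to SOC content by
the van Bemmelen factor 0.58; polygon attributes jittered around the
centroids (texture cv 10%, renormalised; bulk density cv 5%; SOM cv 20%,
floor 2 g kg⁻¹); lognormal areas (median 4000 ha); centroids uniform in the
region's bounding box with sandier polygons placed further west; station
weather with annual means drawn from 2–6 °C and 400–600 mm, a July-peaked
19 °C seasonal temperature amplitude, and 65% of precipitation in
June–August with multiplicative gamma noise.

The monitoring fixture is a black-soil corn plot with the canonical
attributes of a long-term monitoring site (pH 5.0, BD 1.00 g cm⁻³, texture
45.0/34.5/18.7 renormalised, 2413 g C m⁻² initial carbon, observed
1988–2007). Its "observed" series is a forward simulation under a known
productivity multiplier plus 5% multiplicative observation noise, so
validation statistics and calibration recovery are testable against exact
truth. The default truth multiplier is 3.5× the calibrated maintenance
value: a near-maintenance trajectory is almost flat (standard deviation
≈ 0.2 Mg C ha⁻¹ against an observation-noise standard deviation ≈ 1.2), and
no series so dominated by noise can exhibit the high observed/simulated
correlation such validations report; a plot under the era's intensifying
management (maize yields more than doubled over the window, manured
long-term plots gained 40–70% SOC) produces a trajectory whose
signal-to-noise supports the high correlation class across noise
realisations. Degrading plots can be emulated with `productivity_trend < 1`,
but note that losses saturate — decomposition caps the achievable decline
near 25% over twenty years — so strongly-degrading fixtures carry less
signal than strongly-improving ones.

What the generators do **not** emulate: real polygon geometry (centroids
stand in for polygons; no overlay analysis), spatial autocorrelation of
attributes beyond the one west–east texture gradient, measured soil-profile
heterogeneity within groups (the jitter is i.i.d.), observation-error
structure beyond i.i.d. multiplicative noise, and any nitrogen, phosphorus
or sulfur limitation (the model is carbon-only). A passing test suite
therefore demonstrates internal correctness and the qualitative behaviour of
the method, not agreement with any particular measured landscape.

## Numerical choices and degenerate inputs

* Monthly decay uses `1 - exp(-k DEFAC m / 12)`; no clamping is ever needed
  and a negative pool after a step raises an internal-consistency error.
* The affine year map is probed directly from the step function (six
  evaluations), so the analytic and stepped paths cannot drift apart.
* Bisection stops when the achieved SOC content is within 1% of target
  (relative), with a 50-iteration cap; the multiplier bracket [0.1, 10]
  spans all six soil groups' targets with room to spare (observed calibrated
  multipliers: ≈ 0.49–0.93).
* Nearest-station ties within a 10⁻⁹ relative distance band resolve to the
  lowest station id, making assignment deterministic under float jitter.
* A weather record shorter than the simulated span recycles cyclically with
  one logged warning; an empty record is an error.
* Zero residue input yields exactly zero equilibrium pools; a zero-area or
  zero-SOC polygon is rejected before any simulation, with its id attached.
* Density-change bins are left-closed, so exactly −5 falls in [−5,0) and
  exactly 0 counts as a gain.

## Problem sizes used in tests

The shipped tests and the acceptance script run the complete pipeline at
desk scale, the package's intended verification size: a 100-polygon,
31-year regional run (a few hundred thousand monthly steps plus one
calibrated spin-up per polygon, ~15 s), 500-year stepped-versus-analytic
spin-up comparisons, three-point calibration-recovery sweeps, and 100-draw
noise ensembles on the monitoring fixture. Nothing in the method is specific
to that scale; `generator_config()` and the stage plans expose the counts
and durations.

## Known limitations

* Carbon only: no nutrient feedback on production, so fertiliser acts only
  through the production multiplier and amendment carbon.
* One soil layer (0–20 cm) with static bulk density; no erosion, leaching,
  or depth redistribution.
* Management schedules are annual-cyclic within a stage; no rotation-level
  interannual management variability.
* The abiotic scalar ignores soil moisture storage: a dry June after a wet
  May is drier in the model than in the field.
* Calibrating one multiplier against one measured SOC value cannot separate
  production from decomposition errors; the calibrated multiplier absorbs
  both.
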