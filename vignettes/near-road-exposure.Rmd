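---
title: "Modelling near-road exposure from link-based traffic emissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling near-road exposure from link-based traffic emissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nearroad)
```

## The model

`nearroad` estimates hourly concentrations of traffic-generated pollutants
at receptor locations (for example, study participants' homes) with a
bottom-up, fully decoupled emissions-times-dispersion design.

For each road link $i$ the hourly emission is

$$E_i = EF_i \times A_i,$$

where the composite emission factor is the fleet-weighted class factor

$$EF_i = \sum_{\text{veh.class}} ef(\text{pollutant}, \text{speed},
\text{month}, \text{temperature}) \times \text{fleet mix}(\text{veh.class})$$

and the hourly activity allocates annual average daily traffic over time,

$$A_i = AADT_i \times TAF_i(\text{hour}, \text{day}, \text{month}).$$

Dispersion is computed once, at a unit line-source emission rate of
1 g/m/s, giving per-link unit concentrations $\chi_i$ (µg/m³ per g/m/s)
for every receptor and hour. The receptor concentration is then the
linear combination

$$C = \sum_i E_i \times \chi_i .$$

Because $\chi$ never depends on emissions, any emissions revision — a
traffic-volume correction, a fleet-mix reassignment — only requires
re-running the cheap emissions step and re-weighting the stored $\chi$
matrix, never the dispersion model. `apply_adjustments()` exploits exactly
this, and the test suite asserts the $\chi$ matrix is bit-identical across
the adjustment.

### Emission factors and fleet mixes

Emission-factor tables are consumed, not generated: a long table keyed by
month (1–12), pollutant, vehicle class, temperature bin (0–100 °F by 10)
and speed bin (2.5 mph, then 5–75 by 5). Lookups use the nearest bin on
each axis, with ties rounding to the upper bin and out-of-range values
clamped to the end bins. We standardise on the 5-mph bin structure of the
table itself; composite factors renormalise the fleet-mix fractions to sum
exactly 1, so the composite is a convex combination of class factors.

The packaged urban fleet-mix catalog carries three mixes (interstate,
arterial, other). `diesel_fraction()` deliberately sums the *raw printed*
fractions rather than the renormalised ones, so the catalog's diesel
percentages (9.18% for interstates, 5.23% for arterials) reproduce to the
printed digit; the renormalisation inside `composite_ef()` changes fleet
ratios only in the fourth decimal.

Temporal allocation is normalised so that AADT stays the annual-average
daily total: the 24 hourly factors of each day type sum to 1, and the
day-of-week and monthly factors average 1. Holidays are treated as their
weekday; weekends are Saturday and Sunday. Under these conventions a
365-day sum of hourly activity reproduces $365 \times AADT$ to within
0.1% (the residual comes from unequal month lengths and the 52-week
remainder day).

### Dispersion

The line-source kernel is a steady-state Gaussian plume integrated along
the link polyline in the wind-aligned frame of each hour. Hourly surface
meteorology (friction velocity $u_*$, Monin–Obukhov length $L$, convective
and mechanical mixing heights $z_{ic}$/$z_{im}$, roughness $z_0$, wind
speed and direction) drives the derived scales:

* $w_* = u_* (z_{ic} / (\kappa |L|))^{1/3}$ in convective hours, else 0;
* $\sigma_v = \max\!\big(\sqrt{(a_v u_*)^2 + (b w_*)^2},\; 0.2\big)$,
  $\sigma_w = \max\!\big(\sqrt{(a_w u_*)^2 + (b w_*)^2},\; 0.1\big)$;
* effective transport speed $u_e = \sqrt{u^2 + 2\sigma_v^2}$, which stays
  finite and above the mean wind even in light-wind hours;
* mixing lid $z_{mix} = \max(z_{ic}, z_{im})$ when $L < 0$, else $z_{im}$.

Stability classes follow the Monin–Obukhov bands: neutral $|L| > 500$ m,
stable $100 < L \le 500$ m, very stable $0 < L \le 100$ m, convective
$-500 \le L < 0$ m. Band edges belong to the class given by these
inequalities, and the physically ambiguous shallow range $L \in (0, 1]$ m
is treated as very stable. $w_*$ is used only when the hour *classifies*
convective: for a near-neutral hour with a large negative $L$ the
convective velocity scale is not meaningful, and suppressing it there also
keeps $\sigma_v$ continuous across the $L \to -\infty$ / $L \to +\infty$
neutral limit.

Plume growth uses travel time $t = x/u_e$:
$\sigma_y = \sigma_v t (1 + t/T_y)^{-1/2}$ with $T_y = 600$ s, and
$\sigma_z = \sigma_w t \, g(t)$ with $g = (1 + t/T_z)^{-1/2}$, where
$T_z = c_{zs} |L| / \sigma_w$ under stable stratification and
$T_z = c_{zn} z_{mix} / \sigma_w$ in neutral hours ($g = 1$ in convective
hours). The vertical term carries ground reflection and two mixing-lid
image pairs, collapsing to the well-mixed $1/z_{mix}$ limit once
$\sigma_z > 1.2\, z_{mix}$.

Light-wind meander is on by default: a fraction
$f_m = \min(1, 2\sigma_v^2/u_e^2)$ of the material is spread radially
($1/2\pi r$) over all directions, which is what produces the observed
nonzero concentrations at near-road *upwind* receptors in calm stable or
convective hours. With meander disabled, upwind concentrations collapse
to zero.

All constants live in `dispersion_constants()`. Two were set away from
their classical surface-layer values as the package's calibration of the
(otherwise unconstrained) vertical diffusion: `a_w = 1.6` (rather than
1.3) and `c_zn = 1.2` (rather than 0.6). The increased vertical
coefficient absorbs vehicle-induced turbulence over and near the roadway;
the longer neutral time scale weakens the (theoretically under-determined)
neutral damping. With this pair, the normalized
concentration-versus-distance profiles of the representative convective
and neutral hours agree within ~6% over a 10–500 m transect — matching
the observed near-equivalence of those two regimes — while every
structural property (flux conservation within 2%, the exact infinite-line
closed form, monotone decay, the very-stable > stable > neutral ordering
at 100 m) continues to hold, as the property suite asserts.

### Numerical integration

$\chi$ is an adaptive midpoint sum over link elements. The initial element
count is chosen so the spacing does not exceed the receptor's distance to
the link (coarser spacings can alias the narrow crosswind Gaussian and
stall the refinement at a spurious zero), and the count doubles until two
consecutive refinements agree within a relative tolerance of $10^{-3}$.
The test suite checks 20 randomised link/receptor/meteorology
configurations against an independent 10,000-element brute-force sum
written separately in R, requiring agreement within 0.5%. Elements with
downwind distance below $x_{min} = 1$ m contribute only to the meander
term; a receptor within $x_{min}$ of the link centreline is an error
(receptor-on-road is undefined). The source height is 1 m and the default
receptor height 1.5 m (breathing height).

### Validity, completeness and exposure summaries

An hour is usable when the meteorology record is complete and wind speed
is at least 0.5 m/s (inclusive); other hours are masked — never
zero-filled — and excluded from all summaries. Day-period exposure cells
(the five modelled periods: off-peak 00–06, AM peak 07–08, midday 09–15,
PM peak 16–18, off-peak 19–23, plus a 24-h daily cell) are reported only
when at least 75% (inclusive) of the cell's hours are valid.

Receptors classify as HTHD (within 300 m of a high-traffic high-diesel
link), HTLD (within 300 m of a high-traffic low-diesel link) or LT,
with the high-diesel label taking precedence when both are in range and
high traffic meaning AADT ≥ 50,000 vehicles/day. 300 m is the
classification radius; 150 m is recorded as an additional proximity flag
only. Cohort statistics pool valid hourly values across each cohort's
receptors (an alternative — summarising per receptor first — gives the
same orderings on the synthetic scenario but different absolute spreads).

Effective distance divides the perpendicular road distance by the cosine
of the angle between the hourly transport direction and the road normal
toward the receptor. Hours with cosine at or below 0.1 count as upwind:
they are flagged and excluded from per-receptor mean effective distances
(capping the ratio at 10 also keeps near-parallel hours finite).

### Measurement-driven adjustments

`compare_aadt()` reports the percent difference of modelled versus
measured AADT at traffic-recorder links. `rescale_aadt()` multiplies all
interstate AADT by a factor (default 0.8) and adds the removed
vehicle-miles travelled back onto the freeway links as a uniform AADT
increment per metre of freeway length — this makes VMT conservation exact
by construction for any AADT pattern, which is the stated intent of the
length-ratio redistribution; conservation is asserted at machine
precision. The factor is applied uniformly to all interstates (a per-link
correction would require a recorder on every link). `reassign_diesel()`
equates the measured commercial share CAADT/AADT to a diesel share — an
approximation, since commercial vehicles are not exactly the diesel fleet
— and moves each measured link to the catalog mix with the nearest diesel
percentage (ties keep the original), updating its HD/LD group; it never
touches AADT, and the rescale never touches mixes. `relabel_cohorts()`
then reruns classification, keeping receptors that moved HTHD→HTLD under
a dedicated "HD to LD" label for reporting.

## The synthetic scenario

The generators produce every input the pipeline needs, deterministic per
seed. The default scenario is sized to run the full pipeline comfortably
on one core (about 15 s for the dispersion step): 90 days of hourly
meteorology starting 1 August, 21 links, 30 receptors, three pollutants.

* **Network** — two structurally identical neighborhoods 30 km apart
  east-west: a 12 km interstate corridor (NFC 11, six segments, AADT
  drawn 70–110k, speeds 45–60 mph by period) and a freeway corridor
  (NFC 12) carrying *the same* drawn AADT values, so the corridors differ
  only in fleet mix; each neighborhood has three north–south arterials
  (NFC 14/16, AADT 8–18k) and a local street (NFC 17). The east–west
  separation is crosswind to the prevailing flow, so neither cohort sits
  systematically downwind of the other neighborhood — mirroring a real
  study design where cohorts live near different roadways spread across a
  metro area and each is dominated by its own corridor. (With the
  corridors stacked along the wind instead, the downwind cohort inherits
  the other corridor's far field — a steady-state line source above the
  lid dilutes crosswind only — and the traffic-marker comparison between
  cohorts becomes an artifact of the toy geometry.)
* **Participants** — ten per cohort at fixed perpendicular distances
  25–290 m, alternating sides of each corridor, with identical offsets in
  both neighborhoods; ten low-traffic receptors 2.8–3.3 km north near the
  arterial band. Construction guarantees the classifier reproduces the
  intended cohorts exactly.
* **Meteorology** — a diurnal stability cycle (stable pre-dawn, very
  stable 05–08 lasting through the morning rush, convective 09–16,
  neutral evening), each hour jittered multiplicatively (15%) around the
  packaged representative regime rows and clamped to its regime's
  stability band; wind directions normal around 315° (northwest) with
  45° spread; 4% calm hours (u < 0.5 m/s) and 2% incomplete records.
  Zero jitter reproduces the representative rows verbatim.
* **Emission factors** — a diesel marker (`pm25_like`, class contrast
  0.3 vs 0.01 g/veh/mi), an intermediate (`nox_like`, 2.0 vs 0.2) and a
  traffic marker (`co_like`, identical for all classes, so fleet
  composition cancels exactly); a U-shaped speed curve (highest at
  2.5 mph, minimum near 45), mild temperature decrease and a weak
  seasonal cycle. Magnitudes are arbitrary; only the contrast structure
  matters.
* **Traffic recorders** — one per corridor link; measured AADT embodies a
  +20% model overestimate on interstates (s.d. 5%) and none on freeways;
  measured commercial shares alternate 9%/5% on interstates and sit at 5%
  on freeways, so some interstate stretches measure freeway-like diesel.

What the synthetic data do *not* emulate: real street-network geometry,
signal-driven congestion and hourly traffic events, spatially varying
meteorology, background and non-road sources, and pollutant chemistry.
Passing the end-to-end tests therefore demonstrates that the method
recovers designed contrasts under its own assumptions — not that those
assumptions hold in any particular city.

## Known limitations

Primary, inert pollutants only (no chemistry, so no NO₂); flat, at-grade
roadways without noise barriers or depressions; one meteorological
station applied to the whole domain; a steady-state kernel whose
well-mixed far field does not decay downwind for an infinite line, so
distant large sources contribute a background-like floor; commercial
traffic equated to diesel traffic in the adjustment step; and no
estimation of traffic on links without recorders.
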