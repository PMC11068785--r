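---
title: "SiTHv2 in R: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SiTHv2 in R: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sithv2)
```

## The model in brief

`sithv2` simulates the daily water pathway through the
groundwater–soil–plant–atmosphere continuum at a point (or independently at
every cell of a grid). Total evapotranspiration is partitioned as

$$ET = E_i + E_s + T_r,$$

where $E_i$ is evaporation of canopy-intercepted rainfall, $E_s$ bare-soil
evaporation and $T_r$ plant transpiration. Each component is a potential
(energy-driven) flux scaled down by multiplicative, dimensionless stress
constraints:

$$E_i = f_{wet}\,E_{pc}, \qquad E_s = f_{sm}\,E_{ps}, \qquad
T_r = f_v\, f_t \left[\sum_{i=1}^{3} f_{smv,i}\, T_{ps,i}
 + \sum_{i=1}^{3} T_{pg,i}\right].$$

Potentials come from the Priestley–Taylor equation applied separately to the
soil- and canopy-allocated parts of net radiation; a Beer-law extinction
$R_{ns} = e^{-k_{Rn}\,LAI} R_n$ splits the two, so canopy and soil energy
close exactly by construction. Potential transpiration is the canopy
potential left after interception, $T_p = (1-f_{wet})E_{pc}$, distributed
over three soil layers by root density and relative wetness and split, per
layer, between the unsaturated zone (subject to the per-layer moisture
stress $f_{smv,i}$) and the saturated zone below the groundwater table
(exempt from that stress — roots in saturated soil are not water-limited).

The prognostic state is the soil moisture of the three layers (default
bottoms at 5, 50 and 300 cm; the first is fixed by the product definition,
the others configurable) plus the groundwater table depth. A bucket scheme
advances the state: throughfall infiltrates the surface layer, saturation
excess runs off instantly, water above field capacity drains downward at a
rate capped by the saturated hydraulic conductivity, and drainage out of the
deepest layer recharges the groundwater, whose table moves through a
specific yield.

## Stress constraints

* **Canopy wetness** $f_{wet}$: canopy storage is $S_c = P \cdot LAI$ and a
  fraction $\chi = 0.7$ of it can evaporate during daytime. The printed
  wetness definition divides by the very transpiration it modulates, which
  is circular; we close the loop by evaluating wetness against the canopy
  potential, giving the explicit form $E_i = \min(\chi S_c, E_{pc})$. We
  additionally cap $E_i$ at the day's precipitation — interception cannot
  exceed rainfall — which the min-form alone does not guarantee when
  $\chi \cdot LAI > 1$. The wetness fraction is then recovered as
  $f_{wet} = E_i / E_{pc}$ so the identity $E_i = f_{wet} E_{pc}$ is exact.
* **Soil evaporation** $f_{sm}$: linear ramp of surface-layer moisture
  between wilting point and field capacity.
* **Temperature** $f_t = \exp\{-[(T_a - T_{opt})/T_{opt}]^2\}$. The optimum
  $T_{opt}$ is a site trait: the air temperature on the climatology day
  where $LAI \cdot R_n \cdot T_a$ peaks, computed once and held fixed. The
  form is undefined for $T_{opt} \le 0\,^\circ$C; such configurations are
  rejected as errors rather than silently patched.
* **Vegetation water content** $f_v = \sqrt{VOD/VOD_{max}}$, with
  $VOD_{max}$ the per-site maximum over the full record (a per-calendar-year
  maximum is a documented alternative reading; values above the reference
  clamp at 1).
* **Per-layer transpiration stress** $f_{smv,i}$ uses a *dynamic* critical
  moisture $\theta_c$: with $k = \sqrt{H_c}$ and the height-adjusted wilting
  point $\theta_{wp}^h = \theta_{wp}/k$,
  $$p = \frac{1}{1+E_p} - \frac{w}{1+H_c}, \qquad
    \theta_c = (1-p)(\theta_{fc} - \theta_{wp}^h) + \theta_{wp}^h,$$
  clamped into $[\theta_{wp}^h, \theta_{fc}]$. Higher evaporative demand
  lowers $p$ and therefore *raises* $\theta_c$ — plants become water-limited
  earlier on high-demand days — while taller canopies (larger $H_c$,
  deeper-reaching, better-buffered plants) lower the effective wilting
  point. $E_p$ (the day's $E_{ps} + E_{pc}$ in mm d$^{-1}$) enters
  $1/(1+E_p)$ dimensionlessly, as printed. A canopy-height floor of 0.1 m
  protects $\theta_{wp}/\sqrt{H_c}$ from the singularity at zero height.

## Root profile and the saturated split

Root density follows the linear dose–response profile: the cumulative
fraction above depth $z$ is $F(z) = 1/(1+(z/D_{50})^c)$ with $c < 0$ chosen
so that $F(D_{50}) = 0.5$ and $F(D_{95}) = 0.95$, i.e.
$c = \log_{10}(1/19)/\log_{10}(D_{95}/D_{50})$. Layer fractions are
differences of $F$ at the layer bottoms; mass below the deepest layer is
ignored (the allocation renormalizes over the three layers anyway).
Allocation weights are $r_i(\bar\theta_i/\theta_s)^b$, where $\bar\theta_i$
is the thickness-weighted mean of the prognostic moisture over the
unsaturated part of the layer and $\theta_s$ over the submerged part — the
only reading consistent with the saturated/unsaturated weighting used for
the split itself. The split of each layer's demand is proportional to
$(z_{gw} - z_{top})\theta_i$ versus $(z_{bot} - z_{gw})\theta_s$, is exactly
complementary, and is continuous in $z_{gw}$ at both layer boundaries.

All depths are positive downward in cm. Saturated-zone transpiration is
charged to groundwater, not to layer storage; consequently the *reported*
per-day recharge is net (gravity drainage minus saturated uptake), which
makes the daily budget
$P - (ET + Q + R_{net} + \Delta S_{soil})$ close to rounding error
($\lesssim 10^{-13}$ mm per step). A residual above $10^{-6}$ mm is treated
as an internal bug and fails hard.

## Within-day ordering and extraction clipping

The scheme is explicit: every flux of day $t$ is evaluated from the
beginning-of-day state — interception first, then evaporation/transpiration
demand on beginning-of-day moisture, then infiltration and drainage, then
the groundwater update. If demanded extraction exceeds the water available
above a residual floor (0.01 m$^3$ m$^{-3}$), the layer's fluxes are scaled
down proportionally and ET recomputed, keeping the ET identity exact and
storage non-negative. The stress functions already drive demand to zero
near the wilting point, so clipping binds rarely.

The exact infiltration/runoff formulation of the original model code is not
restated in the product description; the bucket scheme here (instant
saturation-excess runoff, free drainage above field capacity capped by
$k_{sat}$ and by the receiving layer's remaining capacity) is this package's
own documented choice and is the component most likely to differ from the
original implementation.

## Tunable parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `alpha` | Priestley–Taylor coefficient | – | 1.26 |
| `gamma` | psychrometric constant | kPa °C⁻¹ | 0.066 (pressure-adjusted form behind `pressure_gamma`) |
| `chi` | daytime interception fraction | – | 0.7 |
| `k_rn` | canopy radiation extinction | – | 0.6 |
| `w` | canopy-height weight on θ_c | – | 0.1 |
| `h_c_min` | canopy height floor | m | 0.1 |
| `g_fraction` | ground heat flux as share of R_ns | – | 0 (daily G ≈ 0) |
| `specific_yield` | aquifer specific yield | – | 0.05 |
| `z_gw_max` | water-table depth cap | cm | 3000 |
| `theta_residual` | extraction floor | m³ m⁻³ | 0.01 |

The slope of the saturation vapour-pressure curve uses the FAO-56 closed
form and the latent heat of vaporization the Harrison linear form; the
model description prescribes neither, and these are the community-standard
choices. Negative available energy clamps potentials at zero — the model
has no dew pathway. Soil hydraulics per texture class and canopy
height/rooting depths per plant functional type ship as editable CSV tables
under `inst/extdata/`; they are repository-supplied class means in the
Clapp–Hornberger/Cosby tradition, *not* values prescribed by the model
description, which tabulates neither.

## Synthetic forcing: what it emulates, and what it does not

`generate_forcing()` produces seed-deterministic daily series on a 365-day
no-leap calendar (leap-day branching removed from all model tests):
temperature, shortwave radiation and LAI follow annual sinusoids with
regime-specific means and amplitudes (LAI lags temperature by 30 days);
precipitation is independent Bernoulli wet-day occurrence times an
exponential depth — the simplest structure that exercises both wet- and
dry-day branches of the constraint functions; wet days are cloudier (lower
direct-beam fraction, reduced shortwave, moister longwave emission); VOD is
$VOD_{max}\sqrt{LAI/LAI_{max}}$ plus small noise, floored at zero, which
guarantees $f_v$ spans $(0,1]$ over a year. Three built-in regimes (arid,
temperate, humid-tropical) provide contrasting wetness and seasonality;
their parameters are round numbers a hydrologist would call typical for
each climate (e.g. temperate: mean 10 °C, amplitude 12 °C, wet-day
probability 0.35, mean depth 5 mm ⇒ ≈ 640 mm yr⁻¹).

What the generator does *not* emulate: persistence (no wet/dry spells
beyond independence), sub-daily structure, interannual variability in the
seasonal cycles, snow, or covariance structures of real reanalysis data.
Passing tests therefore demonstrate internal consistency, conservation and
the model's limiting behaviours — not skill against observations, which
requires the real multi-decade forcing archives that are outside this
package's scope.

Grid fixtures derive a per-cell sub-seed deterministically from the master
seed and cell index, so cells are independent realizations and any
execution order (serial, forked workers) gives bit-identical cubes.

## Spin-up and numerical conventions

Spin-up repeats one forcing year (by default the first available year —
the simplest reproducible choice; a climatological mean year can be
supplied instead) from an initial state of field capacity with the water
table at the bottom of layer 3, and tracks the maximum year-over-year
change of layer moisture. The production default is 100 cycles; the test
suite measures convergence with 25–100 cycles and verifies that two
distant initial states are contracted to nearly the same equilibrium, which
is what makes the choice of initial state irrelevant.

Problem sizes in the shipped tests are chosen to probe the properties at
full strength while remaining desk-scale: 10,000 randomized single steps
and 27 (3 regimes × 3 textures × 3 PFTs) 39-year point runs for
conservation; $10^5$ random water-table draws for the saturated split;
5×5-cell, 2-year cubes for grid determinism.

## Product I/O

Outputs are stored as 16-bit short integers with two decimal places:
`stored = round(value × 100)`. The published rescaling rule is
`value = stored × scale_factor⁻¹` with attribute `scale_factor = 100` —
note this *inverts* the CF convention (CF: `value = stored ×
scale_factor`). The writer follows the reciprocal rule by default and
records a `packing` attribute naming the convention; `cf = TRUE` writes a
CF-compliant file (`scale_factor = 0.01`) instead, so CF tooling is not
silently trapped. Filenames follow `SiTH.v2.<VV>.<XXXX>.<YYYY>.nc` and
parse back losslessly. Files are NetCDF-3 classic, written and read by a
small built-in backend (`nc3_write()`/`nc3_read()`); the test suite
cross-checks it in both directions against SciPy's independent
implementation of the same format. Coordinates are cell centers, latitude
descending north→south, longitude −180→180 — fixed here for reproducible
grids because the product description does not state them.

Preprocessing contracts: bilinear regridding (nearest-edge policy outside
the source hull, with a warning) reproduces constants, nodal values and
bilinear fields exactly; temporal gap-filling uses a cubic spline with
Forsythe–Malcolm–Moler end conditions — chosen over a natural spline
because FMM reproduces cubic polynomials exactly — with non-negative
variables floored at zero and a linear fallback below 4 knots.

## Evaluation tools

`fit_metrics()` implements Pearson $r$, RMSE, Nash–Sutcliffe efficiency and
the OLS regression of simulation on observation, with pairwise deletion of
missing data; a constant observation series makes NSE undefined and it is
reported as missing, never as zero. `water_balance_et()` is the basin
residual $P - Q - \Delta S$. Annual trends pair an OLS slope (the trend
value) with the distribution-free Mann–Kendall test — the trend estimator
is not named where the trends are reported, so OLS is the default and
Sen's slope is reported alongside. The Mann–Kendall statistic uses the
tie-corrected variance and continuity correction, with the exact
permutation distribution for $n \le 10$ untied values; it is verified
against exhaustive pair counting and against Kendall's tau of the series
versus time.

## Known limitations

* No soil freeze–thaw physics: winter soil moisture in cold climates is
  liquid-equivalent and unrealistic where frost dominates.
* No lateral flow, irrigation, hydraulic redistribution or dynamic root
  growth; cells are fully independent.
* The infiltration/runoff bucket is a documented stand-in for the original
  code's scheme (see above).
* Layers lying below the water table keep their prognostic moisture value;
  the table depth enters through the allocation and split only, so a
  rapidly rising table does not instantaneously saturate layer storage.
* Soil/PFT parameter tables are class-mean defaults; site applications
  should override them.
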