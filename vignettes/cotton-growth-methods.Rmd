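---
title: "Methods: relative logistic cotton growth models and irrigation response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relative logistic cotton growth models and irrigation response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotgrow)
```

## The modelling problem

Cotton growth indices — plant height H (cm), leaf area index LAI, and
above-ground dry matter D (g/plant) — follow similar seasonal trajectories
across regions once two normalisations are applied: the index is divided by
its theoretical seasonal maximum, and calendar time is replaced by a
*relative season driver* on [0, 1]. `cotgrow` supports two drivers:

* **R_CGDD** — cumulative growing degree days divided by the season total.
  Daily GDD is the mean of the daily extremes, clamped into the cotton
  activity window (base 10 °C, upper limit 40 °C), minus the base.
* **R_CETo** — cumulative FAO-56 Penman–Monteith reference
  evapotranspiration divided by its season total. ET₀ integrates
  temperature, net radiation, vapor pressure deficit and wind, so this
  clock responds to the full meteorological environment rather than
  temperature alone.

On either clock the relative indices follow logistic curves with a
polynomial exponent:

$$R(x) = \frac{1}{1 + e^{a + b x}} \quad (H, D; \; b < 0), \qquad
  R(x) = \frac{1}{1 + e^{a + b x + c x^2}} \quad (LAI; \; c > 0).$$

The quadratic exponent lets LAI rise and then fall within the season; its
maximum sits at $x^\* = -b/(2c)$ (`peak_driver()`). We keep the exponent in
the $a + bx$ sign convention (growth curves have negative slope) rather
than re-parameterising to the textbook midpoint/steepness form, so the
published regional coefficient tables drop in verbatim
(`cotton_region_params()`).

### Assumptions

* Both cumulative drivers are nondecreasing within the season, so the
  relative driver is a valid monotone re-clocking of time.
* The relative transformation removes most regional differences in absolute
  magnitude (irrigation method, soil fertility, variety); what remains is a
  common shape.
* The season window is the extent of the supplied weather table; the caller
  is responsible for aligning it with sowing and harvest.

## Driver computation details

Auxiliary FAO-56 terms not fixed by the Penman–Monteith equation itself use
the standard daily formulations: Tetens saturation vapor pressure,
$\Delta = 4098\,e^0(T)/(T+237.3)^2$, $\gamma = 0.000665\,P$, saturation
pressure averaged over the daily extremes, actual vapor pressure from
relative humidity when not supplied directly, soil heat flux G = 0 for
daily steps, and P = 101.3 kPa unless an elevation column is present.

Two numerical choices matter:

* **Clamping order for GDD.** Only the daily *mean* is clamped into
  [10, 40] °C; the extremes are never clamped individually. A day at
  (8, 4) °C contributes 0; a day at (48, 40) °C contributes the ceiling
  30 °C·d.
* **Negative daily ET₀.** The Penman–Monteith value can be negative when
  soil heat flux exceeds net radiation with no vapor deficit. Such days are
  clamped to zero *before accumulation* so CET₀ is monotone — required for
  the relative driver to be a valid clock — while `daily_eto` keeps the raw
  value for inspection.

## Fitting

`fit_growth()` minimises least squares on the original scale with
Levenberg–Marquardt (`minpack.lm::nlsLM`, iteration cap 200, relative
tolerances 1e−12). Start values come from ordinary least squares on the
logit transform $\ln(1/y - 1)$, which is linear (or quadratic) in $x$;
observations at exactly 0 or 1 are nudged inward by 1e−6 for the
initialiser only. With this two-stage scheme, noise-free data are recovered
to better than 1e−6 in every coefficient, and the fit is invariant to
observation order up to solver tolerance (~1e−9 relative). Fit quality is
reported as the squared Pearson correlation, the RMSE, and a
sum-of-squares relative error in percent (error sum of squares over
measured sum of squares).

## Converting between driver bases

Within a region the two relative drivers are very nearly affinely related,
$R_{CETo} = m R_{CGDD} + n$ with $m > 0$. Substituting the link into the
exponent gives exact conversion formulas (`convert_params()`); converting
and then converting back restores the coefficients to machine precision.
A cubic link form is also evaluated (`eval_cubic_link()`) but deliberately
not fitted or used for conversion: its composition with the quadratic LAI
exponent is unwieldy and the linear link already achieves R² > 0.97 on
simulated seasons.

Per-region links were not published; `region_links()` back-solves them from
the published coefficient pairs. For linear-exponent pairs the solution is
exact and unique. A quadratic pair *overdetermines* (m, n): we take
$m = \sqrt{c/f}$ and solve $n$ from the slope equation, which reproduces
the published slope and curvature exactly but not necessarily the published
intercept — the published quadratic intercepts carry independent rounding
(one region is substantially inconsistent under any (m, n)), a known
limitation of round-tripping printed 3–4 significant-figure tables. For the
same reason, recomputed fitted-vs-calculated deviations
(`param_deviation()`) agree with the published deviation columns to about
5e−4 rather than exactly.

## Yield, irrigation and water use efficiency

The yield and leaf-area responses are concave quadratics fitted (in the
source analyses) to category means — LAI_max binned 2–3 … 8–9 and
irrigation binned 400–450 … 650–700 mm. `bin_average()` reproduces that
preprocessing with half-open [lo, hi) bins, the final bin closed; a value
on an interior boundary joins the upper bin. This convention is a package
decision — any deterministic convention works, but one must be fixed.

The optimisation chain is closed-form: the yield vertex gives the optimal
LAI_max (6.043) and maximum yield (7171.7 kg/ha); solving the irrigation
response for that leaf area has two roots, and the *ascending* (smaller)
root is the default — it is the water-economical solution, and it is the
one the source chain reports (518.793 mm, below the response vertex at
573.541 mm). Following that chain, `yield_summary()` and the acceptance
script hand the 3-decimal LAI_max (6.043) to the root solve; using the
unrounded vertex instead shifts the required irrigation to ≈518.82 mm.
A target above the response's vertex value has no real root and errors; a
discriminant within −1e−9 of zero (a target numerically at the vertex) is
clamped to zero rather than rejected.

Two IWUE variants are deliberately exposed:

* `as_printed` evaluates the published quartic-over-W expression with its
  five coefficients verbatim, giving 21.153 kg/(ha·mm) at 518.793 mm.
* `composed` evaluates $Y(L(W))/W$ exactly, giving 13.824 kg/(ha·mm) at
  the same point.

The discrepancy traces to a single printed coefficient: the exact W³ term
of the composition is 1.4728e−3 but is printed as 0.0015, and at W ≈ 519 mm
that rounding is worth ≈ 7 kg/(ha·mm) after division by W. Neither variant
is "corrected" into the other: `as_printed` is the reproduction default,
`composed` the internally consistent one, and results should state which
was used. Relatedly, the published pairing of the irrigation-response
vertex (573.541 mm) with a leaf area of 4.938 is not reproducible from the
printed coefficients, whose vertex value is ≈ 6.438; we treat 4.938 as an
erratum and report the coefficient-implied value.

## What the simulator emulates — and what it does not

`simulate_weather()` produces one April–October season: daily mean
temperature as an annual sinusoid (peak mid-July) plus AR(1) noise
(lag-1 correlation 0.6, sd 1.5 °C — synoptic persistence, a fixture choice),
split into max/min by a fixed diurnal range; net radiation as a seasonal
sinusoid with white noise floored at 0; humidity as profile mean plus noise;
wind log-normal. Two profiles set the regional contrast:

| parameter | arid-continental | warm-temperate-monsoon |
|---|---|---|
| mean annual T (°C) | 10 | 13 |
| seasonal half-amplitude (°C) | 15 | 14 |
| diurnal range (°C) | 14 | 10 |
| net radiation mean ± amp (MJ/m²/d) | 12 ± 5 | 11 ± 5 |
| mean RH (%) | 45 | 70 |
| mean wind at 2 m (m/s) | 2.2 | 1.8 |

These values were chosen once so that an arid season accumulates a
realistic 1400–2000 °C·d of thermal time (interior-basin cotton seasons
peak around 1600–1800 °C·d) with seasonal ET₀ of roughly 900–1100 mm, and
the monsoon profile differs in the humidity-driven direction. The simulator
deliberately omits precipitation (none of the models consume it), cloud
cover structure, heat waves, and any calibration to a specific station; it
is a fixture generator, not a WGEN-class stochastic weather model.
Consequently, passing pipeline tests show that the *machinery* (drivers →
normalisation → fitting → link conversion) is self-consistent under the
models' own assumptions — they do not validate the biological coefficients
against new field data.

`simulate_growth()` adds Gaussian noise to a true curve, truncated into the
open unit interval — the simplest structure consistent with scatter about a
relative growth curve — and requires the driver values to span at least 0.8
of [0, 1] so the sigmoid is identified.

## Problem sizes and runtime

The test suite works at deliberately small scales: single simulated seasons
(≈ 184 days), 20–60 observation fits, 100-point identity checks, a 10⁵-point
grid for the peak-location oracle and a 10⁶-point grid for the yield-vertex
oracle. The full suite runs in a few seconds on one core; the acceptance
script is closed-form and effectively instantaneous.

## Known limitations

* Coefficient presets are printed-precision constants; derived quantities
  inherit that rounding (see the link back-solving discussion above).
* Extrapolation of the growth curves outside [0, 1] is permitted but
  warned about; the curves have no biological meaning there.
* The driver link is assumed constant within a season and shared across
  indices within a region.
* Crop-coefficient (Kc) adjustment to actual crop evapotranspiration,
  hourly ET₀, and radiation estimation from sunshine hours are out of
  scope: the weather table must supply net radiation directly.
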