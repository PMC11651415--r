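---
title: "Pod-area-aware growth simulation and calibration for oilseed rape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pod-area-aware growth simulation and calibration for oilseed rape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpaicrop)
```

## The problem

Winter oilseed rape (*Brassica napus*) is unusual among field crops in that
its photosynthetic canopy changes identity mid-season.  From emergence to
flowering the leaves do essentially all the light interception; after
flowering the siliques (seed pods) expand rapidly, keep their walls green,
and take over much of the carbon supply for seed filling while the leaves
senesce.  A crop simulation calibrated only against the leaf area index
(LAI) therefore starves the simulated crop of its late-season carbon source
and systematically under-predicts storage-organ yield (TWSO) and
above-ground biomass (TAGP).

`tpaicrop` implements a daily process-based growth engine in which pod area
participates in light interception, plus the calibration machinery to
exploit it.  The central quantity is the **total photosynthetic area
index**

$$\mathrm{TPAI} = \mathrm{LAI} + \mathrm{PAI},$$

where the pod area index is tied to storage-organ dry mass through the
**specific pod area** (SPA, ha kg^-1^): $\mathrm{PAI} = \mathrm{SPA}\cdot
W_{so}$ once the crop passes flowering (development stage DVS $\ge$ 1).

On the observation side, field measurements reach the same quantity
through the organ-geometry regressions: single leaves are treated as
ellipses ($A = \pi/4\,l\,w$), siliques as cylinders ($A = \pi d l$; a
prolate-spheroid alternative is provided, which for elongated pods gives
$\pi/4$ of the cylinder value), and aggregated organ area maps to an
optical area index through the linear fit index $= 0.005\,S + 1.318$, used
for leaves and reused for silique area.  Before silique emergence the
silique area index is 0 by definition, whatever the regression intercept
says at zero area.

## The growth engine

The engine is a re-implementation of the potential-production core of the
WOFOST family, chosen so the whole toolkit runs on a desk with no external
model installation:

* **Phenology.** Effective temperature $\max(0, T_{mean} - T_{base})$
  accumulates; DVS runs 0 → 1 over TSUM1 degree-days (emergence to
  flowering) and 1 → 2 over TSUM2 (flowering to maturity).  Emergence
  itself needs TSUMEM degree-days above TBASEM from sowing.
* **Assimilation.** Daily gross CO~2~ assimilation integrates a
  negative-exponential leaf light response (asymptote AMAXTB, modulated by
  TMPFTB; initial slope EFFTB) over canopy depth and over the daylight
  period with three-point Gaussian quadrature.  Light attenuates over the
  *total* photosynthetic area (TPAI) with extinction KDIFTB — this is the
  package's central mechanism; a flag restricts interception to LAI to
  reproduce the traditional leaf-only model.  Radiation comes from
  sunshine duration through the Angström–Prescott relation
  ($a = 0.25$, $b = 0.50$, both configurable).
* **Respiration and growth.** Maintenance respiration is
  $\sum_x RM_x W_x$ scaled by $Q_{10}^{(T-25)/10}$ with $Q_{10} = 2$,
  capped at gross assimilation.  Net assimilate is split by the
  DVS-indexed partition tables (roots first via FRTB, then leaves, stems
  and storage organs via FLTB/FSTB/FOTB, which must sum to 1 at every
  breakpoint) and converted with per-organ efficiencies CVL/CVS/CVO/CVR,
  so the daily carbon ledger closes identically:
  gross − maintenance = $\sum_x \Delta W_x / CV_x$.
* **Leaves.** New leaf mass enters daily cohorts whose area is mass ×
  specific leaf area (SLATB); cohorts age by
  $(T_{mean}-T_{base})/(35-T_{base})$ physiological days and die past the
  life span SPAN, moving to a dead pool.  During the juvenile phase
  (DVS < 0.3) area growth is exponential at rate RGRLAI per degree-day,
  capped by the assimilate supply.
* **Water.** A one-layer bucket (initial content WAV, capacity SOIL_CAP)
  gains rain and loses a Hargreaves-type reference evaporation split by
  canopy cover; the stress factor is 1 above half capacity and declines
  linearly to 0.  Potential-production mode — used throughout the test
  suite — ignores the stress factor but still keeps the water ledger,
  which also closes exactly.

All DVS- or temperature-indexed parameters are piecewise-linear breakpoint
tables (`afgen`), clamped outside their range, exactly as the model
family's crop files define them.

Default parameter values use the published single-point rape calibration
means where available (TSUM1 = 701 °C d, TSUM2 = 737 °C d, TDWI = 8.9
kg ha^-1^, SPA = 6.5 × 10^-4^ ha kg^-1^, SPAN = 37.4 d, the four
conversion efficiencies, the eight-stage partition tables, WAV = 42 cm).
The partition means at DVS 0.7 print as 0.34/0.01/0.66, which sums to
1.01; the constructor renormalizes every triplet onto the simplex.  The
remaining engine parameters (emergence sums, LAIEM = 0.25, RGRLAI = 0.012,
light-response and respiration coefficients, the declining root-fraction
table) are standard winter-rape-scale choices fixed once so that the
default crop develops a realistic canopy (peak LAI ≈ 3, peak TPAI ≈ 4–5)
and yield (TWSO ≈ 2.7–2.9 t ha^-1^, TAGP ≈ 8–9 t ha^-1^, harvest index ≈
0.33) under the regional weather statistics.  Because the engine has no
vernalization or photoperiod response, the simulated season compresses
into roughly 120–130 days; all internal consistency results are unaffected
by this, but simulated calendar dates should not be read as real-world
phenology.

## Calibration methods

`calibrate_crop()` fits parameters to a five-stage observation campaign
(seedling, budding, flowering, milky, maturity) and returns a classed
model object with `print`, `summary`, `coef`, `predict`, `fitted`,
`residuals` and `plot` methods.

All three methods first recover TSUM1/TSUM2 from the stage calendar: the
effective temperature accumulated from emergence to the flowering date and
from flowering to the harvest date.  The stage calendar only brackets each
crossing within one day, so the estimate is centred half a day into the
crossing day — without the centring the simulated crop sits exactly on the
DVS = 1 boundary at the flowering visit, where the discontinuous pod-area
onset makes objectives jumpy.  Estimates outside the published ranges are
clamped with a warning.

* **`"lai"` (baseline).** Bounded least squares of the free parameters
  against the LAI observations only, engine in leaf-only interception
  mode.  This is the traditional protocol, retained as the control: on
  pod-bearing synthetic truth it under-predicts TWSO.
* **`"tpai-spa"`.** After phenology, a line search on SPA starting from
  the preset 0.007 (kept verbatim although it exceeds the single-point
  maximum of 9 × 10^-4^; the search is clamped to the documented
  (0, 0.01] range) in steps of 5 × 10^-4^, stepping in the direction that
  reduces the TPAI misfit at pod-bearing stages until it stops improving;
  then bounded least squares of the free set against the TPAI
  observations.  The refinement objective also carries the stage TWSO and
  TAGP residuals (as relative errors scaled to TPAI units): the field
  protocol adjusts the allocation and conversion parameters against
  measured yields, and without that information SPA and storage mass are
  only identified through their product.
* **`"tpai-curve"`.** After phenology, the free set (less SPA) is fitted
  to the LAI observations; the resulting simulated LAI curve provides the
  first anchor (its peak, earliest day on ties), the highest later TPAI
  observation the second, and the final pre-harvest observation the
  third.  The unique quadratic through the three anchors, sampled daily
  and clamped at zero, is the TPAI calibration curve; a final bounded
  least squares (free set plus TSUM1/TSUM2) matches the simulated TPAI to
  it day by day, together with the pre-peak LAI residuals and the
  weighted stage-yield residuals.  The first anchor takes the simulated
  *TPAI* value at the LAI peak: identical to the LAI value whenever pods
  are still absent there (the construction's premise), and still a
  matchable anchor when the simulated LAI peaks after pod emergence.  If
  the peak falls so late that no middle anchor remains, the anchor falls
  back to the latest earlier observation that leaves one.

The default free set is the sensitivity-informed list KDIFTB2.00,
EFFTB0.00, SPA, FSTB1.70, CVO, EFFTB40.00 and SLATB0.00; bounds come from
the published single-point ranges where a symbol has one, otherwise from
the generic model-documentation ranges.  Setting one member of a
partition triplet renormalizes the other two onto the simplex.  The
optimizer is `stats::optim` (L-BFGS-B) on unit-box-scaled parameters;
`control = list(maxit, factr, ndeps, spa_preset, spa_step)` exposes its
budget.  The defaults (maxit = 20, factr = 10^12^) favour speed; the
twin-experiment convergence demonstrations use maxit = 300, factr = 10^6^.

## Sensitivity analysis

`generate_design()`/`compute_indices()` implement the classic extended
FAST estimator: each parameter in turn carries the maximum search-curve
frequency $\omega_{max} = \lfloor (n-1)/2M \rfloor$ (harmonics $M = 4$)
while the others oscillate at low complementary frequencies; first-order
indices come from the spectral power at $\omega_{max}$ and its harmonics,
total indices from one minus the low-frequency share.  The sample count
per parameter must exceed 65 times the number of parameters, and the run
count is $n \times p$.  On closed-form test cases the estimator matches
analytic indices to ±0.02 at $n = 2000$ (additive two-parameter model:
0.2/0.8; Ishigami with $a=7$, $b=0.1$: 0.3139/0.4424/0).

The dry-matter partition coefficients cannot be varied independently.
`apply_partition_constraint()` reproduces the sequential-conditional
scheme: per row, the leaf fraction is rescaled to [0, 1], the stem
fraction to [0, 1 − FL], and the storage-organ fraction set to the
remainder, so every row sums to exactly 1 with all coordinates
non-negative.  This conditional construction is deliberately *not*
replaced by a symmetric Dirichlet draw, and the overwrite destroys the
pure search-curve structure of those columns, so their indices are
flagged `approximate` in the result.

One empirical caveat: in this engine's potential-production mode with
±10% parameter ranges, SPA's total-order index for final TWSO is small
(TSUM1 and the conversion efficiencies dominate), because pod-area
feedback acts only over the DVS 1–1.5 storage-filling window and the
partition tables stop yield accumulation at DVS 1.5.  The strong SPA
sensitivity reported for field conditions is not reproduced at this scale;
the test suite asserts the ordering that is robust here (phenology and
conversion on top, SPA above the leaf life span).

## Synthetic data

The generators make every result in this package reproducible from a seed
with no external data:

* `generate_weather()` draws a daily season (default 2020-10-01 to
  2021-05-31 at the Hengyang coordinates) with sinusoidal seasonal
  temperature (half-amplitude 6 °C, coldest mid-January, centred so the
  window means equal the regional means: tmin 9.87 °C, tmax 16.89 °C),
  AR(1) day-to-day noise, Bernoulli-gamma precipitation recentred to the
  1.92 mm d^-1^ mean, truncated-normal sunshine (3.08 h), and
  near-constant vapour pressure and wind.  It emulates the regional
  seasonal *statistics* only: no weather fronts, no multi-day wet spells,
  no vernalizing cold waves — so passing tests show internal consistency
  of the method chain, not skill on real meteorology.
* `generate_truth()` returns the single-point means verbatim, or draws
  each scalar uniformly within its published range with the partition
  triplets renormalized per breakpoint.
* `generate_campaign()` runs the engine with a truth set and samples the
  five stages at DVS triggers 0.2, 0.6, 1.0, 1.5, 1.9 — each at the last
  day still within its trigger, so the flowering visit happens just
  before pod emergence and the first three stages carry SAI = 0, like the
  field protocol.  Observation noise is multiplicative lognormal at a 5%
  coefficient of variation by default (field biomass errors scale with
  magnitude; the magnitude itself is an engineering choice, no measured
  error model being available).  Stage triggers are DVS-based rather than
  calendar-based so fixtures adapt to any weather seed.

## What the test suite demonstrates

With twenty-seed ensembles at the default settings (each calibration a
full season simulation per objective evaluation, roughly 120–250
evaluations per fit):

* the engine closes its daily carbon ledger to 10^-9^ relative and its
  water ledger to 10^-9^ cm, keeps DVS monotone, TPAI ≡ LAI + PAI, and
  collapses to the leaf-only model at SPA = 0;
* twin experiments recover SPA = 6.5 × 10^-4^ within one line-search step
  and reach a sub-10^-3^ curve-matching objective against an
  engine-generated calibration curve;
* with 5% observation noise the median maturity-TWSO error of the
  TPAI-Curve method stays under 10%;
* the leaf-only baseline under-predicts TWSO on pod-bearing truth in the
  clear majority of seeds, and both TPAI methods shrink the mean absolute
  bias — the package's directional reproduction of the underestimation
  phenomenon that motivates TPAI calibration.

## Known limitations

* No vernalization or photoperiod control: simulated phenology is
  temperature-sum only, and the synthetic season is compressed relative
  to a real winter-rape calendar.
* Pod area switches on discontinuously at DVS = 1 (storage mass
  accumulated before flowering acquires area at once); the partition
  tables are followed literally even where they imply storage mass before
  visible pods.
* The quadratic calibration curve is an approximation; on synthetic
  truth whose TPAI plateaus after flowering it can sit slightly above
  the true curve, which is why the curve method carries the stage-yield
  residuals in its objective.
* The water-limited mode is a deliberately simple one-layer bucket, and
  all headline results run in potential mode.
* Reusing the leaf regression's slope and intercept for silique area is
  taken as given, not validated here.
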