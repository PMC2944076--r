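---
title: "Estimating the global mortality burden of anthropogenic ozone and fine particulate matter"
author: "airburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the global mortality burden of anthropogenic ozone and fine particulate matter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airburden)
```

## The problem

Ground-level ozone (O3) and fine particulate matter (PM2.5) have risen far
above their preindustrial levels and both are associated with premature
mortality in long-term cohort studies. `airburden` estimates the worldwide
excess mortality and years of life lost (YLL) attributable to that
anthropogenic increase. The anthropogenic exposure in each grid cell is the
difference between a "present-day" and a "preindustrial" surface
concentration field (the preindustrial simulation, with fossil-fuel
emissions removed, is the counterfactual that defines "anthropogenic").
The package takes such gridded fields as input — it never runs atmospheric
chemistry itself — together with a gridded population surface and country/
region vital-statistics tables, and propagates them through a health impact
function per grid cell.

## The health impact function

For a concentration increase $\Delta X$ and a cause-specific
concentration–response factor $\beta$ (the slope of the log-linear
concentration–mortality relation), the relative risk, attributable
fraction, excess mortality and years of life lost in a cell are

$$RR = e^{\beta \Delta X}, \qquad
AF = \frac{RR - 1}{RR} = 1 - e^{-\beta \Delta X},$$

$$\Delta \mathrm{Mort} = y_0 \cdot AF \cdot \mathrm{Pop}, \qquad
\Delta \mathrm{YLL} = \Delta \mathrm{Mort} \cdot \mathrm{YLL}_0,$$

with $y_0$ the baseline mortality rate of the cause, $\mathrm{Pop}$ the
exposed population aged $\ge 30$ (the cohort-study population), and
$\mathrm{YLL}_0$ the baseline years of life lost per death (tabulated per
region and cause with 3% discounting and non-uniform age weights already
folded in). $AF \in [0, 1)$ and is increasing in both $\beta$ and
$\Delta X$.

Published relative risks per concentration increment convert to slopes via
$\beta = \ln(RR)/\text{increment}$, with standard error
$\ln(RR_{hi}/RR_{lo}) / (2 \times 1.96 \times \text{increment})$ from the
symmetric normal log-scale 95% interval — standard epidemiological
practice, and the cohort studies report only CIs. Models published directly
as slopes (e.g. the threshold-including O3 fit, $0.00432 \pm 0.00121$
ppb$^{-1}$) enter verbatim through `crf_direct()`. The bundled registry
(`default_crf_registry()`) carries the adult cohort estimates used by the
burden and sensitivity analyses: O3 respiratory RR 1.04 (1.013–1.067) per
10 ppb from the two-pollutant model (default), the single-pollutant
alternative, the 56-ppb threshold model, and three PM2.5 sets
(extended-reanalysis default 1.06/1.13/1.14 per 10 µg/m³ for all-cause/
cardiopulmonary/lung cancer, plus the earlier ACS and Six Cities
alternatives). All-cause CRFs are an alternative to, never additive with,
the cause-specific ones; likewise O3 and PM2.5 burdens are kept separate
unless explicitly summed with `sum_burdens()`, which flags the
double-counting assumption in its output.

## Exposure metrics

**O3** uses the seasonal mean of the monthly daily 1-hr maximum: for each
cell independently, `o3_season_average()` finds the consecutive 6-month
window (wrapping across the year boundary, since the high-ozone season
differs by hemisphere) with the highest mean. Ties are broken toward the
earliest start month — a documented, tested convention that only matters
for degenerate (e.g. constant) series. Monthly means of the daily 1-hr
maximum are the finest temporal input; daily data would not change the
metric.

**PM2.5** is reconstructed from speciated aerosol masses as

$$\mathrm{PM}_{2.5} = 1.375\,\mathrm{SO}_4 + 1.291\,\mathrm{NO}_3 +
\mathrm{BC} + 1.4\,\mathrm{OC},$$

i.e. sulfate and nitrate fully neutralised as ammonium sulfate and
ammonium nitrate (molar-mass ratios 132.14/96.06 and 80.04/62.00), organic
carbon scaled by 1.4 for non-carbon organic matter, and dust, sea salt and
secondary organics excluded (assumed unchanged since preindustrial times).
The default `drop_simulated_nh4` mode discards any simulated ammonium
field because the salt factors already supply the ammonium mass; applying
both would double-count it. The `add_simulated_nh4` mode (simulated NH4
added, unit salt factors) is available where the input model's own
ammonium is preferred.

## Thresholds and the exposure delta

Because the concentration–mortality relation is unobserved outside the
measured concentration range, burdens can be computed with a
low-concentration threshold (LCT) below which no effect is assumed, and a
high-concentration threshold (HCT) capping the effective concentration.
Per cell,

$$\Delta X = \max\bigl(0,\; \min(X_{present}, HCT) -
\max(X_{preindustrial}, LCT)\bigr).$$

The LCT replaces the preindustrial baseline wherever it exceeds it, so in
cells whose preindustrial concentration is already above the threshold the
natural background remains the counterfactual. The HCT is a cap on the
present-day side, which reduces burden only in cells whose modelled
concentrations exceed it and leaves all others untouched. $\Delta X$ is
floored at zero everywhere: the health impact function quantifies excess
risk from an anthropogenic *increase*, and the rare cells where the
baseline exceeds the effective present level contribute nothing rather
than negative deaths. Whether the comparison in such cells should be
against the present concentration or the delta is ambiguous in principle;
when present $\ge$ preindustrial the two readings coincide, and the zero
floor covers both. Burden is non-increasing in the LCT and non-decreasing
in the HCT, cell-wise — a tested invariant.

Defaults of interest: 33.3 ppb (O3) and 5.8 µg/m³ (PM2.5), the lowest
measured levels of the underlying cohorts; 56 ppb pairs with the threshold
model slope; 30 and 50 µg/m³ are HCT sensitivity values.

## Demography on the grid

Baseline mortality rates are country-specific where available; otherwise
the country's regional rate substitutes (`resolve_rate()`). The published
procedure back-calculates missing-country rates by removing known
countries from regional aggregates, but that requires country population
weights that are not tabulated; plain regional substitution is the
testable core implemented here, and the table schema keeps a hook
(per-country `available` flags) for the subtractive variant. Rates are
gridded with cell-to-country area weights — a cell overlapping several
countries gets the area-weighted average — and ocean cells carry rate 0
and population 0, so global sums need no masking. The adult population is
the total surface scaled by a per-region fraction aged $\ge 30$; country
rates tabulated for ages $\ge 25$ are treated as interchangeable with
$\ge 30$ rates (a single cutoff everywhere). $\mathrm{YLL}_0$ is constant
within a region per cause.

## Monte Carlo uncertainty

`mc_burden()` propagates two uncertainty sources through the full chain,
with 500 draws by default:

* the CRF: $\beta$ drawn from $N(\beta, se^2)$;
* the present-day concentrations: a multiplicative $N(1, 0.25^2)$ factor
  (SD = 25% of the simulated value). The preindustrial surface is never
  perturbed.

The concentration factor is applied in `correlated` mode by default — one
factor per draw shared by every cell — because a 25% uncertainty on
simulated concentrations represents model-wide bias rather than
independent cell noise; independent per-cell factors would average out in
aggregation and shrink regional SDs implausibly. `independent` mode is
implemented and selectable since the correlation structure is genuinely a
modelling choice. Negative draws (slope or factor) are truncated at zero
rather than resampled: truncation is simple and monotone, and the tail
mass is small for the published parameters (about 1 SD-unit beyond 2.9 for
the widest CRF). Thresholds are applied after perturbation, to the
perturbed present-day surface.

Regional means and SDs are computed from draw-level regional sums — not
from per-cell SDs — which preserves the within-draw spatial covariance
that "mean ± 1 SD" regional tables require. Every random stream is a pure
function of the configuration seed (with per-CRF and per-draw substreams),
so identical configurations give bit-identical results.

## Reporting conventions

Regional tables report thousands of deaths (or YLL) as "mean ± 1 SD",
integer-rounded half away from zero; the World row is summed before any
rounding, so it can differ by one from the sum of its rounded region rows.
Sensitivity percent changes are computed from unrounded totals as
$100 (alt - base)/base$ and rounded half away from zero to one decimal —
this pair of conventions exactly reproduces the published parenthesised
percentages from their printed numerators and baselines. Density maps
report deaths per 1,000 km² and per 10⁶ people; zero-population cells are
missing (not zero) in the per-capita map.

## The synthetic world

The generator (`gen_world()`) produces every input the pipeline consumes,
with the statistical structure the analysis assumes, so the whole method
is testable without any external download:

* a uniform cell-centered latitude–longitude grid (default 64 × 128,
  ≈ 2.8°). The simulation record the package emulates uses a Gaussian
  grid; a uniform grid is simpler and the method is grid-agnostic, which
  is why cell-area checks against quoted Gaussian-grid areas carry a 10%
  tolerance. Cell areas use the authalic Earth radius 6,371 km and sum
  exactly to the sphere's surface;
* a synthetic land mask: threshold on a smooth random surface, ~30% land —
  no coastline data involved;
* countries grown by seeded flood-fill from random land seeds (default
  60); cells on internal borders get half/half fractional weights between
  the two adjacent countries, exercising the area-weighted averaging path
  without polygon geometry. Countries are grouped into six continental
  regions by clustering their seed locations;
* population: log-normal hotspot kernels on land (default 40 hotspots),
  normalised to 6.6 × 10⁹ people;
* concentrations: present = smooth background + anthropogenic plumes
  centred on the population hotspots (broad plumes for long-lived O3,
  narrow for short-lived PM2.5); preindustrial = a configurable fraction
  of the background component only. Present therefore dominates
  preindustrial cell-wise by construction, and pollution co-locates with
  population (population-weighted means exceed unweighted means; the
  land-cell correlation between population and PM2.5 is positive). A
  `violation_cells` switch deliberately raises preindustrial above present
  in a few cells to exercise the delta clamp;
* O3 seasonality: a sinusoidal cycle peaking in July north of the equator
  and January south of it (amplitude 0.3, 2% multiplicative noise), which
  forces wrap-around windows in the southern hemisphere. The phase
  distance is folded to [0, 6] months so the cycle is exactly symmetric
  and periodic in the phase;
* PM speciation: species shares perturbed smoothly (±5%) around the
  target composition — by default 45.6/9.1/4.9/40.4% OC/BC/NO3/SO4, the
  present-day composition of the emulated record — with the simulated
  ammonium derived stoichiometrically;
* demography: country rates drawn log-normally (SD ≈ 20%) around their
  region's default rate (regional defaults follow the published regional
  summary: world averages ≈ 0.134/0.754/0.042%/yr for respiratory/
  cardiopulmonary/lung cancer; the all-cause defaults are plausible adult
  crude rates chosen for the synthetic tables), adult fractions jittered
  ±7% around the world-implied 0.439 (published regional *fractions* are
  not tabulated, only adult counts, so the synthetic spread is kept narrow
  around the global value), YLL₀ jittered ±15% around the global averages
  7.89/9.77/8.93 years per death. A configurable fraction of countries is
  flagged "rate unavailable" to exercise the regional fallback.

Numeric defaults that anchor the generated fields to the emulated record:
present-day grid-cell ranges 6.41–90.3 ppb (seasonal O3 metric) and
0.25–55.9 µg/m³ (reconstructed PM2.5 — the configured range is divided by
the mean speciation gain before generating raw species masses), and
preindustrial/background scales 0.45 (O3) and 0.08 (PM2.5), chosen so the
population-weighted preindustrial levels sit near the published global
values (≈ 20 ppb and ≈ 1 µg/m³).

What the synthetic world does **not** emulate: atmospheric chemistry,
meteorology, real coastlines or country shapes, realistic seasonal
asymmetries, or the actual spatial patterns of the emulated simulations
beyond the summary statistics above. Tests passing on synthetic worlds
therefore validate the *method* — metrics, thresholds, demographic
regridding, uncertainty propagation, aggregation — not the published
absolute burdens, which depend on the real gridded inputs (none of which
are deposited). The worked-example validations that *are* recomputable
from printed numbers (population-weighted exposure increases, every
sensitivity percent change, the world cardiopulmonary YLL/death ratio)
are checked exactly, from the bundled reference tables.

## Numerical choices

* Window tie-break: earliest start month; applied identically everywhere.
* Mixing grids is an error, never a silent regrid; all surfaces of a run
  share one `grid_spec`.
* Field I/O is plain text at full double precision (`%.17g`), so
  write–read–write is byte-stable.
* The one-pass per-cell variance accumulator carries $O(n\,\varepsilon)$
  cancellation error; variances below that floor are reported as exactly
  zero, so degenerate (zero-uncertainty) configurations return SD = 0.
* Random substreams are derived from the master seed by a small string
  hash, kept below $2^{31}$.
* Test problem sizes: module and property tests run on 16 × 32 and
  32 × 64 worlds; the end-to-end acceptance run uses the full 64 × 128
  grid with 500 draws and three pollutant–cause pairs, which completes in
  well under a minute on one core.

## Known limitations

* Regional-rate substitution rather than subtractive back-calculation for
  missing countries (see above).
* One adult age cutoff; no age-stratified CRFs, cause-of-death
  redistribution, or competing risks.
* No downscaling or urban-increment correction: coarse cells smooth urban
  concentration peaks, which in real applications biases PM2.5 exposure —
  and hence burden — downward in cities.
* The O3/PM2.5 CRF draws are independent; no covariance between
  pollutants or formal model averaging across cohort studies.
* The synthetic world's regional demographic spread is deliberately
  narrower than reality's, so regional synthetic burdens should not be
  read as predictions for the corresponding real continents.
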