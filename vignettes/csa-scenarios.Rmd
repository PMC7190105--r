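---
title: "Methods: desk-scale climate-smart agriculture scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale climate-smart agriculture scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csascen)
```

`csascen` simulates, on a synthetic world, the chain of reasoning used in
global climate-smart agriculture (CSA) assessments: which practice does a
farmer adopt in each grid cell, how do the adopted yield gains aggregate
into supply shifters, how do shifted supplies propagate through commodity
markets to 2050, what do practice switches do to cropland greenhouse-gas
emissions, and how do cheaper staples translate into fewer undernourished
people. This vignette documents the model, its parameters, and the design
choices made where the problem was genuinely open.

## The synthetic world

`generate_world()` is first-class, tested code, not a fixture: it defines
the study conditions for everything downstream.

A world is five tibbles. **Cells** are the finest unit — one row per grid
cell × crop × water system — carrying harvested area (ha), baseline yield
(t fresh matter/ha), four nitrogen channels (kg N/ha: mineral fertiliser,
manure, crop residue, mineralised soil N), growing-season length (days,
clamped to 60–250), and, for rice, straw and farmyard-manure amendment
rates (t/ha). Cells nest in food production units (FPUs), FPUs in
countries; countries double as the market regions. **Responses** give each
compatible cell × practice × climate path a fractional yield delta, a soil
organic carbon (SOC) delta (t C/ha/yr), an output water regime, and
optional overrides of the N channels (ISFM adds manure N). **Climate**
holds per-FPU × crop annual yield-trend modifiers for two contrasting
pseudo-climate paths, one "drier/cooler", one "hotter" — stand-ins for two
general circulation models, which is what makes the two-climate
mean-and-range reporting meaningful. **Macro** carries SSP2-style drivers:
population growth 0.006/yr and per-capita income growth 0.02/yr, constant
over 2010–2050. **Market parameters** are calibrated from the generated
cells (next section).

Default size is 2 000 cells, 40 FPUs, 15 countries: large enough that
within-FPU quartile statistics are meaningful, small enough that a full
26-run design completes in well under a minute. Yield deltas are truncated
normal on [-0.5, 0.5] with per-practice means and spreads chosen to encode
the qualitative evidence base — no-till small and mixed-sign
(mean +0.02, sd 0.06), ISFM clearly positive (+0.05), NUE positive
(+0.04), AWD yield-neutral to slightly negative (-0.01) — both signs must
occur, because the adoption rules are the filter. Manure N is log-normal
across cells, mimicking the skewness of site-specific application rasters.
Six configurable country ids form the no-till exclusion set.

What the generator deliberately does **not** emulate: geographic
coordinates and spatial autocorrelation of responses within FPUs (the
variance structure is a free parameter, not an estimate), real crop
physiology, cultivar or management detail, and any correspondence to actual
countries. Rainfed rice is generated unflooded (regime "none", hence no
CH₄) — a desk-scale simplification. Passing tests therefore demonstrate
that the *machinery* is correct under plausible statistical structure, not
that any real-world magnitude is reproduced.

Determinism is a contract: identical `(config, seed)` gives a byte-identical
world (truncated-normal draws use inverse-CDF sampling so the RNG stream
length is data-independent), and the caller's RNG state is restored.

## Emission accounting

Tier-1 arithmetic, exactly as printed in the standard parameterisation:

* Direct N₂O-N on unflooded soils:
  `0.01·N_min + 0.01·N_org + 0.007·N_res + 0.01·N_mineralised`.
  The residue channel is the one genuinely ambiguous point — residue N is
  cited both under a uniform 1 % clause and at a residue-specific ~0.7 % —
  and the package defaults to 0.007 with `ef_n_residue = 0.01` one config
  field away.
* Flooded rice soils: `0.003 × applied N` (mineral + manure). Applied-N
  only; mineralised N is excluded by default. A paddy under multiple
  drainage (the AWD regime) still counts as flooded for N₂O — switching
  continuous flooding to multiple drainage changes CH₄ only.
* Rice CH₄ per season:
  `1.3 × SF_water × (1 + ROA_straw + 0.14·ROA_fym)^0.59 × days`, with
  `SF_water` 1 for continuous flooding, 0.52 for multiple drainage, 0 for
  unflooded. The 0.59 is read as the exponent of the IPCC-2006-style
  organic-amendment scaling with straw conversion factor 1 — the Yan et al.
  Tier-1 convention — and the baseline 1.3 is taken in
  kg CH₄ ha⁻¹ day⁻¹.
* CO₂e: `(298·N₂O + 34·CH₄)/1000 − SOC·44/12` t/ha/yr. The GWP₁₀₀ values
  are configuration, not constants; defaults are AR5 including
  climate-carbon feedbacks. N₂O-N converts to N₂O by 44/28.

Emission intensity is net CO₂e per tonne of realised fresh output,
`co2e_total / (yield_base·(1+yield_delta))`; a non-positive realised yield
flags the intensity as undefined rather than erroring, and such candidates
are simply ineligible under intensity-based rules. Totals multiply per-ha
ledgers by **base-year** harvested areas; feeding projected areas back into
the ledger is intentionally outside the desk-scale loop, so "abatement"
here is a practice-switch effect at fixed area.

## Adoption and tailoring

Rules act per cell on the candidates compatible with its crop and water
system (no-till/ISFM for maize and wheat, NUE for rice, AWD for irrigated
rice only; no-till never in the excluded countries). Rule 1 adopts the
largest strictly positive yield delta — "higher yields" is read strictly,
equality retains. Rule 2 adds `intensity_alt < intensity_bau`, compared at
cell level, where the rules operate. The AWD cost extension admits AWD with
a decline smaller than `d* = share × reduction × cost/revenue`
(0.30 × 0.30 × 1 = 9 % at defaults), reconstructed from the break-even
condition that the revenue loss equals the irrigation-cost saving with
production cost ≈ gross revenue. Ties break on a fixed practice order
(no_till < isfm < nue < awd), then cell id, making decisions deterministic
and candidate-order invariant. Adopted fractions are 1 (everyone in a
qualifying cell adopts from year one) unless an exogenous country ×
practice rate caps them; the shipped rate table is an explicitly labelled
uniform placeholder (0.4) because no real elicited rates are included.

Tailoring converts adopted cell gains into three FPU × crop shifters: the
area-weighted mean of the lower quartile, of the whole distribution, and of
the upper quartile (poor / average / optimal). The quartile convention on
the weighted empirical CDF is inclusive and symmetric: Q1 is the smallest
gain with cumulative weight ≥ 0.25, Q3 the largest gain with tail weight
≥ 0.25, and the tails average all observations at or beyond the cut. This
reproduces the natural unweighted reading ({1,2,3,4} % → 1 %, 2.5 %, 4 %)
and guarantees poor ≤ average ≤ optimal. Area weighting is the default
(cell-count weighting is a matter of passing unit weights). Adoption *sets*
are fixed across tailoring levels; only the realised gain varies.

Shifters enter supply in growth mode by default: the annual yield growth
factor is multiplied by `(1+shifter)^(1/40)`, so the 2050 scenario/BAU
yield ratio is exactly `1 + shifter` — the additive-increment
approximation was rejected because it breaks that identity at non-zero
baseline growth. A level mode (one-off multiplier) is also provided.
Because a shifter describes the adopting area only, it is diluted by the
adopted share of each FPU's crop area before area-weighted aggregation to
the market region.

## The market model

Constant-elasticity (log-linear) forms, the documented structure of the
large linked models this stands in for; the parameterisation is synthetic
and configurable. For region r and crop c in year t:

* supply `S = A₀ P^{ε_a} · Y₀ (1+g)^t`, with `ε_a ∈ [0.1, 0.4]` the
  own-price area elasticity and g the exogenous yield growth
  (0.5–1.2 %/yr) plus climate trend plus shifter adjustment;
* demand `D = D₀ P^{ε_d} · (pop_t/pop₀) · (inc_t/inc₀)^{ε_y}`, with
  `ε_d ∈ [-0.6, -0.25]`, `ε_y ∈ [0.2, 0.6]`.

One world trade pool per commodity: the clearing price equates world supply
and demand, and regional net trade sums to zero by construction. The
base-year is calibrated to an exact unit-price equilibrium: supply
intercepts come from the generated cells (area × area-weighted yield), and
demand intercepts allocate the world total across regions by population.

Supply responds to the **current-year** price. A lagged-area (cobweb)
variant was considered and rejected: the annual-equilibrium reading keeps
each year a self-contained monotone clearing problem with a closed form on
one-region instances — which is what makes the solver independently
checkable — and avoids cobweb oscillation artefacts in a model whose
purpose is comparative statics between scenario and BAU paths.

The solver works on log price, where log excess supply is strictly
increasing (ε_a ≥ 0 > ε_d); Brent root-bracketing with an expanding
interval finds the unique root, and the result is rejected unless relative
excess demand is below 1e-10 (the exported guarantee is 1e-8). This is
deterministic, derivative-free, and immune to the step-size tuning a
damped fixed point would need. Degenerate flat instances (all elasticities
zero) return price 1 when they happen to clear. Crops are solved
independently — no cross-price terms — so land competition between crops is
reduced-form only; feed demand is a fixed share of each region-crop's
demand, and its price index drives the livestock herd through a constant
(negative) elasticity with per-head emissions.

## Food security

Food consumption is the non-feed share of demand. Kilocalorie availability
per capita per day uses per-crop energy contents (defaults: maize 3.56,
wheat 3.34, rice 2.80 Mkcal/t, standard food-composition magnitudes —
configuration, not estimates). The hunger share is `s₀ · rel^{-η}` clipped
to [0, 1], the simplest strictly monotone form consistent with an
empirical availability–undernourishment correlation; `s₀ = 0.11` anchors
the share at the reference availability and `η = 3` sets the curvature.
The reference is the run's own base-year world-average availability —
scenario and BAU share their 2010 state, so relative comparisons are
internally consistent. The child-undernourishment share is a linear index
in calorie availability (coefficient constrained ≤ 0) and three social
covariates (women's secondary education, female/male life expectancy
ratio, health-and-sanitation index) that follow exogenous linear
improvement paths, as in SSP2-style drivers; the index is clipped to
[0, 1] and scaled by the under-five population share (0.09).

## Scenario runner and reporting

`build_scenario_matrix()` enumerates 2 BAU runs (one per climate) plus
4 schemes × 2 climates × 3 tailoring levels = 26 specs in deterministic
order. `run_scenario()` executes adoption → tailoring → market → emissions
→ food security (BAU skips the first two), keeping every intermediate
table in the returned object. `summarize_runs()` reports each metric as the
two-climate mean at average tailoring with the min–max range over all
climate × tailoring combinations — ranges span climate *and* tailoring,
matching the wording of the reporting convention. A no-climate-change
switch zeroes the trend modifiers for counterfactual comparisons.

## Numerical choices and degenerate inputs

* Market clearing: residual tolerance 1e-10 internal, 1e-8 contractual;
  tested to 1e-6 relative net-trade residual across full projections and
  against the closed form `(b/a)^{1/(ε_s-ε_d)}` on 10 000 random
  one-region instances.
* AWD water cycle: drydown `(flood − min)/drawdown`, with zero drainage
  events when the cycle is degenerate (min level at flood depth); verified
  against a day-by-day water-level simulation.
* Empty gain lists (no adoption in an FPU) give shifter 0 at all levels;
  zero total weight behaves the same.
* All-negative response worlds collapse every scheme to BAU bit-for-bit —
  the null-scenario identity is tested as strict equality, not tolerance.
* Intensity at non-positive realised yield: flagged `NA`, never an
  exception.

## Problem sizes

The test suite uses worlds of 80–500 cells (10 000 for distributional
checks) and horizons of 11–41 years; the full default design (2 000 cells,
26 runs, 41 years) runs in about half a minute on one core. These sizes
were chosen so quartile and subset properties are exercised with
non-trivial samples while the suite stays interactive.

## Known limitations

No spatial correlation or real geography; no cross-price or land-market
interactions between crops (and none with crops outside the model); no
indirect N₂O, no process-based soil chemistry (SOC deltas are exogenous
inputs); no dynamic adoption diffusion; no welfare accounting; emission
totals at base-year areas. The placeholder adoption-rate table and all
synthetic market parameters must be replaced with real data before any
substantive application.
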