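---
title: "Process models and numerical choices in paddysim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process models and numerical choices in paddysim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paddysim)
```

paddysim simulates one rice cropping season on a layered soil profile at a
daily time step. This vignette is the package's own account of the science:
the process models, their assumptions, the parameters that matter, the
numerical choices, and the limits of what the synthetic test suite can and
cannot show about real fields.

## The daily loop and its ordering

`run_season()` advances the coupled system one day at a time in a fixed
order: weather → potential ET → soil temperature → soil C/N transformation →
crop N demand → water uptake (drought index Sw) → N uptake (nitrogen index
SN) → photosynthesis and allocation → root growth and senescence → water
redistribution and N transport → management events. The ordering is a design
choice with a clear rationale: uptake must see the post-transformation
mineral pools, and allocation must see both stress indices of the same day.
Management (irrigation, fertilizer) acts at the end of the day, so applied
water ponds overnight and infiltrates the next morning, which mirrors field
practice of irrigating onto a drained surface.

Mass conservation is not an aspiration but an invariant: every transfer of
water or nitrogen is an explicit debit/credit between pools, and the driver
recomputes full water and nitrogen balances each day. The residuals are
columns of the output table; the tests require them below 10⁻⁶ (they sit
near 10⁻¹³, i.e. float rounding).

## Potential evapotranspiration

The model uses Priestley–Taylor with α = 1.26 on net radiation approximated
as 0.75 of incoming shortwave, partitioned into potential soil evaporation
and potential transpiration by Beer's law `exp(−k·LAI)` with the cultivar's
extinction coefficient k (default 0.5). A resistance-based ET formulation
would need wind and humidity, which the weather contract (date, Tmin, Tmax,
radiation, rain) deliberately does not require; Priestley–Taylor is the
standard radiation-limited choice for humid rice environments.

## Soil temperature

Layer temperatures follow 1-D heat conduction. The heat capacity is a
de Vries mixture, `H = 2.0·10⁶·(BD/2.65) + 4.18·10⁶·θ` (J m⁻³ K⁻¹), and the
conductivity is a Campbell-style empirical curve rising monotonically with
water content toward a texture-dependent saturated value (sand conducts
better than clay). The discretization is backward-Euler with a tridiagonal
(Thomas) solve — unconditionally stable, which matters with thin surface
layers — sub-stepped 24× per day by default, with a Dirichlet surface
condition and zero flux at the profile bottom (a conservative default for
~1 m profiles; deep boundary temperature data are rarely available).

The surface boundary temperature is a running mean of daily mean air
temperature whose responsiveness is damped by standing water
(half-coupling at 20 mm) and surface residue (half-coupling at
2000 kg ha⁻¹): this encodes the heat-buffering role of the flood layer that
distinguishes paddies from aerobic fields. With a bare dry surface the
boundary equals the daily mean air temperature exactly. Where the surface
holds both water and residue the two damping terms add in the denominator —
no established quantitative rule exists for a mixed water/residue
interface, so the additive form is pinned here as the package's choice.

The scheme is verified against the analytic solution of the heat equation
under sinusoidal forcing: on a deep uniform profile, the annual amplitude
at depth z must decay as `exp(−z/d)` with damping depth
`d = sqrt(2(K/H)/ω)`. The acceptance test runs 3 years at 4 sub-steps/day
on 60 layers of 0.25 m and reproduces the amplitude profile to ~0.05%.

## Soil carbon and nitrogen

Two organic pools per layer — fresh organic matter (fom) and humus — decay
first-order (defaults 0.02 d⁻¹ and 5·10⁻⁵ d⁻¹) under a Q10 = 2 temperature
factor (reference 25 °C, capped at 1.2) and a moisture factor that rises
linearly from 0 at wilting point to 1 at field capacity and declines to an
anaerobic value (0.3) at saturation. A fixed 30% of decomposed fom C is
humified; the humified C immobilizes N at a microbial C:N of 10, the rest
respires as CO₂. Net mineral N release adds to NH₄; net demand draws NH₄
then NO₃ and rations decomposition if mineral N runs out.

Urea hydrolyses to NH₄ first-order (0.25 d⁻¹·fT). Nitrification
(0.2 d⁻¹·fT·fW·f_pH) is suppressed when θ ≥ 0.95·θsat — the flooded-paddy
regime where the anoxic bulk soil protects NH₄ — and denitrification
removes NO₃ only above field capacity, scaling with the saturation excess
and fresh-C availability. Fixed fractions of the two fluxes (0.5% and 2%)
are tallied as N₂O for reporting only; they do not feed back on the pools.
Ammonia volatilizes from the surface layer at a base 0.05 d⁻¹ at pH 7,
doubling per pH unit, zero below pH 5.5, doubled under standing water.
Deposition adds 10 kg N ha⁻¹ yr⁻¹ split NH₄:NO₃ in daily increments.

Mineral N moves advectively with the water fluxes of the same day at the
source layer's dissolved concentration; NH₄ mobility is damped 10× by
adsorption; the organic pools do not move between layers, and dissolved
organic carbon is not represented at all.

Two numerical modes exist for every first-order process: the default
*exact-exponential* update `ΔP = P(1 − e^(−kΔt))`, which removes step-size
artifacts at no cost, and a sub-stepped Euler mode (24 sub-steps/day) kept
for comparison. A single daily Euler step at k = 0.25 d⁻¹ would be 3.7% off
the closed form — beyond the 2% the package demands of itself — which is
why the Euler mode sub-steps the day.

All kinetic constants sit in `default_constants()` and are overridable per
run; they are documented stand-in defaults at field-plausible magnitudes,
not fitted values.

## Water balance and retention

The water balance is a tipping bucket: evaporation (pond first, then the
surface layer down to wilting point), infiltration filling layers to
saturation top-down, drainage of half the above-field-capacity water per
day cascading downward, percolation out of the profile capped by a
profile-level conductivity (5 mm d⁻¹ puddled lowland, 20 mm d⁻¹ aerobic),
ponding up to the bund (100 mm lowland, 0 aerobic), excess running off.
When the profile is saturated under a pond, pond water seeps through at the
percolation cap — the steady percolation of a puddled field. A
Richards-equation solver would need unavailable hydraulic functions and
would buy little for daily lowland water budgets.

Matric potential uses the two-parameter Campbell curve
`ψ = ψe·(θ/θsat)^(−b)`, with ψe and b derived per layer from the layer's
own anchor points (field capacity at 33 kPa, wilting point at 1500 kPa).
This makes the suction scale exactly consistent with the water constants
the user supplies, inverts in closed form, and is what AWD irrigation rules
sense: a 20/40/70 kPa threshold at 0.18 m depth triggers a 50 mm dose.

## Water uptake, extractable water, and Sw

Extractable water per layer is
`ew = (θ − θwp)·Δz·[1/DTF + (1 − 1/DTF)·(θ − θwp)/(θsat − θwp)]`:
at saturation all available water (counting the water between field
capacity and saturation, because rice is hydrophilic) is extractable; as
the layer dries, only a DTF-scaled fraction remains accessible. DTF = 1
collapses to "extractable = available".

Transpiration demand is partitioned over rooted layers by the product of
the layer's root-mass share and extractable-water share, capped per layer
at its extractable water, with one redistribution pass that sends unmet
demand to layers with spare capacity. The drought index is
`Sw = (1 − e^(−a·r))/(1 − e^(−a))`, `a = DTF − 1`, with the analytic limit
`Sw = r` at DTF = 1, so a drought-sensitive cultivar loses photosynthesis
linearly with the uptake ratio while a tolerant one is barely affected by
mild deficits. This two-parameter form was chosen because it satisfies
every property the index must have (exponential shape, DTF range 1–10,
linearity at DTF = 1, endpoint anchoring, monotonicity in both arguments —
all grid-tested) and it is isolated in one function so an alternative
curve can be substituted without touching the driver. DTF deliberately enters
both the extractable-water scaling and the Sw curve with the same value;
the two hooks are separate arguments, so they can be decoupled if a
parameterization ever distinguishes them.

An important emergent behaviour: because the redistribution pass
compensates fully across the root zone, Sw falls below 1 only when
*total* root-zone extractable water approaches the day's transpiration
demand. AWD cycling at thresholds of 20–70 kPa on a 0.4–0.6 m root zone
never gets there — safe-AWD seasons show no drought penalty in this model —
whereas withholding irrigation from panicle initiation (rainfed drought)
does. Yield differences *between* AWD intensities in full runs are instead
nitrogen-mediated (wet–dry cycling drives nitrification–denitrification
losses), which is why the scenario-ordering checks below are run at the
water-limited production level.

## Nitrogen demand, uptake, and SN

Daily demand is the sum of organ deficits against critical contents — leaf
N per unit leaf area (default critical 1.5 g N m⁻², so leaf demand is
`(1.5·LAI·10 − leaf N)` in kg ha⁻¹), stem and panicle critical
concentrations declining with development stage, and root N at the optimal
root C:N — capped by a maximum daily uptake (8 kg N ha⁻¹ d⁻¹). Mass flow
delivers water uptake × dissolved mineral N concentration per layer (so
wetter soil dilutes and reduces N gained per mm of water, while drought
cuts mass flow with the water itself — both stresses co-occur under severe
drying). Diffusion fills the residual demand up to a capacity
`0.2·(root share)·fW·(mineral N)` per layer. `SN = uptake/demand` clipped
to [0, 1], and the growth reduction applied downstream is the greater
stress, `min(Sw, SN)`. The combined factor also scales the potential rates
the next day only through its effect on growth — SN does not additionally
throttle transpiration demand directly, which keeps the two indices
separable in the output; this reading of the stress coupling is flagged as
revisitable.

Uptaken N is allocated to organs proportionally to their deficits; dying
leaves recycle 50% of their N to the remaining green leaves and carry the
rest into the dead-leaf pool.

## Growth, allocation, phenology

Thermal time accrues on a trapezoid between cardinal temperatures (defaults
8/30/42 °C) and maps piecewise-linearly to development stage (0.65 at
panicle initiation, 1 at flowering, 2 at maturity). Daily potential growth
is `RUE · 0.5·srad · (1 − e^(−k·LAI)) · 10` kg ha⁻¹ (RUE default
2.5 g DM MJ⁻¹ intercepted PAR — the 0.5 converts shortwave to PAR), scaled
by `min(Sw, SN)`. The RUE formulation replaces a leaf-level photosynthesis
integration: it preserves the stress-scaling pathway exactly while being
implementable and testable from first principles, and it sits behind the
`daily_growth()` boundary for later substitution.

Allocation starts from development-indexed baseline tables (shoot fraction
of assimilate; leaf/stem/panicle shares within the shoot, summing to 1 at
every node). Under stress `s = min(Sw, SN)`: the shoot fraction is
multiplied by `0.5 + 0.5·s` (stress sends assimilate root-ward, to a floor
of half the baseline), the stem share is multiplied by s with the freed
share split leaf:panicle = 1:2 before flowering and all-panicle after
(storage priority), and above LAI 6 a further 10% of the leaf share moves
to stem + panicle (light competition — tall structure and storage beat
shaded foliage). These shift magnitudes (0.5 floor, 1:2 split, LAI > 6,
10%) are pinned package defaults encoding the qualitative rules; with
s = 1 the baseline tables are recovered bit-exactly, which the tests
assert. Grain yield is reported as panicle mass at maturity converted to
14% moisture (÷0.86).

## Root growth

The root front extends at a base 0.01 m d⁻¹ × temperature factor ×
penetration factor (decreasing in bulk density above 1.1 Mg m⁻³ and in
clay) × moisture factor (zero below wilting point at the front), capped at
the cultivar's maximum rooting depth. New root mass is distributed over
rooted layers by favorability weights — moisture ramp × temperature
trapezoid × a Michaelis-type mineral-N attraction `N/(N + 20)` × rooted
thickness. The N form is a saturating guess where only the controlling
variable is documented; it is isolated for substitution. A legacy
constant-rate mode reproduces the older uniform behaviour for regression
comparisons.

Senescence is N-driven: when root C:N (C = 0.42 g C g⁻¹ DM) exceeds the
cultivar optimum, biomass is shed (≤5%/day) with **half the N of the
senescing tissue resorbed** into the living pool. The resorption is load-
bearing: if shed tissue carried N at the pool's own concentration the C:N
ratio would be invariant under shedding and could never be restored — so a
stated rule of "shed biomass carrying its N" cannot work literally, and
50% resorption (a mid-range literature value for fine-root N resorption)
makes the mechanism mathematically coherent. Dead roots enter the layer's
fresh organic pools, closing the N loop.

## Production levels

`run_season(production = …)` implements the standard production-level
protocol of crop simulation: `"potential"` (both stress pathways held at
1), `"water_limited"` (only Sw acts), `"n_limited"` (only SN), `"actual"`.
Soil processes and uptake run identically in every mode, so the indices are
always computed and reported; the mode gates only their application to
growth and allocation. Two uses matter here: the potential-production
scenario (`scenario_potential()`, a flooded season with saturating soil
mineral N) verifies that the stress machinery is *exactly* neutral when
supply meets demand — the actual and potential runs agree to machine
precision — and the irrigation-regime comparisons are run water-limited so
the water factor is isolated from the nitrogen-loss differences described
above.

## The synthetic generators, and what the tests do not show

`gen_weather()` produces sinusoidal-seasonal temperature with AR(1) noise,
two-state Markov rain occurrence with gamma amounts rescaled to the target
seasonal total (±2% stochastic factor), and radiation anticorrelated with
rain. `gen_scenarios()` builds four experiment families spanning the management
envelopes of contemporary rice agronomy trials: a water-management ladder
(flooded + AWD 20/40/70 kPa, 50 mm doses), sixteen nitrogen split schedules
(0–225 kg N ha⁻¹ over four timings in wet- and dry-season climates), an
aerobic-soil experiment (225/300 kg N, suction-triggered or sparse fixed
irrigation), and a multi-variety drought design (seven DTF variants,
irrigated vs rainfed-after-panicle-initiation, 160 kg N in five splits).
Soil profiles default to nine 0.1 m layers (puddled clay loam, or an
unbunded sandy aerobic variant) because no source profile tables exist.

These generators define *study conditions*, not calibrations: passing tests
show that the process implementations are internally correct (conservation,
analytic oracles, stated properties, orderings) under realistic forcing.
They cannot show that the defaults reproduce any particular field site —
no observed weather, soil, or phenotype data enter the package — and the
evaluation statistics module exists precisely so users can make that
comparison against their own observations.

## Numerical conventions and problem sizes

Tolerances: conservation residuals < 10⁻⁶ (achieved ~10⁻¹³); retention
round-trips < 10⁻¹⁰; exact-exponential pool updates at 10⁻¹²; heat oracle
within 5% (achieved ~0.05%). Ties and degenerate inputs: zero transpiration
demand defines Sw = 1, zero N demand defines SN = 1; all-zero root
favorability falls back to uniform-per-thickness; a zero-variance simulated
series leaves r² undefined (NA) rather than inventing a value. The test
suite runs seasons of 60–150 days on 9-layer profiles, the heat oracle on
60 layers × 3 years, the statistics oracle on 1000 random series, and the
DTF recovery on three seasons × a 10-point grid with daily biomass
observations at 5% noise — sizes chosen so the full suite completes in a
few minutes on one core.

## Known limitations

No methane, no microbial biomass pools, no P/K, no pest/disease, no
salinity, no CO₂ fertilization. No spikelet-sterility or grain-filling sink
limitation — yield responds to stress only through assimilate supply and
allocation, so cold- or heat-induced sterility effects are out of reach. No
groundwater table, hysteresis, or hourly dynamics. Phenology parameters
remain environment-specific inputs. Seedbed raising is not simulated;
transplanted crops start at the transplanting date with user-supplied
seedling biomass. The nitrification–denitrification loss magnitudes under
wet–dry cycling follow directly from the pinned first-order defaults and
should be re-estimated against flux measurements before the emission
tallies are used quantitatively.
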