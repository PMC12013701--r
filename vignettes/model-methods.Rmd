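---
title: "Model structure, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`tallgrass` is a desk-scale, spatially distributed ecohydrological model of
tallgrass prairie: a daily four-layer soil water balance on a flow-routed
elevation grid, coupled to plant growth under nitrogen-water-temperature
co-limitation, surface fuel accounting, prescribed fire, and a grazer
nitrogen budget. This vignette explains the model and the reasoning behind
its defaults, in the spirit of a methods appendix: what is computed, what is
assumed, and what a passing test does and does not establish.

## The modeled system

The template landscape is a dissected midcontinental prairie catchment:
flat-topped ridges with shallow rocky soils, side slopes, and valley
lowlands with deep well-drained soils roughly 120 m below the ridges.
Climate is temperate midcontinental, with a long-term mean near 835 mm/yr of
precipitation of which about three quarters falls in the April-September
growing season. Management is prescribed fire on parcel-specific return
intervals (1, 2, 4, 20 years, typically burned in April) and cattle or bison
grazing either year-round or in a roughly 90-day window opening about two
weeks after a spring burn.

Productivity in this system is co-limited: soil moisture, mineral nitrogen,
and temperature each cap plant nitrogen uptake at different places and
times, and the binding constraint shifts within and between seasons (wet
springs are often N-limited; late summers are water-limited, especially on
uplands). The model's central contract is to let those constraints interact
mechanistically on a routed landscape rather than be prescribed.

## Daily plant nitrogen uptake

Per soil layer, daily plant N uptake is

\[ U_l \;=\; \mathrm{RBN}_l \times \mathrm{TNUscalar} \times \mathrm{NMU}
   \times \min(\mathrm{Nscalar}_l, \mathrm{Wscalar}_l), \]

where RBN$_l$ is root biomass N in the layer (g N/m^2^), NMU is the maximum
specific uptake rate (g N per g root N per day), and the three scalars lie
in [0, 1]:

* **TNUscalar** — piecewise-parabolic in soil temperature, 0 at/below
  `tmin_C` (5) and at/above `tmax_C` (38), 1 at `topt_C` (24). The
  functional form is a stand-in: the anchor behavior (0/1/0 with a smooth
  optimum) is the modeled claim, the quadratic shape is not.
* **Wscalar** — linear in layer WFPS between the wilting point (0.3, the
  one printed soil-moisture constant, for silty clay loam textures) and
  field-capacity WFPS. Uptake ceases at or below wilting.
* **Nscalar** — Michaelis-Menten in plant-available mineral N (ammonium +
  nitrate jointly, one half-saturation constant `n_half_sat_gNm2 = 0.4`
  g N/m^2^ per layer, placed so mid-season values sit in the 0.3-0.6 range
  and both limitation regimes are exercised).

The minimum of the N and water scalars is selected per layer, uptake is
additionally capped by the layer's mineral N, and layer uptakes sum to the
day's NPP in nitrogen units. Fixed allocation fractions (leaf 0.40,
aboveground stem 0.20, belowground stem 0.05, roots 0.35, roots split
0.45/0.30/0.15/0.10 over layers) and pool C:N ratios (35/60/60/45) convert
N uptake to carbon; dry weight is carbon / 0.45.

A note on units: source descriptions of this uptake equation list both RBN
and NMU in areal units (g N/m^2^ and g N/m^2^/d), whose product would
square mass. NMU is therefore implemented as a *specific* rate (per g root
N per day), which makes the product dimensionally consistent; its default
0.02/d was set in calibration.

## Hydrology

Each cell carries four soil layers with thickness, porosity,
field-capacity and wilting WFPS, and saturated conductivity, assigned by
topographic position (upland / slope / lowland). The daily order of
operations is fixed for reproducibility: infiltration, vertical
percolation, lateral downslope flow in topological order,
evapotranspiration, then same-day streamflow accounting.

* **Infiltration** is `min(precip, capacity, free top-layer pore space)`;
  the excess is surface runoff, delivered to the outlet the same day.
* **Percolation** moves water above field capacity downward, capped by
  conductivity and the receiving layer's free pore space, in a single
  top-down pass (so a saturated middle layer cascades water to the layer
  below it). The bottom of layer 4 is closed: the model deliberately has no
  deep aquifer, so bottom-layer excess leaves only laterally.
* **Lateral flow** transfers water above field capacity at a daily fraction
  `ksat x slope / thickness` (clamped, scaled by `lateral_mult`), split
  among downslope neighbors by gradient-weighted flow weights, processed
  upslope-to-downslope so the day's transfers are single-pass. Stream cells
  (contributing area at least `stream_threshold_cells`, default 50) drain
  their excess, and any lateral arrival, directly to the channel; channel
  water reaches the outlet the same day (no channel storage at a daily
  step). Receiving-layer overflow above saturation cascades upward and
  ultimately becomes surface runoff.
* **Evapotranspiration** is Hamon potential ET (temperature and daylength
  only, the only quantities the forcing provides), zero on frozen days,
  scaled by a leaf-biomass factor rising from a bare-soil floor
  (`et_base = 0.45`) toward a plateau (`et_max = 1.30`, half-saturation 60
  g leaf C/m^2^), apportioned over layers by root fraction and limited to
  water above wilting. High biomass therefore means high water use, which
  is what couples productivity back into the water balance.

Snow is ignored: sub-zero days produce no ET and infiltrate normally. This
is a known limitation; it biases winter timing of discharge but not annual
totals at this latitude's precipitation phase.

## Terrain

The synthetic DEM is a sinusoidal-profile ridge-valley catchment with
deliberately flat ridge tops (to exercise flat processing), correlated
dissection noise on the side slopes, and a valley floor tilted to a single
boundary outlet; total relief defaults to 120 m. Flat processing is a
priority-flood from the outlet imposing a 1e-5 m epsilon gradient over
flats and pits — only flat or pit cells change, and basins fenced off from
the outlet raise an error naming the offending cell. Flow weights are
positive elevation gradients to the (up to 8) lower neighbors, normalized
to 1; ties split the flow rather than being broken, which is the
multi-direction behavior the routing is meant to reproduce. Cells are
ordered by descending resolved elevation, which is a valid topological
order of the flow graph and is used everywhere routing must be single-pass.

Topographic position uses relative elevation within a 9-cell moving window
plus contributing area: valley-bottom cells (large contributing area or
bottom tercile) are lowland, top-tercile cells with small contributing area
are upland, the rest slope. Locally flat windows fall back to grid-wide
relative elevation (so ridge plateaus classify as upland), and a globally
flat grid is all lowland by convention.

## Carbon, nitrogen, fuel

Litter, standing dead, and soil organic pools decompose first-order with a
Q10 temperature factor (zero when frozen, capped at 1.3) and a parabolic
moisture factor peaking at WFPS 0.6. Decomposed C leaves as CO2. For the
soil organic pool, decomposed N is mineralized to ammonium except for a
30% microbial retention fraction. Surface fuels are different: dead grass
decomposes at roughly twice the C:N of live tissue, so microbes
immobilize most of its N — 70% of fuel N routes to soil organic matter
(humification) and only 30% mineralizes directly. This matters for the
fire comparison: unburned parcels recover their fuel N slowly through the
soil organic pool, rather than getting an immediate mineral return.
Nitrification is first-order in ammonium with an aerobic moisture optimum;
denitrification is first-order in nitrate, negligible below field capacity
and rising quadratically above it. Dissolved mineral N advects with the
day's percolation and lateral water fluxes in proportion to the fraction
of layer water moved, times a species mobility (nitrate 1.0, ammonium
0.1); N reaching stream cells is exported. Non-symbiotic fixation adds a
small ammonium input (8e-4 g N/m^2^/d), boosted 50-fold for 60 days after
fire (~2.4 g N/m^2^ per burn, at the top of the range reported for
post-fire cyanobacterial crust fixation) — this post-burn flush, together with ash
N, produces the spring pulse of available N on burned parcels.

Two further mechanisms close the fire-productivity loop. First, surface
fuel shades and insulates the soil: the effective surface temperature
driving the soil-temperature profile is the air temperature plus
`sun_warm_C` (5 °C) times one minus a fuel-shading factor
(`fuel C / (fuel C + 150)`), so fire-blackened, litter-free cells warm
faster in spring — higher TNUscalar, earlier growth and mineralization.
Second, autumn senescence resorbs half of the departing leaf and stem N
into the belowground stem (rhizome/crown) store before abscission, which
is why the dead fuel pool carries roughly twice the C:N of live tissue
and why burning the fuel does not volatilize the plant's whole aboveground
N capital. With these three pieces (immobilization, warming, resorption,
plus the fixation pulse and ash return) the model reproduces the observed
ordering — annually burned parcels out-produce unburned parcels — despite
fire being a net nitrogen export.

Senescence begins when day length falls below 12.5 h after mid-year
(around mid-September at 39°N) and moves 4.5%/d of leaf and aboveground
stem mass to standing dead, so live aboveground biomass is nearly zero by
late December while the fuel pool recovers — the annual fuel cycle the
fire module consumes. Standing dead falls to litter at 1%/d; roots turn
over to soil organic matter year-round. All turnover pauses on frozen
days, which makes a frozen, dry, dormant day an exact fixed point of the
state (a property the tests assert).

Fire combusts 90% of dead fuel and 90% of live aboveground biomass;
80% of combusted N volatilizes and 20% returns as ash ammonium;
belowground pools are untouched and the post-fire fixation clock resets.
Grazing removes `min(0.007 g N/m^2/d, live aboveground N)` — the one
printed grazing constant — partitioned 15% grazer weight gain (exported),
35% manure (soil organic N), 45% urine (ammonium), 5% volatilized. The
partition values are configuration defaults: the budget compartments are
standard, their shares are not published. The "0.007 is a daily fraction"
phrasing conflicts with its printed flux units; the flux interpretation is
the default and a true daily-fraction mode is available in configuration.

## Mass ledgers

Every run accumulates water, N, and C ledgers and asserts closure at the
end: precipitation = storage change + ET + discharge; N inputs (fixation)
minus exports (fire volatilization, denitrification, stream export, grazer
volatilization and weight gain) equal the change in total N; NPP carbon
equals the change in total C plus CO2, combustion, and grazed C. Residuals
are required below 1e-6 relative (they sit near machine precision in
practice). The ledger is the main defense against silent plumbing errors
in a model with this many pool-to-pool transfers.

## Synthetic forcing: what it emulates, and what it does not

The weather generator is a two-season (April-September vs October-March)
two-state Markov chain for occurrence with gamma-distributed wet-day
depths; the gamma scales are derived from the configured annual mean and
growing-season share, so those two statistics are structural. Temperature
is a sinusoid plus white noise; its parameters (mean 12.7°C, amplitude
14.5°C, coldest day Jan 15, noise sd 3°C) are declared package defaults
for a temperate midcontinental site — the source material does not print
intra-annual temperature statistics, so these must not be read as measured
site values. The generator does not emulate interannual persistence
(drought runs arise only by chance), convective clustering beyond lag-1
wet-day persistence, or any precipitation-temperature coupling. A green
test against this forcing therefore establishes that the model reproduces
the *stated normals* and responds correctly to the *kinds* of variability
prairie experiences — not that any particular historical sequence is
reproduced.

Burn scars are emitted at a scar grid 2x coarser than the simulation grid
(emulating coarse remote-sensing burn products over a finer model grid); a
burning scar cell ignites all nested simulation cells, and treatment
parcels are strip-aligned to scar columns so scars cover whole scar cells.

## Calibration and the acceptance targets

Most rate constants in this model are not printed in its source material.
They were set in a single calibration pass against the printed benchmarks —
mean annual runoff near 20 cm of ~84 cm precipitation, treatment-level
ANPP inside the observed 200-800 g dw/m^2 range with lowland above upland,
most production accrued before July 2 — and then frozen; the emergent
quantities (resolution invariance, grazing reductions) were measured
afterwards and are reported as found, not tuned. The calibrated values
live in `default_config()` and `default_soil_library()`; every one of them
is an ordinary configuration parameter, so a user disagreeing with a
default can override it in the JSON configuration without touching code.

Numerical conventions worth knowing: grid indexing is row-major with row 1
at the north edge and neighbor order E, NE, N, NW, W, SW, S, SE; the flat
epsilon is 1e-5 m; simulations run 3 spin-up years on real antecedent
generator weather preceding the reporting period (discarded from all
statistics) because synthetic initial pools need equilibration — antecedent
years rather than a replay of year 1, because identically repeated forcing
lets small systematic state differences (e.g., between grid resolutions)
compound through the root-nitrogen store and surface as a spurious
first-reporting-year anomaly; annual ANPP is peak-season standing live
aboveground biomass sampled August 27; fuel maps are December 31 standing
dead + litter carbon, nodata off grassland; WFPS snapshots default to
July 2. One master seed derives independent sub-streams for climate,
terrain, and scars, so regenerating one input never perturbs another and
runs are bit-reproducible.

## Known limitations

No snowpack; no deep groundwater (deliberate); no species composition,
woody encroachment, symbiotic fixation, or phosphorus; fire is
instantaneous and weather-independent in completeness; grazer energetics
reduce to a nitrogen budget. The synthetic catchment is one template, not
a sampling of landscapes: emergent numbers (runoff ratio, grazing
reductions, resolution sensitivity) are properties of this stated world
under this calibration, and the acceptance report should be read that way.
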