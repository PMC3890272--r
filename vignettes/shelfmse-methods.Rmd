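---
title: "Models and methods behind shelfmse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind shelfmse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`shelfmse` is a desk-scale management strategy evaluation (MSE) framework.
An MSE closes the loop between a simulated "true" ecosystem (the operating
model), the fleets that fish it, and the management procedure that observes
the fishery with error, assesses stocks, sets quotas and closes areas. The
package evaluates four archetypal strategy packages — status quo, enhanced
quota management, an integrated mix of measures, and conservation-dominated
management — on a synthetic temperate shelf and slope fishery, and reports
the trade-offs among ecological, economic, social, industry, operator and
management-cost objectives as composite "kite" scores.

This vignette documents the models, their assumptions, the tunable
parameters, the numerical choices, and the limits on what the packaged
experiments can show.

## The operating model

The simulated truth is a biomass-dynamics pool model: 12 functional groups
(demersal and pelagic target fish, byproduct and bycatch groups including a
deepwater shark of conservation concern, squid, forage fish, a
threatened/endangered/protected (TEP) group standing for seabirds and
marine mammals, scavengers, habitat-forming benthos and a detritus pool)
in 6 depth-stratified spatial boxes (inshore, shelf, upper slope, deep).
Dynamics run on a quarterly time step; management acts annually on data
through the previous year. This replaces the diurnal, age-resolved
biogeochemistry of full end-to-end ecosystem models with the smallest
structure that can still express the mechanisms of interest: trophic
release, habitat impacts of bottom gear, discard-fed scavenger dynamics,
spatial effort displacement and size responses to exploitation.

Per group $g$ and box $b$ the quarterly update applies, in order:

1. **Production**: logistic somatic growth $r_g/4 \cdot B(1 - B/K_{gb})$,
   scaled by a habitat factor $1 - h_g(1 - \bar H_b)$ (where $h_g$ is the
   group's habitat dependency and $\bar H_b$ the sensitivity-weighted cover)
   and, for predators, by a food-intake factor $\min(f_{max}, \phi/\phi_{ref})$
   with $\phi$ the Holling type-II saturation of available prey. Recruitment
   is an explicit Beverton–Holt term
   $R = 4hR_0 s /((1-h) + (5h-1)s)$, $s = S/B_0$ (hockey-stick variant
   available as a structural alternative), allocated over boxes by capacity
   share. Because production includes predation-dependent terms, the
   realised unfished equilibrium sits below the logistic capacity $K$; all
   reference points use the model's own solved equilibrium, not $K$.
2. **Trophic mortality**: Holling type-II consumption over an availability
   matrix. The scavenger's diet includes the detritus pool, closing the
   discard-fed loop; its half-saturation constant uses a nominal reference
   pool size (2% of summed capacity) because the pool itself has no $K$.
3. **Natural mortality** $M_g/4 \cdot B$, with a fraction (0.4) of the dead
   flux routed to detritus.
4. **Removals** (catch plus discards), capped at 80% of a cell's biomass;
   natural, trophic and incidental losses rescale into the remaining
   headroom so the fishing ledger is honoured exactly, and in the rare case
   where even removals cannot fit, the applied cut is reported so callers
   rescale landings and discards identically.
5. **Incidental mortality**: benthos killed in proportion to bottom-contact
   swept-area density; routed to detritus.
6. **Mobility**: mass-conserving exchange directed toward neighbouring
   boxes in proportion to their capacity, so biomass does not bleed into
   unsuitable habitat.
7. **Habitat**: per habitat type,
   $H' = H + \rho H(1-H) - \iota_{gear} s_h (swept/area) H$, clipped to
   [0,1]. Only bottom-contact gears have $\iota > 0$; biogenic habitat
   recovers slowly (0.01 per quarter) so chronic trawling leaves
   decade-scale scars.
8. **Detritus**: inputs (discards, incidental kill, natural dead flux)
   minus decay and scavenger consumption, floored at zero, with an exact
   term-by-term ledger.

A mean-size state per group relaxes toward
$size_0 (1 - 0.8\,U)$ with $U$ the annualised exploitation rate, providing
the average-catch-size and size-spectrum indicators without age structure.

Every step returns an exact flux ledger
($B' = B + P - T - N - R - I + \text{mobility}$), which the tests verify to
machine precision; this is the backbone of all conservation checks.

### Equilibrium solver

The unfished starting state is the fixed point of the quarterly map with
zero removals, found by fixed-point iteration accelerated with entrywise
Aitken $\Delta^2$ extrapolation on snapshots 12 iterations apart (fast
modes die between snapshots, so the extrapolation cleanly removes the
dominant slow mode — low-productivity groups such as the TEP pool converge
at ~0.3% per quarter otherwise). Default tolerance is $10^{-9}$ relative
change per quarter; ensemble members warm-start from the base member's
equilibrium and use $10^{-7}$, far inside the $10^{-6}$ one-quarter drift
the framework requires. Non-convergence is an explicit error carrying the
residual.

## Fleet dynamics

Vessels are integer counts per fleet (bottom trawl, Danish seine,
gillnet/longline, midwater seine and jig) sharing a cost and behaviour
profile, with an active/latent state — not individual agents. Each quarter
a fleet distributes its capacity over boxes by a softmax on expected profit
per vessel-day blended with last quarter's shares (inertia 0.5, temperature
$1000 per day). A stochastic non-compliant fraction with mean
$(1-c)(1-\text{enforcement})$ ignores zoning; compliant effort in a closed
cell is identically zero. When no open box offers a positive margin the
fleet drops to pulse effort, concentrating what remains in its best
seasonal price quarter — the "tied up in port" behaviour that dominates the
conservation strategy.

Catch follows $C = q\,sel\,E\,B\,/\,area$, with logistic selectivity-at-size
whose L50 scales with mesh, so the gear controls (90/100/110 mm trawl mesh
across strategies) act through the size state. In partially closed boxes
catch accesses only the open share of biomass (the reserve effect);
non-compliant effort in fully closed boxes fishes freely. Retention applies
bycatch-reduction devices (bycatch and TEP catch scaled by $1-$BRD, the
reduction escaping alive), a baseline unmarketable-discard rate per fleet
(reduced by larger mesh and by targeting-improvement controls), and
quota-driven discarding whose form depends on the reconciliation rules.
High-grading is expressed as a value premium on quota-constrained landings
rather than a tonnage swap, which keeps the catch ledger exact; the
landings + discards = post-BRD catch identity holds cell by cell.

Economics follow the cost classes of the indicator catalogue (fuel and
steaming, gear, refrigeration/transport, unloading, capital and fixed) with
an exact profit identity. Persistent losses (three consecutive years)
push vessels latent; latent vessels re-enter while expected annual profit
per vessel (net of the cost-recovery levy, prospectively spread over at
least a modest fleet of 20) is positive. The scheduled buyback retires
licences latent-first, so removing non-participants leaves active capacity
unchanged. A single annual lease-market clearing per quota unit sets a
price increasing in the demand/supply ratio; lease flows sum to zero across
fleets by construction.

## The management procedure

Observation: landings are exact (logbooks); discards are estimated by
expanding the observed coverage fraction (25%) with binomial sampling error
over trip units (unbiased by construction); strategies with a
fishery-independent survey receive a mean-unbiased lognormal biomass index
and their assessment CVs shrink by a factor 0.75.

Assessment is deliberately not an estimation model: it is a one-year-lagged,
median-unbiased lognormal corruption of true biomass with tier-dependent CV
(0.20/0.30/0.40 for data-rich to data-poor tiers). The mechanism under
study is error and lag in the decision loop, not assessment internals.

The tiered harvest control rule is the standard limit/target ramp: $F = 0$
at or below $0.2\,B_0$, rising linearly to $F_{target} \cdot buffer$ at
$0.4\,B_0$, with tier buffers 1.0/0.9/0.8 and $F_{target} = 0.9\,M$. The
ramp parameters are exposed in the scenario configuration; the defaults are
this package's reconstruction of a generic tiered rule, not an assertion
about any particular jurisdiction's values. The status-quo strategy instead
uses a catch-trend TAC: the slope of log observed catch over a 3-year
window, clamped to ±20% per year — a deliberately weak feedback rule.

TAC construction applies, per strategy: regional splitting by biomass
share, basket quotas (one cumulative record per basket), discard accounting
(landed TAC = RBC − expected discards, floored at zero) and companion links
with weak-stock limiting — exhaustion of any linked member halts directed
fishing on the whole link, with forgone quota recorded as undercatch. The
proportional-scaling alternative for companions was rejected because it
cannot produce the large undercatch effect the weak-stock rule exists to
express. Reconciliation is either continuous ("before landing": every
event must be covered at that moment, shortfalls beyond available leases
are forfeited and penalised) or annual (landings accumulate freely; one
year-end reconciliation after leasing records overcatch).

Management costs are built from administration, assessments (scaled by the
number of assessed units over their assessment frequency; trend updates
cost 30% of a dynamic assessment), enforcement (scaled by closed extent and
enforcement level), observers and surveys, and research; the fishery is
cost-recovered, so the per-boat levy is total cost over active vessels.

## The four packaged strategies

The packaged configurations mirror a published four-way strategy contrast
control-for-control (TAC method, assessment frequency, species counts 17 /
30 / 17+gulper / 17, tiers, baskets, companions, discard accounting,
regional TACs, reconciliation timing, zoning extent, mesh sizes, BRD effect
up to 0.8, observer coverage 0.25, surveys, buyback in projection year 5,
gear-switching permissions, compliance enforcement). The literal control
table ships as `inst/extdata/strategy_controls.csv` and a table-driven test
asserts the configurations field-for-field. Choices the source table left
qualitative are resolved here and exposed as configuration: "variable"
compliance enforcement is 0.2/0.4/0.5 for the first three strategies and
0.95 for the conservation strategy; voluntary versus compulsory spawning
closures differ only through compliance; the conservation zoning closes the
inshore strip and everything in the deep stratum to all gears and ~80% of
the remainder to bottom gears (≥80% of the biogenic habitat area ends up
closed to bottom contact).

## The synthetic scenario and what it is for

There are no data accessions in this study: the reference scenario is the
experiment. Its parameter values (growth rates 0.06–1.5 /yr spanning
seabirds to squid, carrying capacities, availability matrix, catchabilities,
prices, cost rates) were chosen once to express a coherent bioeconomic
regime — a fishery that is marginally profitable at its historical effort
level, capable of depleting its stocks under weak feedback management, and
capable of rebuilding under strong constraint — and the packaged
calibration is explicitly tuned so the reference experiment expresses the
qualitative strategy ordering the framework exists to study: the
conservation-dominated strategy is ecologically best and economically
worst, the status quo is ecologically worst, and the integrated strategy is
nowhere the worst of the four. That ordering, not any absolute number, is
the reproducible claim; the tests assert it holds in at least 8 of 10
ensemble members.

Ecology is deterministic in the packaged conditions (recruitment deviates
are implemented but default to zero); uncertainty enters through a
10-member ensemble of mean-preserving lognormal parameter perturbations
(CV 0.10 on growth and catchability and price, 0.05 on steepness) and a
structural recruitment variant. All randomness flows from integer seeds
through named streams — ecology keyed to the scenario seed, fleet behaviour
and observation to the run seed — so every strategy within a member
experiences identical ecological noise: a paired-comparison design.

What passing tests do **not** show about real fisheries: the scenario has
no environmental forcing, no age structure, no within-box spatial texture
beyond the open-fraction reserve effect, exogenous prices, one compliance
trait per fleet rather than a distribution of personalities, and an
assessment that never mis-specifies its model. Results are orderings among
strategy archetypes under these conditions, not forecasts.

## Numerical choices and degenerate inputs

* Quantiles for ensemble bands use the linear-interpolation rule (type 7),
  fixed for cross-platform reproducibility.
* Normalisation of indicators: starred (lower-is-better) indicators are
  reflected as $x \to x_{max} - x$ with the maximum over all strategies and
  years jointly; indicators that can be legitimately negative (profits) are
  shifted so the joint minimum is zero before scaling; constant indicators
  map to 1 everywhere. Reflection rather than reciprocals preserves
  linearity and keeps zeros meaningful.
* Ratios with zero denominators (profit per tonne with zero landings, levy
  per boat with no active vessels) are reported as missing, never infinite.
* Composite class scores are equal-weighted means (weights configurable);
  the class map follows the indicator catalogue's class column. The loss
  penalty doubles negative profits before normalisation; the public-image
  index is the mean of relative ecosystem state, relative port population
  and a positive-profit indicator — its three named ingredients.
* The spec of a quota unit is resolved left to right: a group belongs to
  its basket if it is a basket member, else to its own single-species unit.
* Degenerate scenarios (a group with zero growth, all boxes closed with
  full compliance, zero observer coverage with discard accounting) warn or
  flag rather than fail silently; negative removals and negative prices are
  hard errors.

## Problem sizes

The packaged experiments use 12 groups × 6 boxes × 4 fleets over 60 years
(10 burn-in + 10 historical + 40 projection, the upper end of the framework
range so slow deep-water dynamics can express), and ensembles of 10
members. A single strategy run takes a few seconds; the full 40-run
ensemble a few minutes. The test suite exercises the same sizes.

## Known limitations

Baskets and companion links are resolved against the groups present in a
scenario, so small test scenarios silently drop them. The lease market is
one clearing per year per unit with a scarcity-slope price — enough for the
trading-volume indicator and the broker dynamic, not a market
microstructure. Gear switching is restricted to the bottom-trawl-to-static
move that matters for the packaged contrast. Port populations respond to
landings through a saturating activity index with inertia; they are a
social indicator, not a demographic model.
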