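# shelfmse

Closed-loop **management strategy evaluation (MSE)** for a multispecies,
multi-fleet shelf and slope fishery, at desk scale.

Fisheries agencies weighing ecosystem-based management face a genuine
design question: should they double down on quota machinery, on gear and
effort controls, on large spatial closures — or on an integrated mix?
`shelfmse` is for modellers and fisheries scientists who want to study that
question as a closed simulation loop: a spatial multispecies operating
model (the "truth") is fished by profit-driven fleets, observed with error,
assessed, and managed by a configurable procedure, and the consequences are
scored against ecological, economic, social, industry, operator and
management-cost objectives simultaneously.

## The core of the method

An MSE couples three models and a scoring rule:

* **Operating model** — biomass dynamics for 12 functional groups in 6
  depth-stratified boxes on a quarterly step:
  logistic production with explicit Beverton–Holt recruitment
  (R = 4hR₀s / ((1−h) + (5h−1)s)), Holling type-II trophic mortality over
  an availability matrix, habitat cover H′ = H + ρH(1−H) − ι·(swept/area)·H
  impacted by bottom-contact gear, a discard-fed detritus–scavenger loop,
  and capacity-directed mobility. Every quarterly step carries an exact
  flux ledger (B′ = B + P − T − N − R − I + mobility).
* **Fleet dynamics** — effort allocated by a softmax on expected profit per
  vessel-day with inertia and a stochastic non-compliant fraction; catch
  C = q·sel(mesh)·E·B/area with the open-fraction reserve effect in closed
  areas; bycatch-reduction devices, baseline and quota-driven discarding;
  an annual quota lease market; exact profit accounting; loss-driven exit,
  latency, re-entry, gear switching and a licence buyback.
* **Management procedure** — logbook-exact landings, observer-expanded
  discard estimates, optional survey; model-free lagged assessments with
  tier-dependent CV; a tiered harvest control rule (F ramps linearly from 0
  at 0.2·B₀ to F_target·buffer at 0.4·B₀; RBC = F·B̂) or a clamped
  catch-trend TAC; regional, basket and companion ("weak-stock limiting")
  quotas; discard accounting; at-landing or annual reconciliation; zoning
  and gear controls; cost-recovered management costs.
* **Scoring** — a catalogue of ~30 annual performance indicators in six
  objective classes; lower-is-better indicators are inverted (x → x_max −
  x), everything is normalised jointly over strategies and years so the
  best value is 1, and class means give the composite "kite" scores.

Four packaged strategies (`S1_status_quo`, `S2_enhanced_quota`,
`S3_integrated`, `S4_conservation`) mirror a published four-way strategy
contrast control-for-control; the literal control table ships in
`inst/extdata/strategy_controls.csv`.

## A worked example

```r
library(shelfmse)

cfg <- generate_scenario("reference", seed = 1)   # 12 groups x 6 boxes x 4 fleets
eq  <- initialize_equilibrium(cfg)                # unfished fixed point
res <- run_mse(cfg, strategy_config("S4_conservation", cfg),
               seed = 1, equilibrium = eq)
tail(res$annual[, c("year", "landings", "gvp", "profit", "active_vessels")], 1)
```

Running the numbered drivers under `analysis/` reproduces the full
comparison. `analysis/02_run_strategies.R` prints, for the final projection
year (paired seeds, so all strategies share the same burn-in and history):

```
S1_status_quo      final year: landings  12291 t, GVP  29.5 M$, profit  -3.21 M$,  39 active vessels
S2_enhanced_quota  final year: landings   5562 t, GVP  21.8 M$, profit  -1.30 M$,  31 active vessels
S3_integrated      final year: landings   1712 t, GVP   8.6 M$, profit  -5.53 M$,  16 active vessels
S4_conservation    final year: landings    254 t, GVP   1.2 M$, profit  -8.01 M$,   5 active vessels
```

Read: the status quo keeps fishing hard (effort only −4% from its
historical level) and ends with the most degraded habitat (cover 0.883 vs
0.956 under conservation zoning); the conservation strategy shutters the
fleet. `analysis/04_kite_composites.R` aggregates the 10-member ensemble
into final-year composite class scores (1 = best observed anywhere):

```
           class S1_status_quo S2_enhanced_quota S3_integrated S4_conservation
        industry          0.58              0.77          0.69            0.64
        operator          0.98              0.94          0.85            0.72
 management_cost          0.93              0.43          0.65            0.39
          social          0.74              0.67          0.58            0.54
        economic          0.68              0.71          0.67            0.59
      ecological          0.72              0.77          0.80            0.83
```

and reports that the qualitative trade-off pattern — conservation best
ecologically and worst economically, status quo worst ecologically, and the
integrated strategy nowhere the worst of the four — holds in 10 of 10
ensemble members. That ordering (not any absolute dollar or tonne) is the
reproducible result: the kite diagram's lopsided conservation shape, the
status quo's ecological collapse, and the integrated strategy's even
performance across every axis.

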