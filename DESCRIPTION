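Package: shelfmse
Title: Closed-Loop Management Strategy Evaluation for a Multispecies Shelf Fishery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale management strategy evaluation (MSE) framework for a
    synthetic temperate shelf and slope fishery. Couples a quarterly
    multispecies spatial operating model (biomass dynamics with trophic
    interactions, habitat impacts of bottom-contact gear and a discard-fed
    detritus-scavenger loop) to fleet dynamics (profit-driven effort
    allocation with inertia and compliance, quota trading, discarding and
    participation decisions) and a configurable management procedure
    (observation error, tiered harvest control rules, basket and companion
    quotas, regional TACs, reconciliation timing, zoning and gear controls).
    Evaluates four packaged management strategies (status quo, enhanced
    quota, integrated, conservation dominated) against a catalogue of
    ecological, economic, social and management performance indicators,
    normalised and aggregated into composite trade-off (kite) scores, with
    ensemble runs summarised by quartile bands.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
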