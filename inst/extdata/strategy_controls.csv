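control,S1_status_quo,S2_enhanced_quota,S3_integrated,S4_conservation
tac_method,catch_trend,dynamic_assessment,dynamic_assessment,dynamic_assessment
assessment_frequency_min_years,1,1,1,1
assessment_frequency_max_years,1,3,3,3
n_species_under_tac,17,30,18,17
tiered_hcr,no,yes,yes,yes
non_quota_baskets,no,yes,yes,no
companion_tacs_weak_stock,no,yes,yes,no
discard_accounting,no,no,yes,yes
regional_tacs,no,yes,yes,yes
reconciliation,annual,at_landing,at_landing,at_landing
trawl_mesh_mm,90,90,100,110
danish_seine_mesh_mm,38,38,38,45
brd_effect,0,0.8,0.8,0.8
buyback_year,NA,NA,NA,5
gear_switching_allowed,no,no,yes,yes
observer_coverage,0.25,0.25,0.25,0.25
fishery_independent_survey,no,yes,no,yes
discard_monitoring_enforcement,no,no,yes,no
compliance_enforcement,variable,variable,variable,high
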