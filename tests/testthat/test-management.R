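test_that("observation model: exact landings, unbiased discard expansion", {
  cfg <- ref_cfg()
  st <- strategy_config("S1_status_quo", cfg)
  truth <- list(landings = c(flathead = 500, ling = 200),
                discards = c(flathead = 100, ling = 40),
                biomass = matrix(c(1e4, 5e3), 2, 1,
                                 dimnames = list(c("flathead", "ling"), "all")))
  rng <- shelfmse:::make_rng(4, "observation")
  obs <- simulate_observation(truth, st, cfg, rng)
  expect_identical(obs$landings, truth$landings)
  # coverage 1 reproduces true discards exactly
  st1 <- st; st1$observer_coverage <- 1
  obs1 <- simulate_observation(truth, st1, cfg, rng)
  expect_identical(obs1$discards_est, truth$discards)
  # 25% coverage: unbiased over replicates
  est <- replicate(2000, simulate_observation(truth, st, cfg,
                                              rng)$discards_est[["flathead"]])
  expect_equal(mean(est), 100, tolerance = 0.03)
  # no survey under S1; survey index present under S2
  expect_null(obs$survey_index)
  st2 <- strategy_config("S2_enhanced_quota", cfg)
  truth2 <- truth
  obs2 <- simulate_observation(truth2, st2, cfg, rng)
  expect_false(is.null(obs2$survey_index))
  # zero coverage with discard accounting flags the gap
  st0 <- strategy_config("S3_integrated", cfg)
  st0$observer_coverage <- 0
  obs0 <- simulate_observation(truth, st0, cfg, rng)
  expect_true(all(is.na(obs0$discards_est)))
  expect_true("discard_accounting_without_coverage" %in% obs0$flags)
})

test_that("catch-trend TAC follows and clamps the log-catch slope", {
  p <- list(trend_window = 3, trend_max_step = 0.2)
  expect_equal(trend_tac(c(100, 100, 100), 50, p), 50)
  # +10%/yr: multiplier is exp-slope of the log series, about 1.10
  up <- 100 * 1.1^(0:2)
  expect_equal(trend_tac(up, 50, p), 50 * (1 + log(1.1)), tolerance = 1e-9)
  # collapsing catches clamp at the maximum step down
  down <- c(400, 200, 100)
  expect_equal(trend_tac(down, 50, p), 50 * 0.8)
  # short series: held constant
  expect_equal(trend_tac(c(100, 90), 50, p), 50)
})

test_that("dynamic assessment is lagged truth with tiered lognormal error", {
  p <- ref_cfg()$params
  a0 <- dynamic_assessment(1234, tier = 1, survey = FALSE, p, rng = NULL)
  expect_equal(a0$B_hat, 1234)
  expect_gt(p$tier_cv[3], p$tier_cv[1])
  expect_lt(dynamic_assessment(1, 2, TRUE, p)$cv,
            dynamic_assessment(1, 2, FALSE, p)$cv)
  rng <- shelfmse:::make_rng(8, "observation")
  draws <- vapply(1:4000, function(i)
    dynamic_assessment(1000, 2, FALSE, p, rng)$B_hat, numeric(1))
  expect_equal(stats::median(draws) / 1000, 1, tolerance = 0.02)
})

test_that("tiered HCR matches the limit/target ramp", {
  p <- ref_cfg()$params
  refs <- list(B0 = 1000, lim_frac = 0.2, targ_frac = 0.4, F_target = 0.2)
  mk <- function(B_hat, tier = 1) list(B_hat = B_hat, tier = tier)
  expect_equal(tiered_hcr(mk(100), refs, p), 0)     # below limit
  expect_equal(tiered_hcr(mk(200), refs, p), 0)     # at limit
  expect_equal(tiered_hcr(mk(400), refs, p), 0.2 * 400)  # at target
  expect_equal(tiered_hcr(mk(300), refs, p), 0.1 * 300)  # ramp midpoint
  # tier buffers shrink the allowed F for data-poor tiers
  expect_gt(tiered_hcr(mk(400, 1), refs, p), tiered_hcr(mk(400, 3), refs, p))
  expect_error(tiered_hcr(mk(400), list(B0 = NA, lim_frac = 0.2,
                                        targ_frac = 0.4, F_target = 0.2), p),
               "reference point")
})

test_that("TAC construction: regions, baskets, discard discount, companions", {
  cfg <- ref_cfg()
  st3 <- strategy_config("S3_integrated", cfg)
  rbcs <- stats::setNames(rep(100, length(unlist(tac_units(st3)))),
                          unlist(tac_units(st3)))
  # discard accounting: landed TAC = RBC - expected discards
  disc <- stats::setNames(rep(0, nrow(cfg$groups)), cfg$groups$id)
  disc["flathead"] <- 20
  tt <- set_tacs(rbcs, st3, discard_estimates = disc, year = 1)
  fl_tac <- sum(tt$records$tac[tt$records$unit == "flathead"])
  expect_equal(fl_tac, 80)
  # basket: one cumulative record summing member RBCs
  expect_true("minor_demersal" %in% tt$records$unit)
  bk <- sum(tt$records$tac[tt$records$unit == "minor_demersal"])
  expect_equal(bk, sum(rbcs[st3$baskets$minor_demersal]) -
                 sum(disc[st3$baskets$minor_demersal]))
  # regional split follows the share matrix
  shares <- matrix(0.5, nrow(cfg$groups), 2,
                   dimnames = list(cfg$groups$id, c("east", "west")))
  shares[, 1] <- 0.7; shares[, 2] <- 0.3
  tt2 <- set_tacs(c(flathead = 100), st3, region_share = shares, year = 1)
  r <- tt2$records[tt2$records$unit == "flathead", ]
  expect_equal(r$tac[r$region == "east"], 70)
  expect_equal(r$tac[r$region == "west"], 30)
  expect_error(set_tacs(c(flathead = -5), st3), "negative")
  # companion link: exhausting the weak stock halts the pair
  tt3 <- set_tacs(rbcs, st3, year = 1)
  i_g <- tt3$records$unit == "gulper_shark"
  tt3$records$landed[i_g] <- tt3$records$tac[i_g]
  tt3 <- shelfmse:::update_companion_state(tt3)
  expect_true(any(tt3$halted))
  expect_true(all(c("ling", "gulper_shark") %in% shelfmse:::halted_groups(tt3)))
})

test_that("reconciliation ledgers match the worked examples", {
  st <- strategy_config("S2_enhanced_quota", ref_cfg())
  base_tt <- list(records = data.frame(unit = "sp", region = "all", year = 1,
                                       tac = 100, landed = 0, overcatch = 0,
                                       undercatch = 0),
                  units = list(sp = "sp"), companion_links = list(),
                  halted = logical(0))
  class(base_tt) <- "tac_table"
  ev <- data.frame(unit = "sp", region = "all", tonnes = c(60, 50))
  # at landing, no lease: second event covers 40, forfeits 10
  r1 <- reconcile(base_tt, ev, "at_landing", lease_available = 0)
  expect_equal(r1$covered, c(60, 40))
  expect_equal(r1$forfeited, c(0, 10))
  expect_equal(r1$overcatch, 10)
  expect_equal(r1$tt$records$landed, 100)
  # annual timing with 10 t leased at year end: zero forfeits
  r2 <- reconcile(base_tt, ev, "annual", lease_available = c(sp = 10))
  expect_equal(r2$overcatch, 0)
  expect_equal(r2$leased_used, 10)
  expect_equal(r2$tt$records$landed, 110)
  # zero landings: no change
  ev0 <- ev[0, ]
  r3 <- reconcile(base_tt, ev0, "at_landing")
  expect_identical(r3$tt$records, base_tt$records)
})

test_that("management cost accounts scale with units, vessels, coverage", {
  cfg <- ref_cfg()
  fl <- cfg$fleets
  s2 <- strategy_config("S2_enhanced_quota", cfg)  # 30 assessed units
  s3 <- strategy_config("S3_integrated", cfg)      # 18 assessed units
  c2 <- management_costs(s2, fl, cfg)
  c3 <- management_costs(s3, fl, cfg)
  expect_gt(c2$assessment, c3$assessment)
  # cost recovery: the per-boat levy is exactly total over active vessels,
  # so halving the fleet at a fixed total doubles it
  c_full <- management_costs(s3, fl, cfg)
  expect_equal(c_full$levy_per_boat, c_full$total / sum(fl$active_vessels))
  fl_half <- fl
  fl_half$active_vessels <- as.integer(round(fl$active_vessels / 2))
  c_half <- management_costs(s3, fl_half, cfg)
  expect_equal(c_half$levy_per_boat, c_half$total / sum(fl_half$active_vessels))
  expect_gt(c_half$levy_per_boat, c_full$levy_per_boat)
  # zero observer coverage and no survey: monitoring component is zero
  s0 <- s3; s0$observer_coverage <- 0
  expect_equal(management_costs(s0, fl, cfg)$monitoring, 0)
  # no active vessels: levy reported as missing
  fl0 <- fl; fl0$active_vessels <- 0L
  expect_true(is.na(management_costs(s3, fl0, cfg)$levy_per_boat))
})

test_that("strategy zoning encodes the depth rules", {
  cfg <- ref_cfg()
  s4 <- strategy_config("S4_conservation", cfg)
  deep <- cfg$boxes$depth_stratum == "deep"
  expect_true(all(s4$zoning[deep, ] == 0))
  expect_true(all(s4$zoning["inshore_e", ] == 0))
  s1 <- strategy_config("S1_status_quo", cfg)
  expect_gte(min(s1$zoning), 0.9)
  expect_error(strategy_config("S9_bogus", cfg), "unknown strategy")
})

test_that("strategy serialisation round-trips", {
  s3 <- strategy_config("S3_integrated", ref_cfg())
  path <- tempfile(fileext = ".json")
  write_strategy(s3, path)
  back <- read_strategy(path)
  expect_identical(back$zoning, s3$zoning)
  expect_identical(back$mesh_mm, s3$mesh_mm)
  expect_identical(back$companion_links, s3$companion_links)
  expect_identical(back$reconciliation, s3$reconciliation)
  unlink(path)
})
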