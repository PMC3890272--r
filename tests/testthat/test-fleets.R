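test_that("larger mesh monotonically lowers selectivity for small fish", {
  sizes <- c(12, 25, 35, 75)
  meshes <- c(90, 100, 110)
  sel <- sapply(meshes, function(m) gear_selectivity(sizes, m, 0.25))
  for (i in seq_along(sizes))
    expect_true(all(diff(sel[i, ]) < 0), info = paste("size", sizes[i]))
})

test_that("effort allocation honours symmetry, limits and zoning", {
  cfg <- min_cfg()
  st <- strategy_config("S1_status_quo", cfg)
  st$zoning[] <- 1
  fl <- cfg$fleets
  fl$compliance_trait <- 1
  cfg2 <- cfg
  cfg2$params$inertia <- 0
  # equal expected profit, zero inertia -> equal shares
  ex <- matrix(100, 1, 2, dimnames = list(fl$id, cfg$boxes$id))
  E <- allocate_effort(fl, ex, st, cfg2)
  expect_equal(E[1, 1], E[1, 2])
  # temperature -> 0 puts all effort in the argmax box
  cfg3 <- cfg2
  cfg3$params$softmax_temp <- 0
  ex2 <- ex; ex2[1, 2] <- 200
  E2 <- allocate_effort(fl, ex2, st, cfg3)
  expect_equal(E2[1, 1], 0)
  expect_gt(E2[1, 2], 0)
  # fully closed box with full compliance -> exactly zero effort there
  st2 <- st; st2$zoning["b1", ] <- 0
  E3 <- allocate_effort(fl, ex, st2, cfg2)
  expect_identical(E3[1, "b1"], 0)
  # all boxes closed, compliance 1 -> zero effort, not an error
  st3 <- st; st3$zoning[] <- 0
  expect_silent(E4 <- allocate_effort(fl, ex, st3, cfg2))
  expect_true(all(E4 == 0))
})

test_that("non-compliant effort appears in closed boxes in expectation", {
  cfg <- min_cfg()
  cfg$params$inertia <- 0
  st <- strategy_config("S1_status_quo", cfg)
  st$zoning[] <- 1
  st$zoning["b1", ] <- 0
  st$enforcement_level <- 0
  fl <- cfg$fleets
  fl$compliance_trait <- 0.5
  ex <- matrix(100, 1, 2, dimnames = list(fl$id, cfg$boxes$id))
  rng <- shelfmse:::make_rng(2, "fleet")
  closed_share <- replicate(400, {
    E <- allocate_effort(fl, ex, st, cfg, rng = rng)
    E[1, "b1"] / sum(E)
  })
  # half the effort is non-compliant; it splits evenly over the two boxes
  expect_equal(mean(closed_share), 0.25, tolerance = 0.02)
  expect_lte(max(closed_share), 0.5 + 1e-9)
})

test_that("harvest follows the catch equation and caps at availability", {
  cfg <- min_cfg()
  cfg$boxes$area_km2 <- c(1000, 1000)
  st <- strategy_config("S1_status_quo", cfg)
  fl <- cfg$fleets
  state <- initial_state(cfg)
  state$B["fish", ] <- c(1000, 500)
  E <- matrix(c(10, 0), 1, 2, dimnames = list(fl$id, cfg$boxes$id))
  hv <- harvest(E, state, fl, st, cfg)
  sel <- gear_selectivity(state$size["fish"], st$mesh_mm["trawl"],
                          fl$sel_l50_factor)
  oracle <- cfg$q[1, "fish"] * sel * 10 * 1000 / 1000
  expect_equal(hv$catch[1, "fish", "b1"], unname(oracle), tolerance = 1e-12)
  expect_equal(hv$catch[1, "fish", "b2"], 0)
  expect_equal(hv$swept[1, 1], 10 * fl$sweep_km2_day)
  # zero effort -> zero catch
  hv0 <- harvest(E * 0, state, fl, st, cfg)
  expect_true(all(hv0$catch == 0))
  # availability cap binds for absurd effort
  Ebig <- E; Ebig[1, 1] <- 1e6
  hvb <- harvest(Ebig, state, fl, st, cfg)
  expect_lte(hvb$catch[1, "fish", "b1"],
             cfg$params$avail_cap * state$B["fish", "b1"] + 1e-9)
})

test_that("retention ledger is exact and quota drives discarding", {
  cfg <- ref_cfg()
  st2 <- strategy_config("S2_enhanced_quota", cfg)
  state <- ref_eq()
  fl <- cfg$fleets
  E <- matrix(200, nrow(fl), nrow(cfg$boxes),
              dimnames = list(fl$id, cfg$boxes$id))
  hv <- harvest(E, state, fl, st2, cfg)
  rbcs <- stats::setNames(rep(1000, nrow(cfg$groups)), cfg$groups$id)
  tt <- set_tacs(rbcs[unlist(tac_units(st2))], st2, year = 1)
  rt <- retention(hv$catch, tt, st2, cfg)
  # exact ledger: landings + discards = post-BRD catch, every cell
  expect_lt(max(abs(rt$landings + rt$discards - rt$post_brd)), 1e-9)
  # BRD: bycatch-guild catch scaled by 1 - brd_effect before retention
  i_by <- which(cfg$groups$guild %in% c("bycatch", "TEP"))
  expect_equal(rt$post_brd[, i_by, ],
               hv$catch[, i_by, ] * (1 - st2$brd_effect), tolerance = 1e-12)
  # zero remaining quota for one species -> fully discarded (at-landing)
  tt0 <- tt
  i_fl <- tt0$records$unit == "flathead"
  tt0$records$landed[i_fl] <- tt0$records$tac[i_fl]
  rt0 <- retention(hv$catch, tt0, st2, cfg)
  expect_equal(sum(rt0$landings[, "flathead", ]), 0)
  expect_equal(sum(rt0$discards[, "flathead", ]),
               sum(rt0$post_brd[, "flathead", ]))
})

test_that("unconstrained retention keeps the whole catch", {
  cfg <- min_cfg()
  st <- strategy_config("S1_status_quo", cfg)
  st$brd_effect <- 0
  catch <- array(5, c(1, 2, 2),
                 dimnames = list(cfg$fleets$id, cfg$groups$id, cfg$boxes$id))
  catch[, "detritus", ] <- 0
  tt <- set_tacs(c(fish = 1e6), st, year = 1)
  rt <- retention(catch, tt, st, cfg)
  expect_equal(rt$landings[, "fish", ], catch[, "fish", ])
  expect_true(all(rt$discards[, "fish", ] == 0))
})

test_that("quota lease market clears at scarcity-dependent prices", {
  pars <- ref_cfg()$params
  # abundant supply: floor price, all demand met
  r1 <- trade_quota(c(a = 1000), c(a = 10), c(a = 5000), pars)
  expect_equal(r1$volume, 10)
  expect_equal(r1$lease_price, pars$lease_price_frac * 5000)
  # zero supply: no volume
  r2 <- trade_quota(c(a = 0), c(a = 50), c(a = 5000), pars)
  expect_equal(r2$volume, 0)
  # binding supply: volume = supply, price above floor
  r3 <- trade_quota(c(a = 50), c(a = 80), c(a = 5000), pars)
  expect_equal(r3$volume, 50)
  expect_gt(r3$lease_price, pars$lease_price_frac * 5000)
})

test_that("fleet economics identity holds exactly", {
  cfg <- min_cfg()
  fl <- cfg$fleets
  land <- matrix(c(100, 0), 1, 2, dimnames = list(fl$id, cfg$groups$id))
  eff <- list(days = 50, dist_km_days = 1000)
  acc <- fleet_economics(land, c(fish = 3000, detritus = 0), eff, fl,
                         levies = 10000, lease_net = 500)
  expect_identical(acc$profit,
                   acc$gvp + acc$lease_net - acc$costs - acc$levy)
  expect_equal(acc$gvp, 300000)
  # zero effort and landings: profit is minus fixed costs (and levies)
  acc0 <- fleet_economics(land * 0, c(fish = 3000, detritus = 0),
                          list(days = 0, dist_km_days = 0), fl)
  expect_equal(acc0$profit, -fl$fixed_cost_yr * fl$active_vessels)
  expect_true(is.na(acc0$profit_per_tonne))
  expect_true(is.na(acc0$profit_per_effort))
  # doubling prices doubles GVP exactly
  acc2 <- fleet_economics(land, c(fish = 6000, detritus = 0), eff, fl)
  expect_equal(acc2$gvp, 2 * acc$gvp)
  expect_error(fleet_economics(land, c(fish = -1, detritus = 0), eff, fl),
               "negative price")
})

test_that("participation rules: loss-streak exit, buyback, gear lock", {
  cfg <- ref_cfg()
  st <- strategy_config("S1_status_quo", cfg)
  fl <- cfg$fleets
  fl$debt <- 0; fl$loss_streak <- 0L
  pr <- stats::setNames(rep(-1, nrow(fl)), fl$id)
  f1 <- fl
  for (i in 1:3) f1 <- update_participation(f1, pr, st, cfg)
  expect_true(all(f1$active_vessels < fl$active_vessels))
  expect_equal(f1$active_vessels + f1$latent_vessels,
               fl$active_vessels + fl$latent_vessels)
  # two loss years: no exit yet
  f2 <- fl
  for (i in 1:2) f2 <- update_participation(f2, pr, st, cfg)
  expect_equal(f2$active_vessels, fl$active_vessels)
  # buyback retires latent licences first: active capacity unchanged
  st4 <- strategy_config("S4_conservation", cfg)
  st4$buyback_licences <- 6L
  fb <- fl
  fb$active_vessels <- rep(4L, nrow(fb))
  fb$latent_vessels <- rep(6L, nrow(fb))
  pr0 <- stats::setNames(rep(1, nrow(fl)), fl$id)
  fb2 <- update_participation(fb, pr0, st4, cfg, projection_year = 5)
  expect_equal(fb2$active_vessels, fb$active_vessels)
  expect_equal(sum(fb$latent_vessels) - sum(fb2$latent_vessels), 6)
  # gear is immutable when the strategy forbids switching
  fs <- fl; fs$loss_streak <- 5L
  fs2 <- update_participation(fs, pr, st, cfg,
                              expected_profit_by_gear = list(
                                bottom_trawl = -100, gillnet = 1e6))
  expect_identical(fs2$gear, fl$gear)
})

test_that("with zero prices everywhere the fishery winds down completely", {
  cfg <- min_cfg()
  cfg$groups$price[] <- 0
  res <- run_mse(cfg, strategy_config("S1_status_quo", cfg), 1)
  expect_equal(utils::tail(res$annual$active_vessels, 1), 0)
  expect_equal(utils::tail(res$annual$effort_days, 1), 0)
})
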