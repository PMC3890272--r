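test_that("pure logistic single-group config equilibrates at K", {
  cfg <- logistic_cfg(K = 1000)
  eq <- initialize_equilibrium(cfg, tol = 1e-12)
  expect_equal(unname(eq$B["fish", ]), c(1000, 1000), tolerance = 1e-8)
})

test_that("reference equilibrium is a fixed point of the unfished map", {
  cfg <- ref_cfg()
  eq <- ref_eq()
  nx <- step_quarter(eq, zero_mat(cfg), zero_swept(cfg), cfg)
  expect_lt(max(abs(nx$B - eq$B) / pmax(eq$B, 1e-6)), 1e-6)
  # tighter check at the solver's own tolerance
  expect_lt(max(abs(nx$B - eq$B) / pmax(eq$B, 1e-6)), 1e-8)
})

test_that("zero-growth non-detritus group triggers a warning", {
  cfg <- min_cfg()
  cfg$groups$r[1] <- 0
  cfg$groups$rec_share[1] <- 0
  expect_warning(try(initialize_equilibrium(cfg, max_iter = 200), silent = TRUE),
                 "zero growth")
})

test_that("quarterly step satisfies the exact biomass ledger", {
  cfg <- ref_cfg()
  eq <- ref_eq()
  set.seed(11)
  for (rep in 1:5) {
    rem <- matrix(stats::runif(length(eq$B), 0, 0.05), nrow(eq$B)) * eq$B
    swept <- matrix(stats::runif(nrow(cfg$fleets) * nrow(cfg$boxes), 0, 500),
                    nrow(cfg$fleets))
    nx <- step_quarter(eq, rem, swept, cfg)
    led <- attr(nx, "ledger")
    recon <- eq$B + led$production - led$predation - led$natural -
      led$removals - led$incidental + led$mobility_net
    det <- which(cfg$groups$guild == "detritus")
    # fish rows follow the biomass ledger exactly
    expect_lt(max(abs((nx$B - recon)[-det, ])), 1e-8)
    # detritus row additionally gains its inputs minus decay
    dl <- led$detritus
    expect_equal(unname(nx$B[det, ]),
                 unname(recon[det, ] + dl$inputs - dl$decay),
                 tolerance = 1e-8)
  }
})

test_that("state at equilibrium is unchanged by an unfished step", {
  cfg <- ref_cfg()
  eq <- ref_eq()
  nx <- step_quarter(eq, zero_mat(cfg), zero_swept(cfg), cfg)
  expect_equal(nx$B, eq$B, tolerance = 1e-8)
  expect_equal(nx$H, eq$H, tolerance = 1e-12)
})

test_that("negative removals are rejected and over-removals capped", {
  cfg <- min_cfg()
  eq <- initialize_equilibrium(cfg)
  bad <- zero_mat(cfg); bad[1, 1] <- -5
  expect_error(step_quarter(eq, bad, zero_swept(cfg), cfg), "negative")
  huge <- zero_mat(cfg); huge[1, 1] <- eq$B[1, 1] * 2
  expect_warning(nx <- step_quarter(eq, huge, zero_swept(cfg), cfg), "capped")
  expect_true(all(nx$B >= 0))
})

test_that("removing prey lowers predator realised growth next quarter", {
  cfg <- ref_cfg()
  eq <- ref_eq()
  rem <- zero_mat(cfg)
  i_prey <- which(cfg$groups$id == "small_pelagic")
  rem[i_prey, ] <- 0.10 * eq$B[i_prey, ]
  base <- step_quarter(eq, zero_mat(cfg), zero_swept(cfg), cfg)
  hit <- step_quarter(eq, rem, zero_swept(cfg), cfg)
  # second step: predator production with vs without the prey removal
  base2 <- attr(step_quarter(base, zero_mat(cfg), zero_swept(cfg), cfg),
                "ledger")
  hit2 <- attr(step_quarter(hit, zero_mat(cfg), zero_swept(cfg), cfg),
               "ledger")
  i_pred <- which(cfg$groups$id == "mackerel")
  expect_lt(sum(hit2$production[i_pred, ]), sum(base2$production[i_pred, ]))
})

test_that("Beverton-Holt recruitment matches its closed form", {
  grp <- data.frame(steepness = 0.75, rec_form = "beverton_holt", rec_sigma = 0)
  pars <- list(R0 = 500, B0 = 10000)
  expect_identical(recruit(grp, 0, pars), 0)
  expect_equal(recruit(grp, 10000, pars), 500, tolerance = 1e-12)
  # closed form at S = 0.2 B0: 4h R0 s / ((1-h) + (5h-1)s), s = 0.2
  h <- 0.75; s <- 0.2
  oracle <- 4 * h * 500 * s / ((1 - h) + (5 * h - 1) * s)
  expect_equal(recruit(grp, 2000, pars), oracle, tolerance = 1e-12)
  grp2 <- grp; grp2$rec_form <- "hockey_stick"
  expect_equal(recruit(grp2, 10000, pars), 500)
  expect_equal(recruit(grp2, 1000, pars), 250)  # below the 0.2 B0 hinge
  bad <- grp; bad$steepness <- 0.1
  expect_error(recruit(bad, 100, pars), "steepness")
  bad2 <- grp; bad2$steepness <- 1.2
  expect_error(recruit(bad2, 100, pars), "steepness")
})

test_that("recruitment deviates are mean-unbiased", {
  grp <- data.frame(steepness = 0.75, rec_form = "beverton_holt",
                    rec_sigma = 0.6)
  pars <- list(R0 = 100, B0 = 1000)
  rng <- shelfmse:::make_rng(3, "test")
  draws <- vapply(1:4000, function(i) recruit(grp, 1000, pars, rng), numeric(1))
  expect_equal(mean(draws), 100, tolerance = 0.05)
})

test_that("habitat dynamics hit their fixed points", {
  cfg <- min_cfg()
  H <- matrix(1, 2, 1, dimnames = list(cfg$boxes$id, "biogenic"))
  expect_equal(update_habitat(H, zero_swept(cfg), cfg), H)
  # full-intensity sweep with impact 1 and no recovery empties the cover
  cfg2 <- cfg
  cfg2$params$impact_rate["bottom_trawl"] <- 1
  cfg2$params$habitat_recovery["biogenic"] <- 0
  H5 <- H * 0.5
  swept <- matrix(cfg$boxes$area_km2, 1, 2)
  expect_equal(unname(update_habitat(H5, swept, cfg2)[, 1]), c(0, 0))
  # periodic sweeping at constant intensity converges to 1 - d/rho
  cfg3 <- cfg
  cfg3$params$impact_rate["bottom_trawl"] <- 0.1
  cfg3$params$habitat_recovery["biogenic"] <- 0.05
  swept3 <- matrix(0.02 * cfg$boxes$area_km2, 1, 2)  # d = 0.1*0.02 = 0.002
  Hc <- H
  for (i in 1:500) Hc <- update_habitat(Hc, swept3, cfg3)
  expect_equal(unname(Hc[, 1]), rep(1 - 0.002 / 0.05, 2), tolerance = 1e-6)
})

test_that("detritus pool decays geometrically and balances its ledger", {
  pars <- list(detritus_decay = 0.2)
  D <- c(100, 50)
  d1 <- update_detritus(D, c(0, 0), c(0, 0), pars)
  expect_equal(as.numeric(d1), D * 0.8)
  d2 <- update_detritus(D, c(10, 5), c(2, 1), pars,
                        natural_dead = c(3, 3), scavenger_consumption = c(4, 2))
  led <- attr(d2, "ledger")
  expect_equal(as.numeric(d2), D + led$inputs - led$decay - led$consumed)
})

test_that("sustained discarding raises the scavenger equilibrium", {
  cfg <- scav_cfg()
  run_to_eq <- function(discards) {
    st <- initial_state(cfg)
    for (i in 1:400)
      st <- step_quarter(st, zero_mat(cfg), zero_swept(cfg), cfg,
                         discards_to_detritus = discards)
    st
  }
  lo <- run_to_eq(c(0, 0))
  hi <- run_to_eq(c(500, 500))
  expect_gt(sum(hi$B["scavenger", ]), sum(lo$B["scavenger", ]))
  expect_gt(sum(hi$B["detritus", ]), sum(lo$B["detritus", ]))
})

test_that("states remain non-negative under random admissible forcing", {
  cfg <- min_cfg()
  eq <- initialize_equilibrium(cfg)
  set.seed(21)
  st <- eq
  for (i in 1:60) {
    rem <- matrix(stats::runif(length(st$B), 0, 0.4), nrow(st$B)) * st$B
    swept <- matrix(stats::runif(2, 0, 300), 1, 2)
    st <- suppressWarnings(step_quarter(st, rem, swept, cfg))
    expect_true(all(st$B >= 0))
    expect_true(all(st$H >= 0 & st$H <= 1))
  }
})

test_that("unfished reference run stays within 5% of equilibrium", {
  cfg <- ref_cfg()
  eq <- ref_eq()
  st <- eq
  horizon <- sum(cfg$phases) * 4
  worst <- 0
  for (i in seq_len(horizon)) {
    st <- step_quarter(st, zero_mat(cfg), zero_swept(cfg), cfg)
    dev <- max(abs(st$B - eq$B) / pmax(eq$B, 1))
    worst <- max(worst, dev)
  }
  expect_lt(worst, 0.05)
})

test_that("closure after sustained fishing gives monotone recovery", {
  cfg <- min_cfg()
  eq <- initialize_equilibrium(cfg)
  st <- eq
  rem <- zero_mat(cfg)
  rem[1, ] <- 0.1
  for (i in 1:40) {
    rem[1, ] <- 0.10 * st$B[1, ]
    st <- step_quarter(st, rem, zero_swept(cfg), cfg)
  }
  expect_lt(sum(st$B["fish", ]), sum(eq$B["fish", ]))
  prev <- sum(st$B["fish", ])
  for (i in 1:80) {
    st <- step_quarter(st, zero_mat(cfg), zero_swept(cfg), cfg)
    cur <- sum(st$B["fish", ])
    expect_gte(cur, prev - 1e-9)
    prev <- cur
  }
  expect_equal(prev, sum(eq$B["fish", ]), tolerance = 0.02)
})

test_that("snapshot CSV round-trip is bit-exact", {
  cfg <- min_cfg()
  eq <- initialize_equilibrium(cfg)
  snap <- ecosystem_snapshot(eq)
  path <- tempfile(fileext = ".csv")
  write_snapshots(snap, path)
  back <- read_snapshots(path)
  expect_identical(back$biomass, snap$biomass)
  unlink(path)
})
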