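#' Run one closed-loop management strategy evaluation
#'
#' Executes burn-in and historical phases under status-quo management, then
#' the projection under the strategy being tested. Each year: observation of
#' last year's fishery -> assessment (when due) and TAC setting -> four
#' quarters of effort allocation, harvest, retention and ecosystem dynamics
#' -> year-end reconciliation, quota trading, economics, management costs
#' and participation updates. Fully deterministic for a fixed
#' (config, strategy, seed): the ecology stream derives from the scenario
#' seed (shared across strategies, the paired-comparison design) and fleet/
#' observation streams from the run seed.
#'
#' @param config An \code{mse_scenario}.
#' @param strategy An \code{mse_strategy} (used in the projection phase).
#' @param seed Integer run seed.
#' @param equilibrium Optional precomputed unfished equilibrium state.
#' @param record_quarterly Keep quarterly biomass snapshots (memory).
#' @return An \code{mse_result}.
#' @export
run_mse <- function(config, strategy, seed, equilibrium = NULL,
                    record_quarterly = FALSE) {
  p <- config$params
  g <- config$groups
  ng <- nrow(g); nb <- nrow(config$boxes)
  diags <- validate_scenario(config)
  if (length(diags)) stop("invalid scenario: ", diags[1])
  eq <- equilibrium %||% initialize_equilibrium(config)
  s1 <- strategy_config("S1_status_quo", config)
  rng_fleet <- make_rng(seed, "fleet")
  rng_obs <- make_rng(seed, "observation")
  rng_ecol <- make_rng(config$seed, "ecology")

  burn <- config$phases[["burn_in"]]
  hist_end <- burn + config$phases[["historical"]]
  n_years <- hist_end + config$phases[["projection"]]

  # reference points from the model's own unfished equilibrium
  B0_eq <- rowSums(eq$B)
  refs_for <- function(i) list(B0 = B0_eq[i], lim_frac = p$B_lim_frac,
                               targ_frac = p$B_targ_frac,
                               F_target = p$F_target_frac * g$M[i])

  fleets <- config$fleets
  fleets$debt <- 0
  fleets$loss_streak <- 0L
  ports <- config$ports
  ports$population <- ports$population0

  state <- eq
  state$year <- 0L; state$quarter <- 0L
  prev_shares <- NULL
  biomass_year <- matrix(NA_real_, ng, n_years,
                         dimnames = list(g$id, seq_len(n_years)))
  size_year <- matrix(NA_real_, ng, n_years,
                      dimnames = list(g$id, seq_len(n_years)))
  annual <- list()
  accounts <- list()
  snapshots <- list()
  tac_hist <- list()                    # per-year named TAC vectors by unit
  obs_catch_hist <- list()              # observed landings by group, per year
  tac_prev <- NULL
  tt <- NULL
  ledger_totals <- c(requested_removals = 0, realized_removals = 0,
                     landings = 0, discards = 0, incidental = 0)
  Bhist_year_end <- list()              # true biomass by group (lagged data)

  for (y in seq_len(n_years)) {
    strat_now <- if (y <= hist_end) s1 else strategy
    proj_year <- if (y > hist_end) y - hist_end else NA
    idx_g <- stats::setNames(seq_len(ng), g$id)

    # ---- management update (uses data through year y-1) ----
    units <- tac_units(strat_now)
    all_members <- unlist(units)
    if (is.null(tac_prev) || !identical(sort(names(tac_prev)),
                                        sort(names(units)))) {
      tac_prev <- vapply(units, function(m) 0.15 * sum(B0_eq[m]), numeric(1))
      assess_last <- stats::setNames(rep(-99L, length(units)), names(units))
      rbc_last <- tac_prev
    }
    discards_est_by_group <- stats::setNames(rep(0, ng), g$id)
    if (y > 1) {
      last <- annual[[y - 1]]
      truth <- list(landings = last$landings_by_group,
                    discards = last$discards_by_group,
                    biomass = Bhist_year_end[[y - 1]])
      obs <- simulate_observation(truth, strat_now, config, rng_obs)
      ok <- !is.na(obs$discards_est)
      discards_est_by_group[names(obs$discards_est)[ok]] <- obs$discards_est[ok]
      obs_catch_hist[[y - 1]] <- obs$landings
      if (strat_now$tac_method == "catch_trend") {
        for (u in names(units)) {
          series <- vapply(obs_catch_hist, function(cc)
            sum(cc[units[[u]]], na.rm = TRUE), numeric(1))
          tac_prev[u] <- trend_tac(series, tac_prev[u], p)
        }
      } else {
        lag_B <- if (y >= 3) Bhist_year_end[[y - 2]] else Bhist_year_end[[y - 1]]
        lag_tot <- rowSums(lag_B)
        for (u in names(units)) {
          members <- units[[u]]
          tier_u <- max(g$tier[idx_g[members]], na.rm = TRUE)
          freq <- strat_now$assessment_frequency_years[[as.character(tier_u)]]
          if (y - assess_last[u] >= freq) {
            rbc <- 0
            for (m in members) {
              i <- idx_g[[m]]
              as_m <- dynamic_assessment(lag_tot[[m]], g$tier[i],
                                         strat_now$survey, p, rng_obs)
              rbc <- rbc + tiered_hcr(as_m, refs_for(i), p)
            }
            rbc_last[u] <- rbc
            assess_last[u] <- y
          }
          tac_prev[u] <- rbc_last[u]
        }
      }
    }
    # regional biomass shares (true spatial structure, bioregion proxy)
    region_map <- box_regions(strat_now, config)
    regions <- unique(region_map)
    region_share <- vapply(regions, function(rg)
      rowSums(state$B[, region_map == rg, drop = FALSE]), numeric(ng))
    region_share <- region_share / pmax(rowSums(region_share), 1e-12)
    rbcs_by_group <- stats::setNames(rep(0, ng), g$id)
    for (u in names(units)) {
      m <- units[[u]]
      rbcs_by_group[m] <- tac_prev[u] / length(m)
    }
    tt <- set_tacs(rbcs_by_group[all_members], strat_now,
                   discard_estimates = discards_est_by_group,
                   region_share = region_share, year = y)
    tt <- update_companion_state(tt)
    tac_hist[[y]] <- tac_prev

    # ---- quarterly fishery + ecosystem dynamics ----
    land_fg <- matrix(0, nrow(fleets), ng, dimnames = list(fleets$id, g$id))
    land_value <- stats::setNames(rep(0, nrow(fleets)), fleets$id)
    disc_by_group <- stats::setNames(rep(0, ng), g$id)
    effort_days <- stats::setNames(rep(0, nrow(fleets)), fleets$id)
    dist_km_days <- effort_days
    swept_total <- 0
    tep_tonnes <- 0
    conflict_count <- 0L
    trip_len_acc <- c(0, 0)
    year_events <- list()
    for (q in 1:4) {
      halted <- halted_groups(tt)
      exp_prof <- expected_profit(state, fleets, strat_now, config, q, halted)
      # fleets throttle when their revenue share under exhausted quota is large
      cap_scale <- rep(1, nrow(fleets))
      rem_zero <- vapply(g$id, function(gr) {
        u <- unit_of(gr, tt)
        if (is.na(u)) return(FALSE)
        all(vapply(unique(tt$records$region), function(rg)
          tac_remaining(tt, u, rg) <= 1e-9, logical(1)))
      }, logical(1))
      if (any(rem_zero)) for (f in seq_len(nrow(fleets))) {
        sel <- gear_selectivity(state$size, strat_now$mesh_mm[fleets$id[f]],
                                fleets$sel_l50_factor[f])
        wrev <- config$q[f, ] * sel * g$price * rowSums(state$B)
        tot <- sum(wrev)
        if (tot > 0) cap_scale[f] <- 1 - 0.8 * sum(wrev[rem_zero]) / tot
      }
      E <- allocate_effort(fleets, exp_prof, strat_now, config, q,
                           prev_shares, cap_scale, rng_fleet)
      prev_shares <- attr(E, "shares")
      openq <- effective_zoning(strat_now, q)
      hv <- harvest(E, state, fleets, strat_now, config, open = openq)
      rt <- retention(hv$catch, tt, strat_now, config)
      penalty_q <- 0
      # reconciliation ledger
      if (strat_now$reconciliation == "at_landing") {
        rec <- reconcile(tt, rt$events, "at_landing", lease_available = 0)
        tt <- rec$tt
        if (any(rec$forfeited > 0)) {
          fpr <- g$price[match(rt$events$group, g$id)]
          penalty_q <- sum(rec$forfeited * fpr) * p$overcatch_penalty
        }
      } else {
        year_events[[length(year_events) + 1L]] <- rt$events
      }
      tt <- update_companion_state(tt)
      # ecosystem step
      removals <- apply(rt$post_brd, c(2, 3), sum)
      disc_gb <- apply(rt$discards, c(2, 3), sum)
      state_new <- step_quarter(state, removals, hv$swept, config, rng_ecol,
                                discards_to_detritus = colSums(disc_gb))
      led <- attr(state_new, "ledger")
      rs <- led$removal_scale
      if (any(rs < 1)) {   # honour the operating model's removal cut exactly
        for (f in seq_len(nrow(fleets))) {
          rt$landings[f, , ] <- rt$landings[f, , ] * rs
          rt$discards[f, , ] <- rt$discards[f, , ] * rs
        }
      }
      ledger_totals["requested_removals"] <-
        ledger_totals["requested_removals"] + sum(removals)
      ledger_totals["realized_removals"] <-
        ledger_totals["realized_removals"] + sum(led$removals)
      ledger_totals["landings"] <- ledger_totals["landings"] + sum(rt$landings)
      ledger_totals["discards"] <- ledger_totals["discards"] + sum(rt$discards)
      ledger_totals["incidental"] <- ledger_totals["incidental"] + sum(led$incidental)
      # accumulate annual aggregates
      lq <- apply(rt$landings, c(1, 2), sum)
      land_fg <- land_fg + lq
      val_q <- as.numeric(lq %*% (g$price * config$price_season[, q])) * rt$hg_premium
      if (penalty_q > 0 && sum(val_q) > 0)   # forfeits + penalty, value-share
        val_q <- val_q - penalty_q * val_q / sum(val_q)
      land_value <- land_value + val_q
      disc_by_group <- disc_by_group + rowSums(disc_gb)
      effort_days <- effort_days + rowSums(E)
      dist_km_days <- dist_km_days +
        vapply(seq_len(nrow(fleets)), function(f)
          sum(E[f, ] * config$port_distance[, fleets$home_port[f]]), numeric(1))
      swept_total <- swept_total +
        sum(hv$swept[fleets$bottom_contact, , drop = FALSE])
      tep_tonnes <- tep_tonnes + sum(rt$post_brd[, g$guild == "TEP", ])
      # gear conflict: towed and static gear co-occurring above threshold
      towed <- fleets$gear %in% c("bottom_trawl", "danish_seine")
      static <- fleets$gear %in% c("gillnet", "longline")
      thr <- p$gear_conflict_threshold
      conflict_count <- conflict_count + sum(
        colSums(E[towed, , drop = FALSE]) > thr &
        colSums(E[static, , drop = FALSE]) > thr)
      # trip length: steaming + hold-filling time, effort-weighted
      for (f in seq_len(nrow(fleets))) {
        ef <- sum(E[f, ])
        if (ef <= 0) next
        cpue_day <- sum(lq[f, ]) / ef
        steam <- sum(E[f, ] * config$port_distance[, fleets$home_port[f]]) / ef /
          p$trip_speed_km_day
        tl <- 2 * steam + p$hold_tonnes / max(cpue_day, 0.05)
        trip_len_acc <- trip_len_acc + c(tl * ef, ef)
      }
      state <- state_new
      if (record_quarterly)
        snapshots[[length(snapshots) + 1L]] <- ecosystem_snapshot(state)
    }

    # ---- year end: annual reconciliation, trading, economics ----
    if (strat_now$reconciliation == "annual" && length(year_events)) {
      ev <- do.call(rbind, year_events)
      supply_pool <- vapply(names(units), function(u)
        max(0, sum(tt$records$tac[tt$records$unit == u]) * 0.2), numeric(1))
      rec <- reconcile(tt, ev, "annual", lease_available = supply_pool)
      tt <- rec$tt
    }
    i_rec <- seq_len(nrow(tt$records))
    tt$records$undercatch[i_rec] <- pmax(0, tt$records$tac - tt$records$landed)

    # quota market: initial holdings by equilibrium catch shares
    nf <- nrow(fleets)
    land_fu <- matrix(0, nf, length(units),
                      dimnames = list(fleets$id, names(units)))
    for (u in names(units))
      land_fu[, u] <- rowSums(land_fg[, units[[u]], drop = FALSE])
    tac_u <- vapply(names(units), function(u)
      sum(tt$records$tac[tt$records$unit == u]), numeric(1))
    share_f <- land_fu
    for (ui in seq_along(units)) {
      tot <- sum(land_fu[, ui])
      share_f[, ui] <- if (tot > 0) land_fu[, ui] / tot else 1 / nf
    }
    owned <- share_f * rep(tac_u, each = nf)
    short_fu <- pmax(land_fu - owned, 0)
    spare_fu <- pmax(owned - land_fu, 0)
    unit_price <- vapply(units, function(m) mean(g$price[idx_g[m]]), numeric(1))
    trades <- trade_quota(colSums(spare_fu), colSums(short_fu), unit_price, p)
    lease_net_f <- rep(0, nrow(fleets))
    for (ui in seq_along(units)) {
      v <- trades$volume[ui]; lp <- trades$lease_price[ui]
      if (v <= 0) next
      dshare <- short_fu[, ui] / max(sum(short_fu[, ui]), 1e-12)
      sshare <- spare_fu[, ui] / max(sum(spare_fu[, ui]), 1e-12)
      lease_net_f <- lease_net_f + v * lp * (sshare - dshare)
    }

    mc <- management_costs(strat_now, fleets, config)
    active_total <- sum(fleets$active_vessels)
    levy_f <- if (active_total > 0)
      mc$total * fleets$active_vessels / active_total else rep(0, nrow(fleets))
    acc <- fleet_economics(land_fg, g$price,
                           list(days = effort_days, dist_km_days = dist_km_days),
                           fleets, levies = levy_f, lease_net = lease_net_f,
                           value = land_value)
    acc$year <- y
    accounts[[y]] <- acc
    profits <- stats::setNames(acc$profit, acc$fleet)
    exp_by_gear <- tapply(acc$profit / pmax(effort_days, 1), fleets$gear, mean)
    # expected annual profit per vessel from the latest profit expectations
    # (open boxes only, haircut for competition), driving re-entry decisions
    eap <- vapply(seq_len(nrow(fleets)), function(f) {
      ob <- openq[, f] > 0
      if (!any(ob)) return(-Inf)
      best_day <- max(exp_prof[f, ob])
      # prospective levy assumes cost recovery over at least a modest fleet
      lev <- mc$total / max(20, sum(fleets$active_vessels))
      0.7 * best_day * fleets$days_per_quarter[f] * 4 -
        fleets$fixed_cost_yr[f] - lev
    }, numeric(1))
    names(eap) <- fleets$id
    eap[is.na(eap)] <- -Inf
    fleets <- update_participation(fleets, profits, strat_now, config,
                                   projection_year = proj_year,
                                   expected_profit_by_gear = as.list(exp_by_gear),
                                   expected_annual_profit = as.list(eap))

    # ports follow landings through their fleets
    land_by_port <- tapply(rowSums(land_fg), fleets$home_port, sum)
    act <- numeric(nrow(ports))
    for (pi in seq_len(nrow(ports))) {
      L <- land_by_port[ports$id[pi]]
      if (is.na(L)) L <- 0
      act[pi] <- L / (L + p$port_half_landings)
      target <- ports$population0[pi] *
        (0.75 + 0.5 * min(1, L / p$port_half_landings))
      ports$population[pi] <- ports$population[pi] +
        p$port_pop_k * (target - ports$population[pi])
    }

    # management stability from year-on-year TAC changes
    stab <- 1
    if (y > 1) {
      prev <- tac_hist[[y - 1]]
      common <- intersect(names(prev), names(tac_prev))
      if (length(common)) {
        relch <- abs(tac_prev[common] - prev[common]) / pmax(prev[common], 1e-9)
        stab <- 1 / (1 + mean(relch))
      }
    }
    zo <- strat_now$zoning
    access <- mean(vapply(seq_len(ncol(zo)), function(f)
      sum(config$boxes$area_km2 * zo[, f]) / sum(config$boxes$area_km2),
      numeric(1)))
    eco_state <- mean(pmin(1, rowSums(state$B)[g$guild %in%
                    c("target", "bycatch", "TEP")] /
                    pmax(B0_eq[g$guild %in% c("target", "bycatch", "TEP")], 1e-9)))
    port_rel <- mean(ports$population / ports$population0)
    total_profit <- sum(acc$profit)
    public_image <- mean(c(eco_state, port_rel, as.numeric(total_profit > 0)))
    habitat_cover <- sum(state$H * config$boxes$area_km2) /
      (sum(config$boxes$area_km2) * ncol(state$H))
    land_g <- colSums(land_fg)
    lt <- sum(land_g)
    low_tl <- g$trophic_level < 3.5

    biomass_year[, y] <- rowSums(state$B)
    size_year[, y] <- state$size
    Bhist_year_end[[y]] <- vapply(regions, function(rg)
      rowSums(state$B[, region_map == rg, drop = FALSE]), numeric(ng))
    annual[[y]] <- list(
      year = y, phase = if (y <= burn) "burn_in" else
        if (y <= hist_end) "historical" else "projection",
      landings = lt, discards = sum(disc_by_group),
      landings_by_group = land_g, discards_by_group = disc_by_group,
      landings_target = sum(land_g[g$guild == "target"]),
      landings_low_tl = sum(land_g[low_tl]),
      landings_high_tl = sum(land_g[!low_tl]),
      effort_days = sum(effort_days), swept_area = swept_total,
      tep_interactions = tep_tonnes,
      avg_catch_size = if (lt > 0)
        sum(land_g * ifelse(is.na(state$size), 0, state$size)) / lt else NA,
      catch_composition = if (lt > 0) max(land_g) / lt else NA,
      access = access, mgmt_stability = stab,
      quota_trading = sum(trades$volume),
      cost_admin = mc$admin, cost_research = mc$research,
      cost_enforcement = mc$enforcement, cost_monitoring = mc$monitoring,
      cost_assessment = mc$assessment, cost_total = mc$total,
      levy_per_boat = mc$levy_per_boat,
      public_image = public_image, gear_conflict = conflict_count,
      port_activity = sum(act),
      gvp = sum(acc$gvp), costs = sum(acc$costs), profit = total_profit,
      habitat_cover = habitat_cover,
      trip_length = if (trip_len_acc[2] > 0)
        trip_len_acc[1] / trip_len_acc[2] else NA,
      active_vessels = sum(fleets$active_vessels),
      latent_vessels = sum(fleets$latent_vessels),
      overcatch = sum(tt$records$overcatch),
      undercatch = sum(tt$records$undercatch))
  }

  annual_df <- do.call(rbind, lapply(annual, function(a) {
    a$landings_by_group <- NULL; a$discards_by_group <- NULL
    as.data.frame(a, stringsAsFactors = FALSE)
  }))
  structure(list(
    template = config$template, member = config$member %||% 0L,
    strategy_id = strategy$id, seed = seed, scenario_seed = config$seed,
    phase_bounds = c(burn_in_end = burn, historical_end = hist_end,
                     final = n_years),
    annual = annual_df,
    annual_raw = annual,
    accounts = do.call(rbind, accounts),
    biomass_year = biomass_year, size_year = size_year,
    equilibrium_B0 = B0_eq,
    fleets_final = fleets, ports_final = ports,
    final_state = state, tac_table = tt,
    ledger_totals = ledger_totals,
    snapshots = if (record_quarterly) do.call(rbind, snapshots) else NULL
  ), class = "mse_result")
}

#' @export
print.mse_result <- function(x, ...) {
  cat("<mse_result>", x$strategy_id, "member", x$member, "seed", x$seed, "\n")
  cat("  years:", nrow(x$annual), " final landings:",
      round(utils::tail(x$annual$landings, 1)), "t\n")
  invisible(x)
}

#' Run an ensemble of scenario members across strategies
#'
#' Members share seeds across strategies (paired comparison). The unfished
#' equilibrium is computed once per member and reused for every strategy;
#' perturbed members warm-start from the base member's equilibrium.
#'
#' @param configs List of \code{mse_scenario} (e.g. from
#'   \code{\link{perturb_ensemble}}).
#' @param strategies List of \code{mse_strategy}.
#' @param base_seed Integer: run seeds derive from it per member.
#' @return List: \code{results} (member x strategy nested list),
#'   \code{indicators} (long table across runs), \code{bands} quartile bands
#'   per strategy-indicator-year.
#' @export
run_ensemble <- function(configs, strategies, base_seed = 1L) {
  stopifnot(length(configs) >= 1, length(strategies) >= 1)
  results <- list()
  ind_rows <- list()
  eq_base <- NULL
  for (m in seq_along(configs)) {
    cfg <- configs[[m]]
    # perturbed members warm-start from the base equilibrium; a 1e-7
    # residual keeps the one-quarter drift well below the 1e-6 contract
    eq <- initialize_equilibrium(cfg, tol = if (m == 1) 1e-9 else 1e-7,
                                 max_iter = 40000, start = eq_base)
    if (m == 1) eq_base <- eq
    seed_m <- stream_seed(base_seed, paste0("member", m - 1))
    for (s in seq_along(strategies)) {
      st <- strategies[[s]]
      res <- run_mse(cfg, st, seed_m, equilibrium = eq)
      results[[paste0("m", m - 1, "_", st$id)]] <- res
      it <- compute_indicator_table(res, cfg)
      it$member <- m - 1L
      ind_rows[[length(ind_rows) + 1L]] <- it
    }
  }
  indicators <- do.call(rbind, ind_rows)
  bands <- quartile_bands(indicators)
  list(results = results, indicators = indicators, bands = bands)
}

#' Quartile bands across ensemble members
#'
#' Lower and upper quartiles (linear-interpolation rule, type 7) plus the
#' member-0 trajectory reported as the best-fit line.
#'
#' @param indicators Long indicator table with a \code{member} column.
#' @return data.frame: strategy, indicator, year, lower, best_fit, upper.
#' @export
quartile_bands <- function(indicators) {
  sp <- split(indicators,
              list(indicators$strategy, indicators$indicator, indicators$year),
              drop = TRUE)
  rows <- lapply(sp, function(d) {
    v <- d$value[!is.na(d$value)]
    data.frame(strategy = d$strategy[1], indicator = d$indicator[1],
               year = d$year[1],
               lower = if (length(v)) band_quantile(v, 0.25) else NA,
               best_fit = d$value[d$member == min(d$member)][1],
               upper = if (length(v)) band_quantile(v, 0.75) else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$strategy, out$indicator, out$year), ]
}

#' Composite kite scores for an ensemble or single run
#'
#' Joint inversion/normalisation over all strategies and years in the
#' table, then class composites, reported at the last historical year and
#' the final projection year.
#'
#' @param indicators Long indicator table (row-bound across strategies).
#' @param phase_bounds Named vector with \code{historical_end} and
#'   \code{final}.
#' @return List: \code{scores} (all years), \code{kites} (reporting years).
#' @export
ensemble_kites <- function(indicators, phase_bounds) {
  unit <- invert_and_normalize(indicators)
  sc <- composite_scores(unit)
  list(scores = sc,
       kites = kite_data(sc, phase_bounds[["historical_end"]],
                         phase_bounds[["final"]]))
}
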