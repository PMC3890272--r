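#' Gear selectivity from mesh size and mean individual size
#'
#' Logistic selectivity-at-size with L50 proportional to mesh: raising mesh
#' monotonically lowers selectivity for small-bodied groups.
#'
#' @param size_cm Mean individual size per group (NA for non-caught pools).
#' @param mesh_mm Mesh size.
#' @param l50_factor Gear-specific cm-per-mm conversion to L50.
#' @return Selectivity in [0,1] (0 where size is NA).
#' @export
gear_selectivity <- function(size_cm, mesh_mm, l50_factor) {
  l50 <- mesh_mm * l50_factor
  s <- 1 / (1 + exp(-(size_cm - l50) / (0.25 * l50)))
  s[is.na(s)] <- 0
  s
}

# effective open fraction per box x fleet for a given quarter, including any
# spawning closure (voluntary closures only bind compliant effort, which is
# how all zoning is applied; "compulsory" additionally zeroes the box)
effective_zoning <- function(strategy, quarter) {
  z <- strategy$zoning
  sc <- strategy$spawning_closure
  if (isTRUE(sc$active) && quarter == sc$quarter && length(sc$boxes))
    z[sc$boxes, ] <- 0
  z
}

#' Allocate quarterly fishing effort over boxes
#'
#' Each fleet spreads its effort capacity over boxes with a softmax on
#' expected profit per day, blended with last quarter's shares (inertia).
#' Compliant effort (a stochastic fraction with mean
#' \eqn{c + (1-c) \cdot enforcement}) respects zoning open fractions;
#' the non-compliant remainder ignores them. Fleets facing negative expected
#' margins pull effort down to a pulse level, concentrating what remains in
#' the quarter with their best seasonal prices.
#'
#' @param fleets Fleet state data.frame.
#' @param expectations Fleet x box expected profit per vessel-day ($).
#' @param strategy An \code{mse_strategy} (zoning, enforcement).
#' @param config Scenario.
#' @param quarter Quarter 1..4 (spawning closures, price seasonality).
#' @param prev_shares Fleet x box matrix of last quarter's effort shares or NULL.
#' @param capacity_scale Per-fleet multiplier in [0,1] (quota exhaustion).
#' @param rng Fleet stream rng (NULL gives the deterministic mean allocation).
#' @return Fleet x box vessel-days matrix with attributes \code{shares},
#'   \code{days} and \code{trip_length}.
#' @export
allocate_effort <- function(fleets, expectations, strategy, config, quarter = 1L,
                            prev_shares = NULL, capacity_scale = NULL, rng = NULL) {
  stopifnot(all(is.finite(expectations)))
  p <- config$params
  nf <- nrow(fleets); nb <- nrow(config$boxes)
  z <- effective_zoning(strategy, quarter)
  E <- matrix(0, nf, nb, dimnames = list(fleets$id, config$boxes$id))
  shares_out <- E
  days_out <- numeric(nf)
  if (is.null(capacity_scale)) capacity_scale <- rep(1, nf)
  enf <- strategy$enforcement_level
  for (f in seq_len(nf)) {
    base <- softmax(expectations[f, ], p$softmax_temp)
    if (!is.null(prev_shares))
      base <- p$inertia * prev_shares[f, ] + (1 - p$inertia) * base
    best <- max(expectations[f, ])
    days <- fleets$days_per_quarter[f]
    if (best < 0) {
      # pulse fishing: keep near-full effort only in the best price quarter
      season <- config$price_season[, quarter]
      wq <- apply(config$price_season, 2, function(s)
        sum(config$q[f, ] * config$groups$price * s))
      days <- days * if (quarter == which.max(wq)) 0.8 else p$pulse_scale
      days <- min(days, p$neg_margin_days * 4)
    }
    capacity <- fleets$active_vessels[f] * days * capacity_scale[f]
    nc_mean <- (1 - fleets$compliance_trait[f]) * (1 - enf)
    nc <- if (is.null(rng)) nc_mean else
      rng_draw(rng, stats::rbinom, 1, 1000, nc_mean) / 1000
    wc <- base * z[, f]
    wc <- if (sum(wc) > 0) wc / sum(wc) else wc * 0
    wnc <- base
    E[f, ] <- capacity * ((1 - nc) * wc + nc * wnc)
    shares_out[f, ] <- if (sum(E[f, ]) > 0) E[f, ] / sum(E[f, ]) else base
    days_out[f] <- days
  }
  attr(E, "shares") <- shares_out
  attr(E, "days") <- days_out
  E
}

#' Expected profit per vessel-day by fleet and box
#'
#' Revenue from local biomass density through catchability and selectivity,
#' minus daily running costs and a steaming cost to the box. Groups whose
#' directed fishing is halted by a companion link contribute no expected
#' revenue (fleets stop targeting them).
#'
#' @param state Ecosystem state.
#' @param fleets Fleet state.
#' @param strategy Strategy (mesh sizes).
#' @param config Scenario.
#' @param quarter Quarter (price seasonality).
#' @param halted Character vector of groups with halted directed fishing.
#' @return Fleet x box $ per vessel-day matrix.
#' @export
expected_profit <- function(state, fleets, strategy, config, quarter = 1L,
                            halted = character()) {
  nf <- nrow(fleets); nb <- nrow(config$boxes)
  out <- matrix(0, nf, nb, dimnames = list(fleets$id, config$boxes$id))
  price <- config$groups$price * config$price_season[, quarter]
  price[config$groups$id %in% halted] <- 0
  for (f in seq_len(nf)) {
    sel <- gear_selectivity(state$size, strategy$mesh_mm[fleets$id[f]],
                            fleets$sel_l50_factor[f])
    rate <- config$q[f, ] * sel          # km2/day equivalent per group
    rev <- as.numeric(crossprod(state$B, rate * price)) / config$boxes$area_km2
    cost <- fleets$fuel_cost_day[f] + fleets$gear_cost_day[f] +
      fleets$dist_cost_km_day[f] * config$port_distance[, fleets$home_port[f]]
    out[f, ] <- rev - cost
  }
  out
}

#' Catch from effort and biomass (pre-retention)
#'
#' \eqn{C_{fgb} = q_{fg} sel_{fg} E_{fb} B_{gb} / area_b}, capped so the
#' total across fleets never exceeds the available fraction of a group's
#' biomass in a box. Also returns swept/interaction area per fleet and box
#' for the habitat and incidental-mortality coupling.
#'
#' @param effort Fleet x box vessel-days.
#' @param state Ecosystem state.
#' @param fleets Fleet state.
#' @param strategy Strategy (mesh).
#' @param config Scenario.
#' @param open Optional box x fleet open-fraction matrix: catch in a
#'   partially closed box only accesses the open share of its biomass (the
#'   reserve effect); fully closed boxes are fished only by non-compliant
#'   effort, which accesses the stock freely.
#' @return List: \code{catch} (fleet x group x box array), \code{swept}
#'   (fleet x box).
#' @export
harvest <- function(effort, state, fleets, strategy, config, open = NULL) {
  stopifnot(all(effort >= 0))
  nf <- nrow(fleets); ng <- nrow(config$groups); nb <- nrow(config$boxes)
  C <- array(0, c(nf, ng, nb),
             dimnames = list(fleets$id, config$groups$id, config$boxes$id))
  for (f in seq_len(nf)) {
    sel <- gear_selectivity(state$size, strategy$mesh_mm[fleets$id[f]],
                            fleets$sel_l50_factor[f])
    rate <- config$q[f, ] * sel
    C[f, , ] <- outer(rate, effort[f, ] / config$boxes$area_km2) * state$B
    if (!is.null(open)) {
      acc <- ifelse(open[, f] > 0, open[, f], 1)
      C[f, , ] <- C[f, , ] * rep(acc, each = ng)
    }
  }
  # cap at available biomass, scaling fleets proportionally
  tot <- apply(C, c(2, 3), sum)
  cap <- config$params$avail_cap * state$B
  over <- tot > cap & tot > 0
  if (any(over)) {
    scl <- matrix(1, ng, nb)
    scl[over] <- cap[over] / tot[over]
    for (f in seq_len(nf)) C[f, , ] <- C[f, , ] * scl
  }
  swept <- effort * fleets$sweep_km2_day
  list(catch = C, swept = swept)
}

#' Retention and discarding of the catch
#'
#' Applies, per fleet x group x box: bycatch-reduction devices (bycatch and
#' TEP-guild catch scaled by 1 - brd_effect; the reduction escapes alive and
#' is never caught); price-based retention (valueless catch is discarded,
#' less any strategy-mandated discard-rate reduction); and quota-driven
#' discarding for groups under TAC (under at-landing reconciliation catch
#' beyond remaining quota is discarded at sea, unless discard monitoring and
#' enforcement forces it to be landed as penalised overcatch; under annual
#' reconciliation everything lands and is reconciled at year end).
#' High-grading is expressed as a value premium on quota-constrained
#' landings rather than a tonnage swap. The identity
#' landings + discards = post-BRD catch holds exactly.
#'
#' @param catch Fleet x group x box catch array from \code{\link{harvest}}.
#' @param tt Current \code{tac_table} (ledger state; remaining quota caps
#'   landings per unit-region).
#' @param strategy Strategy.
#' @param config Scenario.
#' @return List: \code{landings}, \code{discards} (arrays matching catch),
#'   \code{post_brd} catch array, \code{events} (landings events by unit and
#'   region, for reconciliation), \code{hg_premium} per fleet (value factor).
#' @export
retention <- function(catch, tt, strategy, config) {
  stopifnot(all(catch >= 0))
  g <- config$groups
  dims <- dim(catch)
  post <- catch
  brd_guilds <- c("bycatch", "TEP")
  i_brd <- which(g$guild %in% brd_guilds)
  if (length(i_brd) && strategy$brd_effect > 0)
    post[, i_brd, ] <- post[, i_brd, ] * (1 - strategy$brd_effect)
  landings <- post
  discards <- array(0, dims, dimnames = dimnames(catch))
  region_of_box <- box_regions(strategy, config)
  hg_premium <- rep(1, dims[1])

  # 1. valueless catch discarded (reduced by any targeting improvement)
  no_value <- which(g$price <= 0 | g$guild %in% c("TEP", "habitat_former"))
  drr <- strategy$discard_rate_reduction %||% 0
  for (i in no_value) {
    d <- landings[, i, ] * (1 - drr * (g$price[i] > 0))
    discards[, i, ] <- discards[, i, ] + d
    landings[, i, ] <- landings[, i, ] - d
  }
  # 1b. baseline undersized/unmarketable discarding on marketable catch,
  # lowered by larger mesh (fewer small fish caught end up rejected) and by
  # strategy-mandated targeting improvements
  base_rate <- config$fleets$base_discard_rate *
    pmin(1, config$fleets$mesh_mm / strategy$mesh_mm[config$fleets$id]) *
    (1 - drr)
  priced <- setdiff(seq_len(nrow(g)), no_value)
  for (f in seq_len(dims[1])) {
    if (base_rate[f] <= 0) next
    d <- landings[f, priced, ] * base_rate[f]
    discards[f, priced, ] <- discards[f, priced, ] + d
    landings[f, priced, ] <- landings[f, priced, ] - d
  }

  # 2. quota-driven discarding, fleet by fleet in order (shared ledger)
  for (i in seq_len(nrow(g))) {
    u <- unit_of(g$id[i], tt)
    if (is.na(u)) next
    for (rg in unique(region_of_box)) {
      bx <- which(region_of_box == rg)
      rem <- tac_remaining(tt, u, rg)
      if (!is.finite(rem)) next
      for (f in seq_len(dims[1])) {
        take <- sum(landings[f, i, bx])
        if (take <= 0) next
        if (take > rem) {
          excess <- take - max(rem, 0)
          if (strategy$reconciliation == "at_landing" &&
              !isTRUE(strategy$discard_enforcement)) {
            # discard over-quota catch at sea; quota-constrained landings
            # are high-graded (value premium)
            frac_keep <- max(rem, 0) / take
            discards[f, i, bx] <- discards[f, i, bx] +
              landings[f, i, bx] * (1 - frac_keep)
            landings[f, i, bx] <- landings[f, i, bx] * frac_keep
            hg_premium[f] <- 1.15
          }
          # with discard enforcement (or annual timing) everything lands;
          # reconcile() will record overcatch / forfeits
        }
        rem <- rem - sum(landings[f, i, bx])
      }
    }
  }

  # landings events per unit x region (for the reconciliation ledger)
  ev <- list()
  for (i in seq_len(nrow(g))) {
    u <- unit_of(g$id[i], tt)
    if (is.na(u)) next
    for (rg in unique(region_of_box)) {
      bx <- which(region_of_box == rg)
      tons <- sum(landings[, i, bx])
      if (tons > 0)
        ev[[length(ev) + 1L]] <- data.frame(unit = u, region = rg,
                                            group = g$id[i], tonnes = tons,
                                            stringsAsFactors = FALSE)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(unit = character(), region = character(),
               group = character(), tonnes = numeric())
  list(landings = landings, discards = discards, post_brd = post,
       events = events, hg_premium = hg_premium)
}

# map boxes to management regions for a strategy
box_regions <- function(strategy, config) {
  out <- rep("all", nrow(config$boxes))
  names(out) <- config$boxes$id
  if (strategy$regional_tacs)
    for (rg in names(strategy$regions))
      out[strategy$regions[[rg]]] <- rg
  out
}

#' Annual quota lease market clearing
#'
#' One clearing per unit-region-year: excess demand meets excess supply at a
#' price increasing in the demand/supply ratio; traded volume is recorded
#' for the quota-trading indicator and quota is conserved (every leased
#' tonne has a lessor and a lessee).
#'
#' @param supply Named vector: unleased quota tonnes offered per unit.
#' @param demand Named vector: quota tonnes sought per unit.
#' @param prices Named vector: fish price $/t per unit (floor basis).
#' @param params Scenario params (\code{lease_price_frac},
#'   \code{lease_scarcity_slope}).
#' @return data.frame per unit: supply, demand, volume, lease_price.
#' @export
trade_quota <- function(supply, demand, prices, params) {
  stopifnot(all(demand >= 0), all(supply >= 0))
  units <- union(names(supply), names(demand))
  if (!length(units))
    return(data.frame(unit = character(), supply = numeric(),
                      demand = numeric(), volume = numeric(),
                      lease_price = numeric(), stringsAsFactors = FALSE))
  out <- data.frame(unit = units, supply = 0, demand = 0, volume = 0,
                    lease_price = 0, stringsAsFactors = FALSE)
  for (i in seq_along(units)) {
    u <- units[i]
    s <- if (u %in% names(supply)) supply[[u]] else 0
    d <- if (u %in% names(demand)) demand[[u]] else 0
    floor_p <- params$lease_price_frac * (if (u %in% names(prices)) prices[[u]] else 0)
    scarcity <- if (s > 0) max(0, d / s - 1) else if (d > 0) 10 else 0
    out$supply[i] <- s
    out$demand[i] <- d
    out$volume[i] <- min(s, d)
    out$lease_price[i] <- floor_p * (1 + params$lease_scarcity_slope * scarcity)
  }
  out
}

#' Fleet economic accounts for one year
#'
#' Cost classes: fuel (daily rate plus steaming), gear, refrigeration and
#' transport, unloading (per tonne), capital and fixed (per active vessel).
#' The exact identity profit = GVP + lease net - costs - levy always holds;
#' per-tonne and per-effort ratios guard zero denominators by reporting NA.
#'
#' @param landings Fleet x group tonnes landed over the year.
#' @param prices Named price vector per group ($/t), already including any
#'   seasonal or high-grading value factors in \code{value} if supplied.
#' @param effort List with per-fleet \code{days} (vessel-days) and
#'   \code{dist_km_days} (sum over days of distance to ground).
#' @param fleets Fleet state.
#' @param levies Per-fleet management levy ($).
#' @param lease_net Per-fleet lease revenue minus expense ($).
#' @param value Optional per-fleet landed value ($) overriding
#'   \code{landings \%*\% prices} (used when seasonal prices applied).
#' @return data.frame of \code{EconomicAccounts} per fleet.
#' @export
fleet_economics <- function(landings, prices, effort, fleets, levies = 0,
                            lease_net = 0, value = NULL) {
  if (any(prices < 0)) stop("negative price")
  nf <- nrow(fleets)
  levies <- rep_len(levies, nf)
  lease_net <- rep_len(lease_net, nf)
  landed_t <- rowSums(landings)
  gvp <- if (is.null(value)) as.numeric(landings %*% prices) else value
  fuel <- fleets$fuel_cost_day * effort$days +
    fleets$dist_cost_km_day * effort$dist_km_days
  gear <- fleets$gear_cost_day * effort$days
  refrig <- fleets$refrig_cost_t * landed_t
  unload <- fleets$unload_cost_t * landed_t
  fixed <- fleets$fixed_cost_yr * fleets$active_vessels
  costs <- fuel + gear + refrig + unload + fixed
  profit <- gvp + lease_net - costs - levies
  data.frame(
    fleet = fleets$id, landed_t = landed_t, gvp = gvp,
    cost_fuel = fuel, cost_gear = gear, cost_refrig = refrig,
    cost_unload = unload, cost_fixed = fixed, costs = costs,
    levy = levies, lease_net = lease_net, profit = profit,
    profit_per_tonne = ifelse(landed_t > 0, profit / landed_t, NA_real_),
    profit_per_effort = ifelse(effort$days > 0, profit / effort$days, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Vessel participation, latency, gear switching and buyback
#'
#' Vessels accumulate debt in loss years; after a run of consecutive losses
#' (threshold) a share of active vessels goes latent (licences retained).
#' Gear switching, where the strategy allows it, moves a persistently
#' losing bottom-trawl fleet to static gear when the expected profit ratio
#' clears a hurdle. A scheduled buyback retires licences latent-first, so
#' retiring non-participants leaves active capacity unchanged.
#'
#' @param fleets Fleet state.
#' @param profits Named per-fleet profit this year ($).
#' @param strategy Strategy.
#' @param config Scenario.
#' @param projection_year Year index within the projection phase (NA during
#'   burn-in/historical), for the buyback schedule.
#' @param expected_profit_by_gear Optional named vector of $/vessel-day by
#'   gear type, for the switching decision.
#' @param expected_annual_profit Optional named per-fleet expected annual
#'   profit per vessel ($); latent vessels reactivate while it is positive.
#' @return Updated fleet state.
#' @export
update_participation <- function(fleets, profits, strategy, config,
                                 projection_year = NA,
                                 expected_profit_by_gear = NULL,
                                 expected_annual_profit = NULL) {
  p <- config$params
  for (f in seq_len(nrow(fleets))) {
    pr <- profits[[fleets$id[f]]]
    if (is.null(pr) || is.na(pr)) pr <- 0
    if (pr < 0) {
      fleets$loss_streak[f] <- fleets$loss_streak[f] + 1L
      fleets$debt[f] <- fleets$debt[f] - pr
    } else {
      fleets$loss_streak[f] <- 0L
      fleets$debt[f] <- max(0, fleets$debt[f] - pr)
    }
    if (fleets$loss_streak[f] >= p$loss_streak_threshold &&
        fleets$active_vessels[f] > 0) {
      n_exit <- max(1L, ceiling(p$exit_frac * fleets$active_vessels[f]))
      n_exit <- min(n_exit, fleets$active_vessels[f])
      fleets$active_vessels[f] <- fleets$active_vessels[f] - n_exit
      fleets$latent_vessels[f] <- fleets$latent_vessels[f] + n_exit
    }
    # latent vessels re-enter while fishing looks profitable
    if (!is.null(expected_annual_profit) && fleets$latent_vessels[f] > 0) {
      eap <- expected_annual_profit[[fleets$id[f]]]
      if (!is.null(eap) && !is.na(eap) && eap > 0 && pr >= 0) {
        n_in <- min(fleets$latent_vessels[f],
                    max(1L, ceiling(0.25 * fleets$latent_vessels[f])))
        fleets$active_vessels[f] <- fleets$active_vessels[f] + n_in
        fleets$latent_vessels[f] <- fleets$latent_vessels[f] - n_in
      }
    }
    # gear switching (bottom trawl -> static gear) when allowed and justified
    if (isTRUE(strategy$gear_switching_allowed) &&
        fleets$gear[f] == "bottom_trawl" && fleets$loss_streak[f] >= 2L &&
        !is.null(expected_profit_by_gear)) {
      cur <- expected_profit_by_gear[["bottom_trawl"]] %||% 0
      alt <- expected_profit_by_gear[["gillnet"]] %||% 0
      if (alt > p$gear_switch_hurdle * max(cur, 1)) {
        fleets$gear[f] <- "gillnet"
        fleets$bottom_contact[f] <- FALSE
      }
    }
  }
  if (!is.na(projection_year) && !is.na(strategy$buyback_year) &&
      projection_year == strategy$buyback_year) {
    n <- strategy$buyback_licences
    for (f in order(-fleets$latent_vessels)) {
      take_latent <- min(n, fleets$latent_vessels[f])
      fleets$latent_vessels[f] <- fleets$latent_vessels[f] - take_latent
      fleets$licences[f] <- fleets$licences[f] - take_latent
      n <- n - take_latent
    }
    if (n > 0) for (f in order(-fleets$active_vessels)) {
      take <- min(n, fleets$active_vessels[f])
      fleets$active_vessels[f] <- fleets$active_vessels[f] - take
      fleets$licences[f] <- fleets$licences[f] - take
      n <- n - take
    }
  }
  fleets
}
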