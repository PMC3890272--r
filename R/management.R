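#' Observation model: logbooks, observer-estimated discards, optional survey
#'
#' Landings are observed exactly (compulsory logbooks). Discards are
#' estimated by expanding the observed fraction (observer coverage) with
#' binomial sampling error over trip units, so the estimator is unbiased
#' with variance shrinking as coverage grows. When the strategy runs a
#' fishery-independent survey, a mean-unbiased lognormal biomass index is
#' returned and downstream assessment CVs shrink.
#'
#' @param truth List with \code{landings} (named by group), \code{discards}
#'   (named by group) and \code{biomass} (group x region matrix).
#' @param strategy An \code{mse_strategy}.
#' @param config Scenario.
#' @param rng Observation stream rng.
#' @param n_units Number of trip units the discard stream is spread over.
#' @return List: \code{landings}, \code{discards_est}, \code{survey_index}
#'   (or NULL), \code{flags}.
#' @export
simulate_observation <- function(truth, strategy, config, rng, n_units = 100L) {
  stopifnot(all(truth$landings >= 0), all(truth$discards >= 0))
  cov <- strategy$observer_coverage
  flags <- character()
  if (cov <= 0) {
    discards_est <- rep(NA_real_, length(truth$discards))
    names(discards_est) <- names(truth$discards)
    if (isTRUE(strategy$discard_accounting))
      flags <- c(flags, "discard_accounting_without_coverage")
  } else if (cov >= 1) {
    discards_est <- truth$discards
  } else {
    k <- rng_draw(rng, stats::rbinom, length(truth$discards), n_units, cov)
    discards_est <- truth$discards * k / (n_units * cov)
  }
  survey_index <- NULL
  if (isTRUE(strategy$survey)) {
    cv <- 0.25
    sigma <- sqrt(log(1 + cv^2))
    z <- rng_draw(rng, stats::rnorm, length(truth$biomass))
    survey_index <- truth$biomass * exp(sigma * z - sigma^2 / 2)
  }
  list(landings = truth$landings, discards_est = discards_est,
       survey_index = survey_index, flags = flags)
}

#' Catch-trend TAC update
#'
#' \eqn{TAC_{y+1} = TAC_y (1 + clamp(slope, \pm max\_step))} where slope is
#' the least-squares slope of log observed catch over the trailing window.
#' With fewer than \code{window} years of data the TAC is held constant.
#'
#' @param observed_catch Numeric vector of annual observed catches (tonnes).
#' @param current_tac Current TAC (tonnes).
#' @param params List with \code{trend_window} and \code{trend_max_step}.
#' @return Updated TAC (tonnes, never negative).
#' @export
trend_tac <- function(observed_catch, current_tac, params) {
  w <- params$trend_window %||% 3
  if (length(observed_catch) < w) return(current_tac)
  y <- utils::tail(observed_catch, w)
  if (any(y <= 0)) y <- pmax(y, 1e-6)
  slope <- stats::coef(stats::lm(log(y) ~ seq_along(y)))[[2]]
  step <- clamp(slope, -params$trend_max_step, params$trend_max_step)
  max(0, current_tac * (1 + step))
}

#' Model-free dynamic stock assessment
#'
#' The assessment is an error-corrupted, one-year-lagged observation of true
#' biomass: \eqn{\hat B = B \exp(\sigma z)} (median-unbiased) with a CV set
#' by the data tier (tier 3 data-poor stocks get the widest CV) and reduced
#' when a fishery-independent survey exists. It deliberately contains no
#' population-dynamics refit: the mechanism under study is error and lag in
#' the management loop, not assessment internals.
#'
#' @param B_true_lagged True biomass one year before the assessment (tonnes).
#' @param tier Data tier 1 (rich) to 3 (poor).
#' @param survey Whether a survey index exists.
#' @param params Scenario params (\code{tier_cv}, \code{survey_cv_factor}).
#' @param rng Observation stream rng.
#' @return List with \code{B_hat}, \code{cv}, \code{tier}.
#' @export
dynamic_assessment <- function(B_true_lagged, tier, survey, params, rng = NULL) {
  cv <- params$tier_cv[[tier]] * if (isTRUE(survey)) params$survey_cv_factor else 1
  B_hat <- B_true_lagged
  if (cv > 0 && !is.null(rng)) {
    sigma <- sqrt(log(1 + cv^2))
    z <- rng_draw(rng, stats::rnorm, length(B_true_lagged))
    B_hat <- B_true_lagged * exp(sigma * z)
  }
  list(B_hat = B_hat, cv = cv, tier = tier)
}

#' Tiered harvest control rule
#'
#' The standard limit/target ramp: fishing mortality is zero at or below the
#' limit depletion, rises linearly to \eqn{F_{target} \cdot buffer(tier)} at
#' the target depletion, and is constant above it. The tier buffer shrinks
#' the allowed F for data-poor stocks. The recommended biological catch is
#' \eqn{RBC = F \hat B}.
#'
#' @param assessment List with \code{B_hat} and \code{tier} (from
#'   \code{\link{dynamic_assessment}}).
#' @param refs List with \code{B0}, \code{lim_frac}, \code{targ_frac},
#'   \code{F_target}.
#' @param params Scenario params (\code{tier_buffer}).
#' @return RBC in tonnes.
#' @export
tiered_hcr <- function(assessment, refs, params) {
  for (f in c("B0", "lim_frac", "targ_frac", "F_target"))
    if (is.null(refs[[f]]) || is.na(refs[[f]]))
      stop("missing reference point '", f, "'")
  stopifnot(refs$lim_frac > 0, refs$lim_frac < refs$targ_frac,
            refs$targ_frac <= 1)
  buffer <- params$tier_buffer[[assessment$tier]]
  d <- assessment$B_hat / refs$B0
  Fmax <- refs$F_target * buffer
  F_applied <- ifelse(d <= refs$lim_frac, 0,
               ifelse(d >= refs$targ_frac, Fmax,
                      Fmax * (d - refs$lim_frac) / (refs$targ_frac - refs$lim_frac)))
  F_applied * assessment$B_hat
}

# ---- TAC table -------------------------------------------------------------

#' Construct a TAC table from recommended biological catches
#'
#' Applies the strategy's quota machinery: regional TACs split each RBC by
#' regional biomass share; basket members are pooled into one cumulative
#' quota record; when discards are accounted against quota, the landed TAC
#' is the RBC minus expected discards (floored at zero); companion links are
#' recorded with a weak-stock halt state (directed fishing on a link stops
#' when any member's quota is exhausted).
#'
#' @param rbcs Named vector: RBC tonnes per species or basket member group.
#' @param strategy An \code{mse_strategy}.
#' @param discard_estimates Named vector of expected discards per group
#'   (used only under discard accounting; missing treated as zero).
#' @param region_share Group x region matrix of biomass shares (rows sum to
#'   1); single-region strategies ignore it.
#' @param year Management year stamp.
#' @return A \code{tac_table}: records data.frame plus basket membership and
#'   companion state.
#' @export
set_tacs <- function(rbcs, strategy, discard_estimates = NULL,
                     region_share = NULL, year = 1L) {
  if (any(rbcs < 0)) stop("negative RBC")
  units <- tac_units(strategy)
  regions <- if (strategy$regional_tacs) names(strategy$regions) else "all"
  rec <- list()
  for (u in names(units)) {
    members <- units[[u]]
    rbc_u <- sum(rbcs[members], na.rm = TRUE)
    disc_u <- if (isTRUE(strategy$discard_accounting) && !is.null(discard_estimates))
      sum(discard_estimates[members], na.rm = TRUE) else 0
    for (rg in regions) {
      share <- if (length(regions) == 1) 1 else {
        if (is.null(region_share)) 1 / length(regions) else {
          s <- sum(region_share[members, rg, drop = FALSE]) / length(members)
          if (!is.finite(s)) 1 / length(regions) else s
        }
      }
      tac <- max(0, (rbc_u - disc_u) * share)
      rec[[length(rec) + 1L]] <- data.frame(
        unit = u, region = rg, year = year, tac = tac,
        landed = 0, overcatch = 0, undercatch = 0, stringsAsFactors = FALSE)
    }
  }
  structure(list(
    records = do.call(rbind, rec),
    units = units,
    companion_links = strategy$companion_links,
    halted = rep(FALSE, length(strategy$companion_links))
  ), class = "tac_table")
}

#' Quota units (single species and baskets) for a strategy
#' @param strategy An \code{mse_strategy}.
#' @return Named list: unit id -> member group ids.
#' @export
tac_units <- function(strategy) {
  units <- as.list(stats::setNames(strategy$species_under_tac,
                                   strategy$species_under_tac))
  for (b in names(strategy$baskets)) units[[b]] <- strategy$baskets[[b]]
  units
}

#' Map a group id to its quota unit (itself or its basket), or NA
#' @param group Group id.
#' @param tt A \code{tac_table}.
#' @export
unit_of <- function(group, tt) {
  for (u in names(tt$units)) if (group %in% tt$units[[u]]) return(u)
  NA_character_
}

tac_remaining <- function(tt, unit, region) {
  r <- tt$records
  i <- r$unit == unit & r$region == region
  if (!any(i)) return(Inf)
  sum(r$tac[i] - r$landed[i])
}

charge_landing <- function(tt, unit, region, tonnes) {
  i <- which(tt$records$unit == unit & tt$records$region == region)[1]
  if (is.na(i)) return(tt)
  tt$records$landed[i] <- tt$records$landed[i] + tonnes
  tt
}

# refresh weak-stock halt flags from current ledger state
update_companion_state <- function(tt) {
  if (!length(tt$companion_links)) return(tt)
  for (li in seq_along(tt$companion_links)) {
    link <- tt$companion_links[[li]]
    exhausted <- FALSE
    for (m in link) {
      u <- unit_of(m, tt)
      if (is.na(u)) next
      for (rg in unique(tt$records$region))
        if (tac_remaining(tt, u, rg) <= 1e-9) exhausted <- TRUE
    }
    tt$halted[li] <- exhausted
  }
  tt
}

# groups whose directed fishing is halted by a weak-stock companion link
halted_groups <- function(tt) {
  if (!length(tt$companion_links)) return(character())
  unique(unlist(tt$companion_links[tt$halted]))
}

#' Reconcile landings events against quota
#'
#' Under \code{"at_landing"} timing every landing event must be covered by
#' quota at that moment: any shortfall beyond available lease quota is
#' forfeited and recorded as overcatch. Under \code{"annual"} timing
#' landings accumulate freely and a single year-end reconciliation (after
#' leasing) records any excess as overcatch.
#'
#' @param tt A \code{tac_table}.
#' @param landings_events data.frame with columns \code{unit}, \code{region},
#'   \code{tonnes}, in time order.
#' @param timing \code{"at_landing"} or \code{"annual"}.
#' @param lease_available Named vector (by unit) or single number: quota
#'   tonnes obtainable by leasing.
#' @return List: updated \code{tt}, per-event \code{covered} and
#'   \code{forfeited}, total \code{overcatch}, \code{leased_used}.
#' @export
reconcile <- function(tt, landings_events, timing = c("at_landing", "annual"),
                      lease_available = 0) {
  timing <- match.arg(timing)
  n <- nrow(landings_events)
  covered <- forfeited <- numeric(n)
  lease_pool <- function(u) {
    if (is.null(names(lease_available))) return(lease_available[1])
    v <- lease_available[u]
    if (is.na(v)) 0 else unname(v)
  }
  leased_used <- 0
  if (n == 0) return(list(tt = tt, covered = covered, forfeited = forfeited,
                          overcatch = 0, leased_used = 0))
  if (timing == "at_landing") {
    for (i in seq_len(n)) {
      ev <- landings_events[i, ]
      rem <- tac_remaining(tt, ev$unit, ev$region)
      cov <- min(ev$tonnes, max(rem, 0))
      short <- ev$tonnes - cov
      if (short > 0) {
        lease <- min(short, max(lease_pool(ev$unit) - leased_used, 0))
        leased_used <- leased_used + lease
        cov <- cov + lease
        short <- short - lease
      }
      covered[i] <- cov
      forfeited[i] <- short
      tt <- charge_landing(tt, ev$unit, ev$region, ev$tonnes - short)
      if (short > 0) {
        j <- which(tt$records$unit == ev$unit & tt$records$region == ev$region)[1]
        if (!is.na(j)) tt$records$overcatch[j] <- tt$records$overcatch[j] + short
      }
    }
  } else {
    agg <- stats::aggregate(tonnes ~ unit + region, landings_events, sum)
    for (i in seq_len(nrow(agg))) {
      u <- agg$unit[i]; rg <- agg$region[i]; tons <- agg$tonnes[i]
      rem <- tac_remaining(tt, u, rg)
      short <- max(0, tons - max(rem, 0))
      if (short > 0) {
        lease <- min(short, max(lease_pool(u) - leased_used, 0))
        leased_used <- leased_used + lease
        short <- short - lease
      }
      tt <- charge_landing(tt, u, rg, tons)
      if (short > 0) {
        j <- which(tt$records$unit == u & tt$records$region == rg)[1]
        tt$records$overcatch[j] <- tt$records$overcatch[j] + short
      }
    }
    covered <- landings_events$tonnes  # all land; excess recorded above
    forfeited <- rep(0, n)
  }
  list(tt = tt, covered = covered, forfeited = forfeited,
       overcatch = sum(tt$records$overcatch), leased_used = leased_used)
}

#' Management cost accounts for a strategy-year
#'
#' Cost classes follow the indicator catalogue: general administration,
#' assessment (scaled by the number of assessed units over their assessment
#' frequency; catch-trend updates are cheaper per unit), research,
#' enforcement (scaled by closed-area extent and enforcement level),
#' monitoring (observers by coverage and active vessels, plus any survey).
#' The fishery is cost-recovered: the per-boat levy is total cost over
#' active vessels (reported as missing when no vessel is active).
#'
#' @param strategy An \code{mse_strategy}.
#' @param fleets Fleet state data.frame (uses \code{active_vessels}).
#' @param config Scenario.
#' @return List of cost classes ($), \code{total} and \code{levy_per_boat}.
#' @export
management_costs <- function(strategy, fleets, config) {
  p <- config$params
  mean_inv_freq <- mean(1 / strategy$assessment_frequency_years)
  assess_unit_cost <- p$cost_per_assessment *
    (if (strategy$tac_method == "catch_trend") 0.3 else 1)
  assessment <- assess_unit_cost * strategy$n_species_under_tac * mean_inv_freq
  area_w <- config$boxes$area_km2
  closed_extent <- mean(vapply(seq_len(ncol(strategy$zoning)), function(f)
    sum(area_w * (1 - strategy$zoning[, f])) / sum(area_w), numeric(1)))
  enforcement <- p$cost_enforcement_base * closed_extent * strategy$enforcement_level
  active <- sum(fleets$active_vessels)
  monitoring <- p$cost_observer_day * p$observer_days_vessel *
    strategy$observer_coverage * active +
    if (isTRUE(strategy$survey)) p$cost_survey else 0
  research <- p$cost_research_base *
    (if (strategy$tac_method == "dynamic_assessment") 1.5 else 1)
  admin <- p$cost_admin
  total <- admin + assessment + enforcement + monitoring + research
  list(admin = admin, assessment = assessment, research = research,
       enforcement = enforcement, monitoring = monitoring, total = total,
       levy_per_boat = if (active > 0) total / active else NA_real_)
}
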