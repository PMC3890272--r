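#' Initial ecosystem state for a scenario
#'
#' @param config An \code{mse_scenario}.
#' @param B_frac Starting biomass as a fraction of carrying capacity.
#' @return An \code{mse_state}: biomass matrix B (group x box), habitat cover
#'   H (box x habitat type), mean individual size per group, and time.
#' @export
initial_state <- function(config, B_frac = 0.7) {
  g <- config$groups
  B <- config$K * B_frac
  det <- which(g$guild == "detritus")
  # seed the detritus pool at a plausible standing stock
  B[det, ] <- colSums(config$K) * 0.02
  structure(list(
    year = 0L, quarter = 0L,
    B = B,
    H = config$habitat0,
    size = stats::setNames(g$mean_size_cm, g$id)
  ), class = "mse_state")
}

detritus_row <- function(config) which(config$groups$guild == "detritus")

# Availability matrix (predator row, prey column) and Holling half-saturation
# constants per predator x box, derived once per scenario.
om_context <- function(config) {
  g <- config$groups
  ng <- nrow(g); nb <- nrow(config$boxes)
  avail <- matrix(0, ng, ng, dimnames = list(g$id, g$id))
  tl <- config$trophic_links
  if (nrow(tl)) avail[cbind(tl$predator, tl$prey)] <- tl$availability
  # half saturation: fraction of available prey at carrying capacity; the
  # detritus pool (K = 0) uses a nominal reference standing stock so that
  # detritus feeders keep a responsive functional response
  det_i <- which(g$guild == "detritus")
  Keff <- config$K
  Keff[det_i, ] <- colSums(config$K) * 0.02
  AK <- avail %*% Keff               # predator x box, available prey at K
  bhalf <- config$params$bhalf_frac * AK
  bhalf[bhalf == 0] <- 1             # inert for non-predators
  list(avail = avail, bhalf = bhalf,
       is_pred = g$cmax > 0 & rowSums(avail) > 0,
       det = detritus_row(config),
       benthos = which(g$guild == "habitat_former"),
       Kshare = {
         ks <- config$K / pmax(rowSums(config$K), 1e-12)
         ks[rowSums(config$K) == 0, ] <- 0
         ks
       })
}

#' Stock-recruitment relationship with optional lognormal deviates
#'
#' Beverton-Holt by default: \eqn{R = 4 h R0 (S/B0) / ((1-h) + (5h-1) S/B0)},
#' or the hockey-stick variant \eqn{R = R0 \min(1, S/(0.2 B0))}. Deviates are
#' mean-unbiased lognormal (\eqn{\exp(\sigma z - \sigma^2/2)}).
#'
#' @param group One-row data.frame with \code{steepness}, \code{rec_form},
#'   \code{rec_sigma}.
#' @param spawning_biomass Spawning biomass S (tonnes), >= 0.
#' @param params List with \code{R0} (recruitment at S = B0, tonnes/yr) and
#'   \code{B0} (unfished spawning biomass, tonnes).
#' @param rng A stream rng from \code{make_rng}, or NULL for deterministic.
#' @return Annual recruitment (tonnes of new biomass).
#' @export
recruit <- function(group, spawning_biomass, params, rng = NULL) {
  stopifnot(spawning_biomass >= 0)
  h <- group$steepness
  if (is.na(h) || h <= 0.2 || h > 1)
    stop("steepness must be in (0.2, 1], got ", h)
  if (spawning_biomass == 0) return(0)
  s <- spawning_biomass / params$B0
  R <- switch(group$rec_form,
    beverton_holt = 4 * h * params$R0 * s / ((1 - h) + (5 * h - 1) * s),
    hockey_stick  = params$R0 * min(1, s / 0.2),
    stop("unknown recruitment form: ", group$rec_form))
  sigma <- group$rec_sigma %||% 0
  if (!is.na(sigma) && sigma > 0 && !is.null(rng)) {
    z <- rng_draw(rng, stats::rnorm, 1)
    R <- R * exp(sigma * z - sigma^2 / 2)
  }
  R
}

#' Habitat dynamics under gear impact
#'
#' Logistic recovery minus swept-area impact:
#' \eqn{H' = H + \rho_h H (1 - H) - \sum_f \iota_{gear(f)} s_h (swept_f / area) H},
#' clipped to [0,1]. Only bottom-contact gears have positive impact rates.
#'
#' @param H Box x habitat-type cover matrix, entries in [0,1].
#' @param swept Fleet x box swept/interaction area (km^2) this quarter.
#' @param config Scenario.
#' @return Updated cover matrix.
#' @export
update_habitat <- function(H, swept, config) {
  stopifnot(all(H >= 0 & H <= 1), all(swept >= 0))
  p <- config$params
  irate <- p$impact_rate[config$fleets$gear]
  dens <- colSums(swept * irate) / config$boxes$area_km2
  for (h in seq_along(config$habitat_types)) {
    ht <- config$habitat_types[h]
    rec <- p$habitat_recovery[[ht]]
    sens <- p$habitat_sens[[ht]]
    H[, h] <- H[, h] + rec * H[, h] * (1 - H[, h]) - dens * sens * H[, h]
  }
  clamp(H, 0, 1)
}

#' Detritus pool dynamics
#'
#' \eqn{D' = D + discards + incidental + natural\_dead - decay \cdot D -
#' scavenger\_consumption}, floored at zero. Scavenger consumption of
#' detritus is computed by the trophic submodel (Holling type II on the
#' pool), which closes the discard-fed detritus-scavenger loop.
#'
#' @param D Detritus tonnes per box.
#' @param discards Discard tonnes per box entering the pool.
#' @param incidental Incidental-mortality tonnes per box.
#' @param params Scenario params (uses \code{detritus_decay}).
#' @param natural_dead Natural-death flux reaching the pool, per box.
#' @param scavenger_consumption Tonnes consumed from the pool, per box.
#' @return Updated pool with a \code{"ledger"} attribute of the exact terms.
#' @export
update_detritus <- function(D, discards, incidental, params,
                            natural_dead = 0, scavenger_consumption = 0) {
  stopifnot(all(D >= 0), all(discards >= 0), all(incidental >= 0))
  decay <- params$detritus_decay * D
  out <- D + discards + incidental + natural_dead - decay - scavenger_consumption
  out <- pmax(out, 0)
  attr(out, "ledger") <- list(inputs = discards + incidental + natural_dead,
                              decay = decay, consumed = scavenger_consumption)
  out
}

#' Advance the ecosystem one quarter
#'
#' Applies, in order: habitat-modified production (somatic growth plus
#' recruitment), trophic mortality (Holling type II on the availability
#' matrix, with predator growth modulated by food intake), natural mortality,
#' removals (catch plus discards), incidental benthos mortality from swept
#' area, mobility exchange, habitat update and detritus update. All terms are
#' computed from the start-of-quarter state and returned in an exact ledger.
#'
#' @param state An \code{mse_state}.
#' @param removals Group x box tonnes removed by fishing (catch + discards).
#' @param swept Fleet x box swept/interaction area (km^2).
#' @param config Scenario.
#' @param rng Optional stream rng for recruitment deviates.
#' @param discards_to_detritus Tonnes per box of discards entering the
#'   detritus pool (the runner passes the discarded share of removals).
#' @return New \code{mse_state}; attribute \code{"ledger"} holds every flux
#'   (production, predation, natural, removals, incidental, mobility_net,
#'   detritus terms) so that \eqn{B' = B + P - T - N - R - I + mobility}
#'   can be verified exactly.
#' @export
step_quarter <- function(state, removals, swept, config, rng = NULL,
                         discards_to_detritus = NULL) {
  g <- config$groups
  ng <- nrow(g); nb <- nrow(config$boxes)
  if (is.null(dim(removals))) removals <- matrix(removals, ng, nb)
  if (is.null(dim(swept))) swept <- matrix(swept, nrow(config$fleets), nb)
  if (any(removals < 0)) stop("negative removals")
  if (any(swept < 0)) stop("negative swept area")
  if (is.null(discards_to_detritus)) discards_to_detritus <- numeric(nb)
  p <- config$params
  ctx <- om_context(config)
  B <- state$B
  det <- ctx$det
  area <- config$boxes$area_km2

  # habitat quality per box (sensitivity-weighted cover)
  wts <- p$habitat_sens[config$habitat_types]
  quality <- as.numeric(state$H %*% wts) / sum(wts)

  # food intake saturation per predator x box
  A <- ctx$avail %*% B                       # available prey biomass
  phi <- A / (ctx$bhalf + A)
  f_food <- matrix(1, ng, nb)
  f_food[ctx$is_pred, ] <- pmin(p$f_food_max, phi[ctx$is_pred, ] / p$phi_ref)

  # production: logistic somatic growth (habitat-modified) + recruitment
  hmod <- 1 - outer(g$habitat_dependency, 1 - quality)
  logi <- matrix(0, ng, nb)
  ok <- config$K > 0
  logi[ok] <- (B * (1 - B / config$K))[ok]
  logi[!ok] <- -B[!ok]                       # decay where no capacity
  P <- hmod * f_food * (g$r / 4) * logi
  P[det, ] <- 0
  rec_q <- matrix(0, ng, nb)
  for (i in seq_len(ng)[-det]) {
    if (is.na(g$rec_share[i]) || g$rec_share[i] <= 0) next
    K_i <- sum(config$K[i, ])
    R0 <- g$rec_share[i] * g$M[i] * K_i
    if (R0 <= 0 || K_i <= 0) next
    Rann <- recruit(g[i, ], sum(B[i, ]), list(R0 = R0, B0 = K_i), rng)
    rec_q[i, ] <- Rann / 4 * ctx$Kshare[i, ]
  }
  P <- P + rec_q

  # trophic mortality (predation + scavenging on detritus)
  Tm <- matrix(0, ng, nb)
  cons_det <- numeric(nb)
  for (pr in which(ctx$is_pred)) {
    denom <- ctx$bhalf[pr, ] + A[pr, ]
    for (py in which(ctx$avail[pr, ] > 0)) {
      cons <- (g$cmax[pr] / 4) * B[pr, ] * ctx$avail[pr, py] * B[py, ] / denom
      Tm[py, ] <- Tm[py, ] + cons
      if (py == det) cons_det <- cons_det + cons
    }
  }

  # natural mortality
  Nm <- (g$M / 4) * B
  Nm[det, ] <- 0

  # removals, capped by availability
  Rm <- removals
  cap <- p$avail_cap * B
  if (any(Rm > cap + 1e-9)) {
    warning("removals exceed available biomass in ",
            sum(Rm > cap + 1e-9), " cells; capped")
    Rm <- pmin(Rm, cap)
  }

  # incidental benthos mortality from bottom-contact swept area
  Im <- matrix(0, ng, nb)
  bc <- config$fleets$bottom_contact
  if (length(ctx$benthos) && any(bc)) {
    dens <- colSums(swept[bc, , drop = FALSE]) / area
    Im[ctx$benthos, ] <- p$incidental_rate * dens * B[ctx$benthos, ]
  }

  # enforce non-negativity: natural/predation/incidental losses scale into
  # the headroom left after removals (so the fishing ledger stays exact);
  # only if headroom is negative are removals themselves cut, with the
  # factor reported so callers can rescale landings/discards identically
  removal_scale <- matrix(1, ng, nb)
  headroom <- B + P - Rm
  neg <- headroom < 0
  if (any(neg)) {
    removal_scale[neg] <- pmax(0, (B + P)[neg]) / pmax(Rm[neg], 1e-12)
    Rm[neg] <- Rm[neg] * removal_scale[neg]
    headroom[neg] <- 0
  }
  loss <- Tm + Nm + Im
  scl <- matrix(1, ng, nb)
  over <- loss > headroom & loss > 0
  scl[over] <- pmax(0, headroom[over]) / loss[over]
  Tm <- Tm * scl; Nm <- Nm * scl; Im <- Im * scl
  cons_det <- cons_det * scl[det, ]

  B1 <- B + P - Tm - Nm - Rm - Im
  B1[B1 < 0] <- 0   # guard against roundoff

  # mobility exchange: mass-conserving, directed toward suitable habitat
  # (destination weight proportional to the neighbour's carrying capacity)
  mob_net <- matrix(0, ng, nb)
  for (i in seq_len(ng)) {
    m <- g$mobility[i]
    if (m <= 0) next
    Kdest <- if (i == det) rep(1, nb) else config$K[i, ]
    W <- config$adjacency * rep(Kdest, each = nb)
    rs <- rowSums(W)
    movable <- rs > 0
    W[movable, ] <- W[movable, , drop = FALSE] / rs[movable]
    out_flow <- m * B1[i, ] * movable
    in_flow <- as.numeric(crossprod(W, out_flow))
    mob_net[i, ] <- in_flow - out_flow
  }
  B2 <- B1 + mob_net

  # habitat + detritus updates
  H2 <- update_habitat(state$H, swept, config)
  natural_dead <- p$dead_to_detritus * colSums(Nm)
  inc_total <- colSums(Im)
  D2 <- update_detritus(B2[det, ], discards_to_detritus, inc_total, p,
                        natural_dead = natural_dead,
                        scavenger_consumption = 0)  # consumption already in Tm
  det_ledger <- attr(D2, "ledger")
  B2[det, ] <- as.numeric(D2)

  # mean size response to exploitation
  U <- pmin(1, 4 * rowSums(Rm) / pmax(rowSums(B), 1e-9))
  size0 <- config$groups$mean_size_cm
  target <- size0 * (1 - p$size_sens * U)
  size2 <- state$size + p$size_k * (target - state$size)
  size2[is.na(size0)] <- NA

  q_next <- state$quarter %% 4 + 1L
  out <- structure(list(
    year = state$year + as.integer(q_next == 1L),
    quarter = q_next,
    B = B2, H = H2, size = size2
  ), class = "mse_state")
  attr(out, "ledger") <- list(
    production = P, predation = Tm, natural = Nm, removals = Rm,
    incidental = Im, mobility_net = mob_net,
    detritus = det_ledger, detritus_consumed = cons_det,
    removal_scale = removal_scale, capped = any(over))
  out
}

#' Find the unfished equilibrium of the operating model
#'
#' Damped fixed-point iteration of \code{\link{step_quarter}} with zero
#' removals until the relative one-quarter change falls below \code{tol}.
#'
#' @param config Scenario.
#' @param tol Convergence tolerance on max |dB|/B per quarter.
#' @param max_iter Iteration budget.
#' @param damp Damping factor in (0, 1].
#' @param start Optional \code{mse_state} used as a warm start (e.g. the
#'   equilibrium of a nearby parameterisation).
#' @return Converged \code{mse_state}; attribute \code{"residual"} holds the
#'   final one-step relative change and \code{"iterations"} the count.
#' @export
initialize_equilibrium <- function(config, tol = 1e-9, max_iter = 20000,
                                   damp = 1.0, start = NULL) {
  g <- config$groups
  zero_r <- g$r <= 0 & g$guild != "detritus"
  if (any(zero_r))
    warning("groups with zero growth rate will equilibrate at zero biomass: ",
            paste(g$id[zero_r], collapse = ", "))
  st <- if (is.null(start)) initial_state(config) else start
  nf <- nrow(config$fleets); nb <- nrow(config$boxes)
  zero_rem <- matrix(0, nrow(g), nb)
  zero_swept <- matrix(0, nf, nb)
  resid <- Inf
  # entrywise Aitken delta-squared acceleration on snapshots spaced `span`
  # iterations apart: fast modes decay between snapshots, so the
  # extrapolation cleanly removes the dominant slow mode
  span <- 12L
  snaps <- list()
  for (it in seq_len(max_iter)) {
    nx <- step_quarter(st, zero_rem, zero_swept, config, rng = NULL)
    dB <- nx$B - st$B
    resid <- max(abs(dB) / pmax(st$B, 1e-6))
    st$B <- st$B + damp * dB
    st$H <- nx$H
    st$size <- nx$size
    if (resid < tol) break
    if (it %% span == 0L) {
      snaps <- c(snaps, list(st$B))
      if (length(snaps) == 3L) {
        d1 <- snaps[[2]] - snaps[[1]]
        d2 <- snaps[[3]] - snaps[[2]]
        den <- d2 - d1
        ok <- abs(den) > 1e-12 & abs(d2) < abs(d1)  # geometric contraction only
        acc <- st$B
        acc[ok] <- snaps[[3]][ok] - d2[ok]^2 / den[ok]
        st$B <- pmax(acc, 0)
        snaps <- list()
      }
    }
  }
  if (resid >= tol)
    stop("equilibrium not found within ", max_iter,
         " iterations; residual = ", signif(resid, 4))
  st$year <- 0L; st$quarter <- 0L
  attr(st, "residual") <- resid
  attr(st, "iterations") <- it
  st
}

#' Tidy snapshot of an ecosystem state
#' @param state An \code{mse_state}.
#' @return data.frame with year, quarter, box, group, biomass.
#' @export
ecosystem_snapshot <- function(state) {
  data.frame(
    year = state$year, quarter = state$quarter,
    box = rep(colnames(state$B), each = nrow(state$B)),
    group = rep(rownames(state$B), ncol(state$B)),
    biomass = as.numeric(state$B),
    stringsAsFactors = FALSE
  )
}

#' Write quarterly snapshots to CSV with bit-exact numeric round-trip
#' @param snapshots data.frame as from \code{\link{ecosystem_snapshot}}.
#' @param path Output path.
#' @export
write_snapshots <- function(snapshots, path) {
  x <- snapshots
  x$biomass <- sprintf("%.17g", x$biomass)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read snapshots written by \code{\link{write_snapshots}}
#' @param path CSV path.
#' @export
read_snapshots <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$biomass <- as.numeric(x$biomass)
  x
}
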