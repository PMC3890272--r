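#' Generate a packaged fishery-ecosystem scenario
#'
#' Builds a fully specified multispecies, multi-fleet spatial fishery scenario
#' from a packaged template. The \code{"reference"} template emulates a
#' temperate shelf/slope fishery: 12 functional groups (demersal and pelagic
#' fish, chondrichthyans, squid, forage fish, a threatened/endangered/protected
#' (TEP) group, scavengers, habitat-forming benthos and a detritus pool) across
#' 6 depth-stratified spatial boxes fished by 4 gear sectors, with a 10-year
#' burn-in, a 10-year historical phase and a 40-year projection. The
#' \code{"minimal"} template is a tiny 2-box, 2-group configuration used for
#' fast structural checks.
#'
#' @param template_id One of \code{"reference"}, \code{"minimal"}.
#' @param seed Integer seed recorded in the config; all downstream randomness
#'   derives from it through named streams (see \code{\link{stream_seed}}).
#' @return An object of class \code{mse_scenario}.
#' @export
generate_scenario <- function(template_id, seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) || seed != round(seed))
    stop("seed must be a single integer")
  seed <- as.integer(seed)
  cfg <- switch(template_id,
    reference = reference_template(seed),
    minimal   = minimal_template(seed),
    stop("unknown scenario template: '", template_id,
         "' (known templates: reference, minimal)")
  )
  diags <- validate_scenario(cfg)
  if (length(diags)) stop("generated scenario failed validation: ",
                          paste(diags, collapse = "; "))
  cfg
}

# ---- reference template ----------------------------------------------------

reference_template <- function(seed) {
  boxes <- data.frame(
    id = c("inshore_e", "shelf_e", "shelf_w", "slope_e", "slope_w", "deep"),
    area_km2 = c(5000, 20000, 20000, 15000, 15000, 25000),
    depth_stratum = c("inshore", "shelf", "shelf", "upper_slope", "upper_slope", "deep"),
    stringsAsFactors = FALSE
  )
  nb <- nrow(boxes)
  adjacency <- matrix(0, nb, nb, dimnames = list(boxes$id, boxes$id))
  links <- rbind(
    c("inshore_e", "shelf_e"), c("shelf_e", "shelf_w"), c("shelf_e", "slope_e"),
    c("shelf_w", "slope_w"), c("slope_e", "slope_w"), c("slope_e", "deep"),
    c("slope_w", "deep")
  )
  for (i in seq_len(nrow(links))) {
    adjacency[links[i, 1], links[i, 2]] <- 1
    adjacency[links[i, 2], links[i, 1]] <- 1
  }

  ports <- data.frame(id = c("east_port", "west_port"),
                      population0 = c(5000, 3000), stringsAsFactors = FALSE)
  port_distance <- matrix(
    c( 30, 250,    # inshore_e
       80, 200,    # shelf_e
      220,  60,    # shelf_w
      150, 260,    # slope_e
      260, 120,    # slope_w
      320, 300),   # deep
    nrow = nb, byrow = TRUE, dimnames = list(boxes$id, ports$id))

  groups <- data.frame(
    id = c("flathead", "ling", "gummy_shark", "gulper_shark", "morwong",
           "squid", "small_pelagic", "mackerel", "seabird_mammal",
           "scavenger", "benthos", "detritus"),
    guild = c("target", "target", "target", "bycatch", "byproduct",
              "target", "forage", "target", "TEP",
              "scavenger", "habitat_former", "detritus"),
    trophic_level = c(3.6, 4.0, 4.1, 4.2, 3.2, 3.0, 2.6, 3.9, 4.5, 3.1, 2.0, 1.0),
    habitat_assoc = c("demersal", "demersal", "demersal", "demersal", "demersal",
                      "pelagic", "pelagic", "pelagic", "pelagic",
                      "demersal", "demersal", "demersal"),
    finfish = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE,
                FALSE, FALSE, FALSE),
    piscivore = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE,
                  FALSE, FALSE, FALSE),
    r = c(0.60, 0.35, 0.25, 0.08, 0.50, 1.50, 1.20, 0.55, 0.06, 0.80, 0.40, 0),
    M = c(0.25, 0.18, 0.12, 0.08, 0.30, 1.20, 0.80, 0.30, 0.05, 0.60, 0.20, 0),
    steepness = c(0.80, 0.75, 0.60, 0.45, 0.80, 0.90, 0.85, 0.75, 0.40, 0.85, 0.75, NA),
    rec_form = c(rep("beverton_holt", 11), NA),
    rec_share = c(rep(0.15, 11), NA),   # R0 as a fraction of M * K
    rec_sigma = c(rep(0, 11), NA),      # deterministic ecology by default
    mobility = c(0.10, 0.10, 0.15, 0.05, 0.08, 0.30, 0.30, 0.30, 0.40, 0.10, 0.0, 0.02),
    mean_size_cm = c(35, 75, 110, 90, 30, 25, 12, 45, 150, 20, 5, NA),
    price = c(5800, 8500, 7000, 2200, 3600, 2900, 1100, 2600, 0, 450, 0, 0),
    habitat_dependency = c(0.40, 0.30, 0.20, 0.30, 0.50, 0.0, 0.0, 0.0, 0.0, 0.20, 0.60, 0),
    cmax = c(1.0, 0.8, 0.6, 0.4, 0, 2.0, 0, 1.2, 1.5, 1.5, 0, 0),
    tier = c(1, 1, 1, 3, 2, 2, 3, 2, 3, 3, 3, NA),
    stringsAsFactors = FALSE
  )
  ng <- nrow(groups)

  # carrying capacity (tonnes) distributed over boxes
  K_total <- c(flathead = 90000, ling = 60000, gummy_shark = 30000,
               gulper_shark = 10000, morwong = 50000, squid = 60000,
               small_pelagic = 200000, mackerel = 50000, seabird_mammal = 5000,
               scavenger = 40000, benthos = 300000, detritus = 0)
  # box weights per group (rows sum to 1)
  w <- rbind(
    flathead       = c(0.15, 0.40, 0.35, 0.05, 0.05, 0.00),
    ling           = c(0.00, 0.10, 0.10, 0.35, 0.35, 0.10),
    gummy_shark    = c(0.25, 0.35, 0.30, 0.05, 0.05, 0.00),
    gulper_shark   = c(0.00, 0.00, 0.00, 0.30, 0.30, 0.40),
    morwong        = c(0.10, 0.40, 0.40, 0.05, 0.05, 0.00),
    squid          = c(0.15, 0.35, 0.35, 0.08, 0.07, 0.00),
    small_pelagic  = c(0.15, 0.35, 0.35, 0.08, 0.07, 0.00),
    mackerel       = c(0.05, 0.30, 0.30, 0.15, 0.15, 0.05),
    seabird_mammal = c(0.10, 0.25, 0.25, 0.15, 0.15, 0.10),
    scavenger      = c(0.10, 0.25, 0.25, 0.15, 0.15, 0.10),
    benthos        = c(0.05, 0.20, 0.20, 0.15, 0.15, 0.25),
    detritus       = c(1/6, 1/6, 1/6, 1/6, 1/6, 1/6)
  )
  K <- w * K_total[rownames(w)]
  dimnames(K) <- list(groups$id, boxes$id)

  trophic_links <- data.frame(
    predator = c("flathead", "flathead", "flathead",
                 "ling", "ling", "ling",
                 "gummy_shark", "gummy_shark", "gummy_shark",
                 "gulper_shark", "gulper_shark", "gulper_shark",
                 "mackerel", "mackerel",
                 "seabird_mammal", "seabird_mammal", "seabird_mammal",
                 "scavenger", "scavenger",
                 "squid"),
    prey = c("small_pelagic", "squid", "benthos",
             "morwong", "flathead", "squid",
             "flathead", "morwong", "squid",
             "morwong", "squid", "scavenger",
             "small_pelagic", "squid",
             "small_pelagic", "squid", "mackerel",
             "detritus", "benthos",
             "small_pelagic"),
    availability = c(0.30, 0.20, 0.10,
                     0.20, 0.10, 0.20,
                     0.15, 0.15, 0.10,
                     0.10, 0.15, 0.15,
                     0.40, 0.20,
                     0.30, 0.20, 0.10,
                     0.50, 0.10,
                     0.20),
    stringsAsFactors = FALSE
  )

  fleets <- data.frame(
    id = c("bottom_trawl", "danish_seine", "gillnet_longline", "midwater_seine_jig"),
    gear = c("bottom_trawl", "danish_seine", "gillnet", "midwater_seine_jig"),
    bottom_contact = c(TRUE, TRUE, FALSE, FALSE),
    licences = c(50L, 20L, 30L, 15L),
    active_vessels = c(40L, 15L, 25L, 12L),
    latent_vessels = c(10L, 5L, 5L, 3L),
    mesh_mm = c(90, 38, 160, 20),
    sel_l50_factor = c(0.25, 0.50, 0.50, 0.30),
    days_per_quarter = c(60, 60, 60, 60),
    fuel_cost_day = c(2000, 1100, 900, 1800),
    gear_cost_day = c(400, 250, 300, 300),
    dist_cost_km_day = c(3, 3, 2, 3),
    refrig_cost_t = c(150, 150, 120, 100),
    unload_cost_t = c(100, 100, 100, 80),
    fixed_cost_yr = c(120000, 80000, 70000, 100000),
    compliance_trait = c(0.80, 0.85, 0.75, 0.90),
    home_port = c("east_port", "east_port", "west_port", "east_port"),
    sweep_km2_day = c(0.50, 0.30, 0.05, 0.02),
    base_discard_rate = c(0.25, 0.20, 0.08, 0.10),
    stringsAsFactors = FALSE
  )
  nf <- nrow(fleets)

  q <- matrix(0, nf, ng, dimnames = list(fleets$id, groups$id))
  q["bottom_trawl", c("flathead", "ling", "morwong", "gulper_shark", "squid",
                      "gummy_shark", "scavenger", "seabird_mammal")] <-
    c(1.50, 1.20, 1.20, 0.80, 0.60, 0.30, 0.40, 0.010)
  q["danish_seine", c("flathead", "morwong", "squid", "scavenger")] <-
    c(1.50, 1.20, 0.80, 0.30)
  q["gillnet_longline", c("gummy_shark", "ling", "gulper_shark", "flathead",
                          "seabird_mammal")] <-
    c(1.50, 0.80, 0.50, 0.30, 0.050)
  q["midwater_seine_jig", c("small_pelagic", "mackerel", "squid",
                            "seabird_mammal")] <-
    c(2.00, 1.50, 1.20, 0.020)

  price_season <- matrix(1, ng, 4, dimnames = list(groups$id, paste0("Q", 1:4)))
  price_season["squid", ] <- c(0.9, 0.9, 1.0, 1.3)
  price_season["mackerel", ] <- c(0.9, 1.0, 1.0, 1.2)

  habitat_types <- c("biogenic", "soft_sediment")
  habitat0 <- matrix(1, nrow(boxes), length(habitat_types),
                     dimnames = list(boxes$id, habitat_types))

  params <- list(
    # operating model
    avail_cap = 0.8,          # max removable fraction of a group per quarter
    phi_ref = 0.6,            # food saturation giving unit predator growth
    f_food_max = 1.3,
    bhalf_frac = 0.5,         # Holling half-saturation as fraction of avail. K
    habitat_recovery = c(biogenic = 0.01, soft_sediment = 0.15),  # per quarter
    habitat_sens = c(biogenic = 1.0, soft_sediment = 0.3),
    impact_rate = c(bottom_trawl = 0.60, danish_seine = 0.35,
                    gillnet = 0.0, midwater_seine_jig = 0.0),
    incidental_rate = 0.30,   # benthos kill per unit swept density
    detritus_decay = 0.15,    # per quarter
    dead_to_detritus = 0.40,  # share of natural+predation deaths reaching pool
    size_k = 0.2,             # mean-size relaxation per quarter
    size_sens = 0.8,          # max proportional size decline at full exploitation
    # fleet behaviour
    softmax_temp = 1000,      # $ per day scale of profit-choice noise
    inertia = 0.5,
    pulse_scale = 0.3,        # effort retained in low-price quarters at a loss
    neg_margin_days = 20,     # days fished per quarter when expected margin < 0
    loss_streak_threshold = 3,
    exit_frac = 0.15,         # active vessels leaving per trigger year
    gear_switch_hurdle = 1.2, # expected profit ratio needed to switch gear
    trip_speed_km_day = 300,
    hold_tonnes = 15,
    # quota market
    lease_price_frac = 0.10,  # floor lease price as a fraction of fish price
    lease_scarcity_slope = 0.5,
    # management machinery
    B_lim_frac = 0.2,
    B_targ_frac = 0.4,
    F_target_frac = 0.9,      # F_target = frac * M
    tier_buffer = c(1.0, 0.9, 0.8),
    tier_cv = c(0.20, 0.30, 0.40),
    survey_cv_factor = 0.75,
    trend_window = 3,
    trend_max_step = 0.2,
    overcatch_penalty = 2.0,  # $ multiple of landed value forfeited
    # management costs ($)
    cost_admin = 1.5e6,
    cost_per_assessment = 1.0e5,
    cost_enforcement_base = 2.0e6,
    cost_observer_day = 600,
    observer_days_vessel = 100,
    cost_survey = 1.2e6,
    cost_research_base = 8e5,
    # social
    port_half_landings = 10000, # tonnes at which port activity half-saturates
    port_pop_k = 0.15,
    gear_conflict_threshold = 200, # vessel-days per box-quarter
    loss_penalty = 2.0
  )

  structure(list(
    template = "reference", seed = seed, strategy_id = "S1_status_quo",
    phases = c(burn_in = 10L, historical = 10L, projection = 40L),
    quarters_per_year = 4L,
    boxes = boxes, adjacency = adjacency, ports = ports,
    port_distance = port_distance,
    groups = groups, K = K, trophic_links = trophic_links,
    fleets = fleets, q = q, price_season = price_season,
    habitat_types = habitat_types, habitat0 = habitat0,
    params = params
  ), class = "mse_scenario")
}

# ---- minimal template ------------------------------------------------------

minimal_template <- function(seed) {
  boxes <- data.frame(id = c("b1", "b2"), area_km2 = c(1000, 1000),
                      depth_stratum = c("shelf", "shelf"), stringsAsFactors = FALSE)
  adjacency <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(boxes$id, boxes$id))
  ports <- data.frame(id = "p1", population0 = 1000, stringsAsFactors = FALSE)
  port_distance <- matrix(c(20, 40), 2, 1, dimnames = list(boxes$id, ports$id))
  groups <- data.frame(
    id = c("fish", "detritus"),
    guild = c("target", "detritus"),
    trophic_level = c(3.0, 1.0),
    habitat_assoc = c("demersal", "demersal"),
    finfish = c(TRUE, FALSE), piscivore = c(FALSE, FALSE),
    r = c(0.5, 0), M = c(0.2, 0),
    steepness = c(0.75, NA), rec_form = c("beverton_holt", NA),
    rec_share = c(0.15, NA), rec_sigma = c(0, NA),
    mobility = c(0.1, 0.02), mean_size_cm = c(30, NA),
    price = c(3000, 0), habitat_dependency = c(0.2, 0),
    cmax = c(0, 0), tier = c(1, NA),
    stringsAsFactors = FALSE
  )
  K <- matrix(c(20000, 20000, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(groups$id, boxes$id))
  trophic_links <- data.frame(predator = character(), prey = character(),
                              availability = numeric(), stringsAsFactors = FALSE)
  fleets <- data.frame(
    id = "trawl", gear = "bottom_trawl", bottom_contact = TRUE,
    licences = 5L, active_vessels = 4L, latent_vessels = 1L,
    mesh_mm = 90, sel_l50_factor = 0.25, days_per_quarter = 60,
    fuel_cost_day = 1000, gear_cost_day = 200, dist_cost_km_day = 2,
    refrig_cost_t = 100, unload_cost_t = 80, fixed_cost_yr = 50000,
    compliance_trait = 0.9, home_port = "p1",
    sweep_km2_day = 0.2, base_discard_rate = 0, stringsAsFactors = FALSE
  )
  q <- matrix(c(0.3, 0), 1, 2, dimnames = list(fleets$id, groups$id))
  price_season <- matrix(1, 2, 4, dimnames = list(groups$id, paste0("Q", 1:4)))
  habitat_types <- c("biogenic")
  habitat0 <- matrix(1, 2, 1, dimnames = list(boxes$id, habitat_types))
  params <- reference_template(0L)$params
  params$impact_rate <- c(bottom_trawl = 0.1, danish_seine = 0, gillnet = 0,
                          midwater_seine_jig = 0)
  params$habitat_recovery <- c(biogenic = 0.05)
  params$habitat_sens <- c(biogenic = 1.0)
  # management cost base scaled to the small fishery
  params$cost_admin <- 2e5
  params$cost_research_base <- 5e4
  params$cost_enforcement_base <- 2e5
  params$cost_survey <- 1e5
  params$cost_per_assessment <- 1e4
  structure(list(
    template = "minimal", seed = as.integer(seed), strategy_id = "S1_status_quo",
    phases = c(burn_in = 10L, historical = 10L, projection = 20L),
    quarters_per_year = 4L,
    boxes = boxes, adjacency = adjacency, ports = ports,
    port_distance = port_distance,
    groups = groups, K = K, trophic_links = trophic_links,
    fleets = fleets, q = q, price_season = price_season,
    habitat_types = habitat_types, habitat0 = habitat0,
    params = params
  ), class = "mse_scenario")
}

# ---- validation ------------------------------------------------------------

#' Validate a scenario configuration
#'
#' Checks referential integrity (trophic links, fleet/port references,
#' matrix dimnames), non-negativity of all rate parameters, phase lengths and
#' structural invariants (exactly one detritus group, mobility and cover
#' fractions in [0,1]).
#'
#' @param config An \code{mse_scenario}.
#' @return Character vector of diagnostics; zero-length if the scenario is valid.
#' @export
validate_scenario <- function(config) {
  d <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) d <<- c(d, msg)
  g <- config$groups; b <- config$boxes; f <- config$fleets
  chk(config$phases[["burn_in"]] >= 1 && config$phases[["historical"]] >= 1,
      "burn-in and historical phases must be at least 1 year")
  chk(config$phases[["projection"]] >= 1, "projection must be at least 1 year")
  chk(all(b$area_km2 > 0), "box areas must be positive")
  chk(sum(g$guild == "detritus") == 1, "exactly one detritus group required")
  num_ok <- function(x) all(is.finite(x) & x >= 0)
  chk(num_ok(g$r), "growth rates must be finite and non-negative")
  chk(num_ok(g$M), "natural mortality must be finite and non-negative")
  chk(num_ok(config$K), "carrying capacities must be finite and non-negative")
  chk(all(g$mobility >= 0 & g$mobility <= 1), "mobility must be in [0,1]")
  chk(all(config$habitat0 >= 0 & config$habitat0 <= 1), "habitat cover must be in [0,1]")
  tl <- config$trophic_links
  if (nrow(tl)) {
    chk(all(tl$predator %in% g$id) && all(tl$prey %in% g$id),
        "trophic links must reference declared groups")
    chk(all(tl$availability >= 0 & tl$availability <= 1),
        "trophic availabilities must be in [0,1]")
  }
  chk(all(f$active_vessels + f$latent_vessels <= f$licences),
      "active + latent vessels must not exceed licences")
  chk(all(f$mesh_mm > 0), "mesh sizes must be positive")
  chk(all(f$compliance_trait >= 0 & f$compliance_trait <= 1),
      "compliance traits must be in [0,1]")
  chk(all(f$home_port %in% config$ports$id), "home ports must be declared ports")
  chk(num_ok(config$q), "catchabilities must be finite and non-negative")
  chk(identical(rownames(config$K), g$id) && identical(colnames(config$K), b$id),
      "K dimnames must match groups and boxes")
  chk(num_ok(g$price), "prices must be finite and non-negative")
  d
}

# ---- ensembles -------------------------------------------------------------

#' Specify an ensemble of perturbed parameterisations
#'
#' @param n_members Number of members (>= 2); member 0 (the first) is always
#'   the unperturbed base configuration.
#' @param perturbed_parameters Named numeric vector: parameter path ->
#'   multiplicative coefficient of variation (CV). Supported paths:
#'   \code{"groups.r"}, \code{"groups.steepness"}, \code{"groups.price"},
#'   \code{"q"} (catchability).
#' @param structural_variants Character vector, one per member (recycled),
#'   each \code{"beverton_holt"} or \code{"hockey_stick"}; the first member
#'   always keeps the base recruitment form.
#' @param base_seed Integer seed for the perturbation stream.
#' @return An \code{ensemble_spec} list.
#' @export
ensemble_spec <- function(n_members = 10,
                          perturbed_parameters = c("groups.r" = 0.10,
                                                   "groups.steepness" = 0.05,
                                                   "groups.price" = 0.10,
                                                   "q" = 0.10),
                          structural_variants = NULL,
                          base_seed = 1L) {
  stopifnot(n_members >= 2, all(perturbed_parameters >= 0))
  structure(list(n_members = as.integer(n_members),
                 perturbed_parameters = perturbed_parameters,
                 structural_variants = structural_variants,
                 base_seed = as.integer(base_seed)),
            class = "ensemble_spec")
}

perturb_path <- function(cfg, path, mult) {
  switch(path,
    "groups.r" = { cfg$groups$r <- cfg$groups$r * mult; cfg },
    "groups.steepness" = {
      s <- cfg$groups$steepness * mult
      cfg$groups$steepness <- clamp(s, 0.25, 1)
      cfg
    },
    "groups.price" = { cfg$groups$price <- cfg$groups$price * mult; cfg },
    "q" = { cfg$q <- cfg$q * mult; cfg },
    stop("unresolvable parameter path: '", path, "'")
  )
}

#' Generate an ensemble of perturbed scenario configurations
#'
#' Member 1 is the unperturbed base config; members 2..n receive independent
#' mean-preserving lognormal multipliers (median 1, stated CV) on each
#' perturbed parameter, plus any structural recruitment-form variant. All
#' draws derive from \code{spec$base_seed} through the "ensemble" stream.
#'
#' @param config Base \code{mse_scenario}.
#' @param spec An \code{\link{ensemble_spec}}.
#' @return List of \code{mse_scenario}, length \code{spec$n_members}.
#' @export
perturb_ensemble <- function(config, spec) {
  stopifnot(inherits(config, "mse_scenario"), inherits(spec, "ensemble_spec"))
  # fail early on bad paths
  for (p in names(spec$perturbed_parameters)) perturb_path(config, p, 1)
  rng <- make_rng(spec$base_seed, "ensemble")
  members <- vector("list", spec$n_members)
  members[[1]] <- config
  members[[1]]$member <- 0L
  for (m in 2:spec$n_members) {
    cfg <- config
    for (p in names(spec$perturbed_parameters)) {
      cv <- spec$perturbed_parameters[[p]]
      sigma <- sqrt(log(1 + cv^2))
      n_par <- switch(p, "q" = length(cfg$q), nrow(cfg$groups))
      z <- rng_draw(rng, stats::rnorm, n_par)
      cfg <- perturb_path(cfg, p, exp(sigma * z))
    }
    if (!is.null(spec$structural_variants)) {
      sv <- rep(spec$structural_variants, length.out = spec$n_members)[m]
      cfg$groups$rec_form[!is.na(cfg$groups$rec_form)] <- sv
    }
    cfg$member <- m - 1L
    cfg$seed <- stream_seed(config$seed, paste0("member", m - 1L))
    members[[m]] <- cfg
  }
  members
}

# ---- serialisation ---------------------------------------------------------

#' Write a scenario configuration to a structured text document
#'
#' JSON with 17 significant digits, so numeric round-trip is exact.
#' @param config An \code{mse_scenario}.
#' @param path Output file path.
#' @export
write_scenario <- function(config, path) {
  x <- unclass(config)
  for (nm in c("adjacency", "port_distance", "K", "q", "price_season", "habitat0")) {
    x[[nm]] <- list(dim = dim(x[[nm]]),
                    rn = rownames(x[[nm]]), cn = colnames(x[[nm]]),
                    data = as.numeric(x[[nm]]))
  }
  # named vectors must be written as objects or their names are dropped
  x$phases <- as.list(x$phases)
  for (p in c("habitat_recovery", "habitat_sens", "impact_rate"))
    x$params[[p]] <- as.list(x$params[[p]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Read a scenario configuration written by \code{\link{write_scenario}}
#' @param path File path.
#' @return An \code{mse_scenario}.
#' @export
read_scenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("adjacency", "port_distance", "K", "q", "price_season", "habitat0")) {
    m <- matrix(as.numeric(x[[nm]]$data), nrow = x[[nm]]$dim[1],
                dimnames = list(x[[nm]]$rn, x[[nm]]$cn))
    x[[nm]] <- m
  }
  ph <- unlist(x$phases)
  x$phases <- stats::setNames(as.integer(ph), names(ph))
  x$seed <- as.integer(x$seed)
  x$quarters_per_year <- as.integer(x$quarters_per_year)
  for (p in c("habitat_recovery", "habitat_sens", "impact_rate", "tier_buffer",
              "tier_cv")) {
    v <- unlist(x$params[[p]])
    x$params[[p]] <- stats::setNames(as.numeric(v), names(v))
  }
  for (col in c("r", "M", "mobility", "price", "mean_size_cm", "cmax",
                "trophic_level", "habitat_dependency", "rec_share",
                "rec_sigma", "steepness"))
    x$groups[[col]] <- as.numeric(x$groups[[col]])
  structure(x, class = "mse_scenario")
}

#' @export
print.mse_scenario <- function(x, ...) {
  cat("<mse_scenario> template:", x$template, " seed:", x$seed, "\n")
  cat("  ", nrow(x$groups), "groups x", nrow(x$boxes), "boxes x",
      nrow(x$fleets), "fleets; phases",
      paste(x$phases, collapse = "+"), "years\n")
  invisible(x)
}
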