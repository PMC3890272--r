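# Shared fixtures, built lazily once per test run.
.fx <- new.env(parent = emptyenv())

ref_cfg <- function() {
  if (is.null(.fx$cfg)) .fx$cfg <- generate_scenario("reference", 1)
  .fx$cfg
}

ref_eq <- function() {
  if (is.null(.fx$eq)) .fx$eq <- initialize_equilibrium(ref_cfg())
  .fx$eq
}

ref_run <- function(strategy_id, seed = 5) {
  key <- paste0(strategy_id, "_", seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- run_mse(ref_cfg(), strategy_config(strategy_id, ref_cfg()),
                          seed, equilibrium = ref_eq())
  .fx[[key]]
}

min_cfg <- function() generate_scenario("minimal", 7)

# single-group pure-logistic configuration: no natural mortality, no
# recruitment input, no predation, so the unfished fixed point is exactly K
logistic_cfg <- function(K = 1000, r = 0.5) {
  cfg <- generate_scenario("minimal", 1)
  cfg$groups$M[1] <- 0
  cfg$groups$rec_share[1] <- 0
  cfg$groups$habitat_dependency[1] <- 0
  cfg$groups$mobility[1] <- 0
  cfg$groups$r[1] <- r
  cfg$K["fish", ] <- K
  cfg
}

# tiny detritus-scavenger web for the discard-fed loop checks
scav_cfg <- function() {
  cfg <- generate_scenario("minimal", 1)
  g <- cfg$groups
  scav <- g[1, ]
  scav$id <- "scavenger"; scav$guild <- "scavenger"
  scav$r <- 0.8; scav$M <- 0.6; scav$cmax <- 1.5
  scav$rec_share <- 0.15; scav$mobility <- 0
  cfg$groups <- rbind(g[1, ], scav, g[2, ])
  cfg$K <- rbind(cfg$K[1, , drop = FALSE],
                 scavenger = c(5000, 5000),
                 cfg$K[2, , drop = FALSE])
  rownames(cfg$K)[c(1, 3)] <- c("fish", "detritus")
  cfg$trophic_links <- data.frame(predator = "scavenger", prey = "detritus",
                                  availability = 0.5, stringsAsFactors = FALSE)
  cfg$q <- cbind(cfg$q[, 1, drop = FALSE], scavenger = 0,
                 detritus = 0)
  colnames(cfg$q)[1] <- "fish"
  cfg$price_season <- matrix(1, 3, 4,
                             dimnames = list(cfg$groups$id, paste0("Q", 1:4)))
  cfg
}

zero_mat <- function(cfg) matrix(0, nrow(cfg$groups), nrow(cfg$boxes))
zero_swept <- function(cfg) matrix(0, nrow(cfg$fleets), nrow(cfg$boxes))
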