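#' Packaged management strategy configurations
#'
#' Builds one of the four packaged strategies: \code{S1_status_quo} (catch-
#' trend TACs on 17 target species, annual reconciliation, token zoning),
#' \code{S2_enhanced_quota} (dynamic assessments on 30 target/bycatch/
#' conservation species with baskets, companion TACs and a survey),
#' \code{S3_integrated} (17 target species plus gulper sharks, baskets,
#' companions, discard accounting and enforcement, extensive differential
#' zoning, gear switching allowed) and \code{S4_conservation} (17 target
#' species, very extensive closures including all waters deeper than the
#' deep stratum cutoff, compulsory spawning closures, high compliance
#' enforcement, a licence buyback in projection year 5).
#'
#' The literal control settings (TAC method, assessment frequency, species
#' counts, reconciliation timing, mesh sizes, bycatch-reduction effect,
#' observer coverage, survey, buyback) are also shipped as a plain-text
#' mirror in \code{inst/extdata/strategy_controls.csv}.
#'
#' @param id One of \code{"S1_status_quo"}, \code{"S2_enhanced_quota"},
#'   \code{"S3_integrated"}, \code{"S4_conservation"}.
#' @param config Scenario (used to resolve group ids, boxes and fleets).
#' @return An object of class \code{mse_strategy}.
#' @export
strategy_config <- function(id, config = generate_scenario("reference", 1)) {
  ids <- c("S1_status_quo", "S2_enhanced_quota", "S3_integrated", "S4_conservation")
  if (!id %in% ids) stop("unknown strategy id: ", id)
  g <- config$groups
  target_ids <- g$id[g$guild == "target"]
  boxes <- config$boxes$id
  fleets <- config$fleets$id
  nb <- length(boxes); nf <- length(fleets)
  open1 <- matrix(1, nb, nf, dimnames = list(boxes, fleets))

  base <- list(
    id = id,
    tac_method = "dynamic_assessment",
    assessment_frequency_years = c(`1` = 1L, `2` = 2L, `3` = 3L),
    n_species_under_tac = 17L,
    species_under_tac = target_ids,
    tiered_hcr = TRUE,
    baskets = list(),
    companion_links = list(),
    discard_accounting = FALSE,
    regional_tacs = TRUE,
    regions = list(east = c("inshore_e", "shelf_e", "slope_e"),
                   west = c("shelf_w", "slope_w", "deep")),
    reconciliation = "at_landing",
    zoning = open1,
    spawning_closure = list(active = FALSE),
    mesh_mm = stats::setNames(config$fleets$mesh_mm, fleets),
    brd_effect = 0.8,
    discard_rate_reduction = 0,
    discard_enforcement = FALSE,
    observer_coverage = 0.25,
    survey = FALSE,
    buyback_year = NA_integer_,
    buyback_licences = 0L,
    gear_switching_allowed = FALSE,
    compliance_enforcement = "variable",
    enforcement_level = 0.4,
    limited_entry = TRUE,
    restrictions_new_methods = TRUE,
    logbooks = TRUE
  )
  if (!all(c("inshore_e", "deep") %in% boxes)) {
    # non-reference geometry: single region
    base$regions <- list(all = boxes)
  }

  prune <- function(b) {
    # drop basket/companion entries that do not resolve in this scenario
    b$baskets <- Filter(length, b$baskets)
    b$species_under_tac <- intersect(b$species_under_tac, g$id)
    b$companion_links <- Filter(function(l) all(l %in% g$id),
                                b$companion_links)
    b
  }
  s <- switch(id,
    S1_status_quo = {
      b <- base
      b$tac_method <- "catch_trend"
      b$assessment_frequency_years <- c(`1` = 1L, `2` = 1L, `3` = 1L)
      b$tiered_hcr <- FALSE
      b$regional_tacs <- FALSE
      b$regions <- list(all = boxes)
      b$reconciliation <- "annual"
      b$brd_effect <- 0
      b$enforcement_level <- 0.2
      b$restrictions_new_methods <- FALSE
      z <- open1
      if ("inshore_e" %in% boxes) z["inshore_e", "bottom_trawl"] <- 0.9
      b$zoning <- z
      b
    },
    S2_enhanced_quota = {
      b <- base
      b$n_species_under_tac <- 30L
      commercial <- g$id[g$guild %in% c("target", "byproduct", "bycatch", "scavenger")]
      b$baskets <- list(minor_demersal = intersect(c("morwong", "scavenger"), g$id))
      b$species_under_tac <- setdiff(commercial, unlist(b$baskets))
      b$companion_links <- list(c("ling", "gulper_shark"))
      b$survey <- TRUE
      b$enforcement_level <- 0.4
      z <- open1
      if (nb == 6) {
        z[, "bottom_trawl"] <- c(0.8, 0.9, 0.9, 0.7, 0.7, 0.5)
        z[, "danish_seine"] <- c(0.9, 0.9, 0.9, 1.0, 1.0, 1.0)
        z[, "gillnet_longline"] <- c(0.9, 0.9, 0.9, 0.9, 0.9, 0.7)
      }
      b$zoning <- z
      b$discard_rate_reduction <- 0.65
      b
    },
    S3_integrated = {
      b <- base
      b$n_species_under_tac <- 18L
      b$species_under_tac <- union(target_ids, intersect("gulper_shark", g$id))
      b$baskets <- list(minor_demersal = intersect(c("morwong", "scavenger"), g$id))
      b$companion_links <- list(c("ling", "gulper_shark"))
      b$discard_accounting <- TRUE
      b$discard_enforcement <- TRUE
      b$gear_switching_allowed <- TRUE
      b$enforcement_level <- 0.5
      b$mesh_mm["bottom_trawl"] <- 100
      z <- open1
      if (nb == 6) {
        z[, "bottom_trawl"] <- c(0.3, 0.6, 0.6, 0.5, 0.5, 0.3)
        z[, "danish_seine"] <- c(0.5, 0.7, 0.7, 1.0, 1.0, 1.0)
        z[, "gillnet_longline"] <- c(0.5, 0.6, 0.6, 0.6, 0.6, 0.4)
        z[, "midwater_seine_jig"] <- rep(0.8, 6)
      }
      b$zoning <- z
      b$spawning_closure <- list(active = TRUE, quarter = 4L,
                                 boxes = intersect("shelf_e", boxes),
                                 compulsory = FALSE)
      b
    },
    S4_conservation = {
      b <- base
      b$discard_accounting <- TRUE
      b$gear_switching_allowed <- TRUE
      b$compliance_enforcement <- "high"
      b$enforcement_level <- 0.95
      b$survey <- TRUE
      b$buyback_year <- 5L
      b$buyback_licences <- 30L
      b$mesh_mm["bottom_trawl"] <- 110
      b$mesh_mm["danish_seine"] <- 45
      z <- open1 * 0
      if (nb == 6) {
        z[, "bottom_trawl"] <- c(0, 0.2, 0.2, 0.2, 0.2, 0)
        z[, "danish_seine"] <- c(0, 0.2, 0.2, 0, 0, 0)
        z[, "gillnet_longline"] <- c(0, 0.2, 0.2, 0.2, 0.2, 0)
        z[, "midwater_seine_jig"] <- c(0, 0.7, 0.7, 0.7, 0.7, 0)
      }
      # depth rule: deep stratum closed to all fishing
      z[config$boxes$depth_stratum == "deep", ] <- 0
      b$zoning <- z
      b$spawning_closure <- list(active = TRUE, quarter = 4L,
                                 boxes = intersect("shelf_e", boxes),
                                 compulsory = TRUE)
      b
    })
  structure(prune(s), class = "mse_strategy")
}

#' All four packaged strategies
#' @param config Scenario.
#' @return Named list of \code{mse_strategy}.
#' @export
packaged_strategies <- function(config = generate_scenario("reference", 1)) {
  ids <- c("S1_status_quo", "S2_enhanced_quota", "S3_integrated", "S4_conservation")
  stats::setNames(lapply(ids, strategy_config, config = config), ids)
}

#' Share of a habitat type's area closed to bottom-contact fishing
#'
#' Area-weighted closed fraction (one minus the maximum open fraction across
#' bottom-contact fleets), weighted by each box's initial cover of the type.
#'
#' @param strategy An \code{mse_strategy}.
#' @param config Scenario.
#' @return Named vector, one closed share per habitat type.
#' @export
habitat_closure_share <- function(strategy, config) {
  bc <- config$fleets$bottom_contact
  open_b <- apply(strategy$zoning[, bc, drop = FALSE], 1, max)
  vapply(seq_along(config$habitat_types), function(h) {
    w <- config$boxes$area_km2 * config$habitat0[, h]
    sum(w * (1 - open_b)) / sum(w)
  }, numeric(1)) |> stats::setNames(config$habitat_types)
}

#' Write a strategy configuration as a structured text document
#' @param strategy An \code{mse_strategy}.
#' @param path Output path (JSON dialect, exact numeric round-trip).
#' @export
write_strategy <- function(strategy, path) {
  x <- unclass(strategy)
  x$zoning <- list(dim = dim(x$zoning),
                   rn = rownames(x$zoning), cn = colnames(x$zoning),
                   data = as.numeric(x$zoning))
  x$mesh_mm <- as.list(x$mesh_mm)
  x$assessment_frequency_years <- as.list(x$assessment_frequency_years)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Read a strategy written by \code{\link{write_strategy}}
#' @param path File path.
#' @export
read_strategy <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$zoning <- matrix(as.numeric(x$zoning$data), nrow = x$zoning$dim[1],
                     dimnames = list(x$zoning$rn, x$zoning$cn))
  x$mesh_mm <- stats::setNames(as.numeric(unlist(x$mesh_mm)),
                               names(unlist(x$mesh_mm)))
  x$assessment_frequency_years <-
    stats::setNames(as.integer(unlist(x$assessment_frequency_years)),
                    names(unlist(x$assessment_frequency_years)))
  cl <- x$companion_links
  x$companion_links <- if (is.matrix(cl))
    lapply(seq_len(nrow(cl)), function(i) as.character(cl[i, ]))
  else if (is.character(cl)) list(cl)
  else lapply(cl, function(l) as.character(unlist(l)))
  x$brd_effect <- as.numeric(x$brd_effect)
  x$observer_coverage <- as.numeric(x$observer_coverage)
  bb <- suppressWarnings(as.integer(x$buyback_year))
  x$buyback_year <- if (length(bb) != 1L || is.na(bb)) NA_integer_ else bb
  structure(x, class = "mse_strategy")
}
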