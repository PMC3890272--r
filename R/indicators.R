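#' Slope of the biomass size spectrum
#'
#' OLS slope of log biomass on log mean size class. Needs at least three
#' positive classes; otherwise NA.
#'
#' @param biomass Biomass per size class (tonnes).
#' @param size Mean size per class (cm).
#' @return Slope (dimensionless) or NA.
#' @export
size_spectra_slope <- function(biomass, size) {
  ok <- is.finite(biomass) & is.finite(size) & biomass > 0 & size > 0
  if (sum(ok) < 3) return(NA_real_)
  stats::coef(stats::lm(log(biomass[ok]) ~ log(size[ok])))[[2]]
}

#' Shannon diversity of group biomass shares
#' @param biomass Non-negative biomasses, at least one positive.
#' @return \eqn{H = -\sum p \ln p} over positive shares, NA if all zero.
#' @export
shannon_diversity <- function(biomass) {
  biomass <- biomass[is.finite(biomass) & biomass > 0]
  if (!length(biomass)) return(NA_real_)
  p <- biomass / sum(biomass)
  -sum(p * log(p))
}

#' Catalogue of performance indicators
#'
#' Metadata for every indicator: class (non-economic industry, operator
#' perception, management cost, social, economic, ecological) and whether
#' the indicator is starred, i.e. direction-inverted before normalisation so
#' that high always means good.
#'
#' @return data.frame with columns indicator, class, starred.
#' @export
indicator_catalogue <- function() {
  rbind(
    data.frame(indicator = c("discards", "habitat_impact", "tep_interactions",
                             "total_effort", "total_landings", "cpue",
                             "avg_catch_size", "catch_composition"),
               class = "industry",
               starred = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)),
    data.frame(indicator = c("access", "mgmt_stability", "quota_trading"),
               class = "operator", starred = FALSE),
    data.frame(indicator = c("mgmt_cost_admin", "mgmt_cost_research",
                             "mgmt_cost_enforcement", "mgmt_cost_monitoring",
                             "mgmt_cost_assessment"),
               class = "management_cost", starred = TRUE),
    data.frame(indicator = c("public_image", "gear_conflict", "port_activity"),
               class = "social", starred = c(FALSE, TRUE, FALSE)),
    data.frame(indicator = c("gvp", "operating_costs", "total_profit",
                             "profit_per_tonne", "profit_per_effort"),
               class = "economic", starred = c(FALSE, TRUE, FALSE, FALSE, FALSE)),
    data.frame(indicator = c("biomass_target", "biomass_bycatch",
                             "microfaunal_biomass", "biomass_tep",
                             "biomass_higher_tl", "habitat_cover",
                             "dem_pel_ratio", "pisc_plank_ratio",
                             "size_spectra_change"),
               class = "ecological",
               starred = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                           FALSE, TRUE))
  )
}

#' Compute the annual indicator table from stored simulation series
#'
#' Emits every catalogued indicator for every recorded year of a run, plus
#' reporting extras (CPUE split by trophic level, diversity, trip length)
#' that carry class "extra" and never enter composites.
#'
#' @param res A \code{mse_result} from \code{\link{run_mse}}.
#' @param config Scenario.
#' @return Long data.frame: strategy, year, indicator, value, class, starred.
#' @export
compute_indicator_table <- function(res, config) {
  g <- config$groups
  yrs <- sort(unique(res$annual$year))
  cat_meta <- indicator_catalogue()
  A <- res$annual
  rows <- list()
  emit <- function(year, indicator, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      strategy = res$strategy_id, year = year, indicator = indicator,
      value = value, stringsAsFactors = FALSE)
  }
  # historical-phase mean of the size-spectrum slope as the change baseline
  hist_years <- yrs[yrs <= res$phase_bounds["historical_end"] &
                    yrs > res$phase_bounds["burn_in_end"]]
  slope_by_year <- vapply(yrs, function(y) {
    B <- res$biomass_year[, as.character(y)]
    size <- res$size_year[, as.character(y)]
    size_spectra_slope(B[g$finfish], size[g$finfish])
  }, numeric(1))
  names(slope_by_year) <- as.character(yrs)
  slope_base <- mean(slope_by_year[as.character(hist_years)], na.rm = TRUE)

  for (y in yrs) {
    a <- A[A$year == y, ]
    ych <- as.character(y)
    B <- res$biomass_year[, ych]
    emit(y, "discards", a$discards)
    emit(y, "habitat_impact", a$swept_area)
    emit(y, "tep_interactions", a$tep_interactions)
    emit(y, "total_effort", a$effort_days)
    emit(y, "total_landings", a$landings)
    emit(y, "cpue", if (a$effort_days > 0) a$landings_target / a$effort_days else NA)
    emit(y, "avg_catch_size", a$avg_catch_size)
    emit(y, "catch_composition", a$catch_composition)
    emit(y, "access", a$access)
    emit(y, "mgmt_stability", a$mgmt_stability)
    emit(y, "quota_trading", a$quota_trading)
    emit(y, "mgmt_cost_admin", a$cost_admin)
    emit(y, "mgmt_cost_research", a$cost_research)
    emit(y, "mgmt_cost_enforcement", a$cost_enforcement)
    emit(y, "mgmt_cost_monitoring", a$cost_monitoring)
    emit(y, "mgmt_cost_assessment", a$cost_assessment)
    emit(y, "public_image", a$public_image)
    emit(y, "gear_conflict", a$gear_conflict)
    emit(y, "port_activity", a$port_activity)
    emit(y, "gvp", a$gvp)
    emit(y, "operating_costs", a$costs)
    # loss penalty: negative profits weighted up before aggregation
    pr <- a$profit
    emit(y, "total_profit", if (pr < 0) pr * config$params$loss_penalty else pr)
    emit(y, "profit_per_tonne", if (a$landings > 0) pr / a$landings else NA)
    emit(y, "profit_per_effort", if (a$effort_days > 0) pr / a$effort_days else NA)
    emit(y, "biomass_target", sum(B[g$guild == "target"]))
    emit(y, "biomass_bycatch", sum(B[g$guild == "bycatch"]))
    emit(y, "microfaunal_biomass", sum(B[g$guild == "detritus"]))
    emit(y, "biomass_tep", sum(B[g$guild == "TEP"]))
    emit(y, "biomass_higher_tl", sum(B[g$trophic_level >= 4]))
    emit(y, "habitat_cover", a$habitat_cover)
    dem <- sum(B[g$finfish & g$habitat_assoc == "demersal"])
    pel <- sum(B[g$finfish & g$habitat_assoc == "pelagic"])
    emit(y, "dem_pel_ratio", if (pel > 0) dem / pel else NA)
    pisc <- sum(B[g$finfish & g$piscivore])
    plank <- sum(B[g$finfish & !g$piscivore])
    emit(y, "pisc_plank_ratio", if (plank > 0) pisc / plank else NA)
    emit(y, "size_spectra_change", abs(slope_by_year[ych] - slope_base))
    # reporting extras (class "extra"; excluded from composites)
    emit(y, "cpue_low_tl", if (a$effort_days > 0) a$landings_low_tl / a$effort_days else NA)
    emit(y, "cpue_high_tl", if (a$effort_days > 0) a$landings_high_tl / a$effort_days else NA)
    emit(y, "diversity", shannon_diversity(B[g$guild != "detritus"]))
    emit(y, "trip_length", a$trip_length)
  }
  out <- do.call(rbind, rows)
  meta <- rbind(cat_meta,
                data.frame(indicator = c("cpue_low_tl", "cpue_high_tl",
                                         "diversity", "trip_length"),
                           class = "extra", starred = FALSE))
  out <- merge(out, meta, by = "indicator", sort = FALSE)
  out[order(out$year, match(out$indicator, meta$indicator)),
      c("strategy", "year", "indicator", "class", "starred", "value")]
}

#' Invert starred indicators and normalise so the best value is 1
#'
#' Starred indicators (where low raw values are good) are reflected as
#' \eqn{x \to x_{max} - x}, with the maximum taken jointly over all
#' strategies and years present in the table; every indicator is then
#' divided by its joint maximum so the best observed value is exactly 1.
#' Constant indicators map to 1 everywhere. NAs propagate.
#'
#' @param table Long indicator table from \code{\link{compute_indicator_table}}
#'   (possibly row-bound across strategies).
#' @return Same shape with unit-scaled values in [0,1].
#' @export
invert_and_normalize <- function(table) {
  out <- table
  for (ind in unique(table$indicator)) {
    i <- table$indicator == ind
    v <- table$value[i]
    if (all(is.na(v))) next
    if (table$starred[i][1]) v <- max(v, na.rm = TRUE) - v
    # indicators that can be negative (e.g. profits) are shifted so the
    # joint minimum sits at zero before scaling
    mn <- min(v, na.rm = TRUE)
    if (mn < 0) v <- v - mn
    stopifnot(all(v >= -1e-9, na.rm = TRUE))
    v <- pmax(v, 0)
    mx <- max(v, na.rm = TRUE)
    out$value[i] <- if (mx > 0) v / mx else rep(1, length(v))
  }
  out
}

#' Composite class scores for kite diagrams
#'
#' Arithmetic (optionally weighted) mean of a class's unit-scaled member
#' indicators per strategy and year.
#'
#' @param unit_table Output of \code{\link{invert_and_normalize}}.
#' @param weights Optional named vector of indicator weights.
#' @return data.frame: strategy, year, class, score in [0,1].
#' @export
composite_scores <- function(unit_table, weights = NULL) {
  ut <- unit_table[unit_table$class != "extra", ]
  if (!nrow(ut)) stop("empty indicator table")
  key <- unique(ut[, c("strategy", "year", "class")])
  score <- numeric(nrow(key))
  for (i in seq_len(nrow(key))) {
    sel <- ut$strategy == key$strategy[i] & ut$year == key$year[i] &
      ut$class == key$class[i]
    v <- ut$value[sel]
    w <- if (is.null(weights)) rep(1, sum(sel)) else {
      wv <- weights[ut$indicator[sel]]
      wv[is.na(wv)] <- 1
      wv
    }
    ok <- !is.na(v)
    if (!any(ok)) stop("empty class after NA removal: ", key$class[i])
    score[i] <- sum(v[ok] * w[ok]) / sum(w[ok])
  }
  cbind(key, score = score)
}

#' Kite-diagram data for the reporting years
#'
#' Extracts the six-axis composite scores at the last historical year and
#' the final projection year.
#'
#' @param scores Output of \code{\link{composite_scores}}.
#' @param hist_year Last historical year.
#' @param final_year Final projection year.
#' @return List (strategy -> year label -> axis -> value), JSON-ready.
#' @export
kite_data <- function(scores, hist_year, final_year) {
  out <- list()
  for (s in unique(scores$strategy)) {
    out[[s]] <- list()
    for (yl in c(historical = hist_year, final = final_year)) {
      lab <- names(which(c(historical = hist_year, final = final_year) == yl))[1]
      sub <- scores[scores$strategy == s & scores$year == yl, ]
      out[[s]][[lab]] <- stats::setNames(as.list(sub$score), sub$class)
    }
  }
  out
}
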